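# End-to-end orchestration: simulate -> normalize -> ratios -> rollup ->
# call -> ligand -> enrich -> score, with a content-digest manifest, plus
# recovery scoring of call sets against planted ground truth.

#' Pipeline stage toggles
#'
#' @param normalize Equalize channel totals before ratio formation.
#' @param rollup Roll peptides up to sites/proteins.
#' @param calling Call reactivity changes.
#' @param ligand Simulate and analyze the ATP add-back experiment.
#' @param enrichment Annotation-class enrichment of the called proteins.
#' @param score Score calls against the planted ground truth.
#' @return Named list of logical toggles.
#' @export
pipeline_stages <- function(normalize = TRUE, rollup = TRUE, calling = TRUE,
                            ligand = TRUE, enrichment = TRUE, score = TRUE) {
  list(normalize = normalize, rollup = rollup, calling = calling,
       ligand = ligand, enrichment = enrichment, score = score)
}

#' Run the full synthetic-data pipeline
#'
#' Generates the proteome and experiments from `config`, writes every
#' input and stage artifact under `out_dir`, and returns the in-memory
#' objects. Deterministic given `config$seed`: re-running with the same
#' configuration reproduces every output byte for byte (verified via the
#' md5 manifest). Disabling a stage that a later stage depends on aborts
#' with the name of the missing input.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages A [pipeline_stages()] list.
#' @param params A [call_params()] for reactivity calling.
#' @param ligand_threshold Fold gate for ATP sensitivity (default 2).
#' @param cross_states Two states contrasted by the cross-state rule
#'   (default `c("D8C", "D2")`).
#' @return Invisible list with all stage objects (`proteome`,
#'   `experiment`, `sites`, `proteins`, `calls`, `ligand_calls`,
#'   `cross_state`, `enrichment`, `recovery`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, stages = pipeline_stages(),
                         params = call_params(),
                         ligand_threshold = 2,
                         cross_states = c("D8C", "D2")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n"),
        file = logf, append = TRUE)
  }
  unlink(logf)
  written <- character(0)
  emit <- function(x, name, writer = write_table) {
    path <- file.path(out_dir, name)
    writer(x, path)
    written <<- c(written, path)
    path
  }

  log_line("stage simulate: seed ", config$seed)
  proteome <- simulate_proteome(config)
  experiment <- simulate_experiment(config, proteome)
  emit(proteome$database, "proteins.fasta", write_fasta)
  emit(proteome$annotations, "annotations.tsv", write_annotations)
  emit(proteome$truth, "ground_truth.tsv", write_ground_truth)
  emit(experiment$layout, "experiment.layout", write_layout)
  for (px in unique(experiment$layout$plex_id)) {
    emit(experiment$enriched[experiment$enriched$plex_id == px, ],
         paste0("enriched_", px, ".tsv"),
         function(x, p) write_quant_table(x, p, experiment$layout))
    emit(experiment$unenriched[experiment$unenriched$plex_id == px, ],
         paste0("unenriched_", px, ".tsv"),
         function(x, p) write_quant_table(x, p, experiment$layout))
  }

  enriched <- experiment$enriched
  unenriched <- experiment$unenriched
  if (isTRUE(stages$normalize)) {
    log_line("stage normalize")
    enriched <- normalize_channels(enriched, experiment$layout)
    unenriched <- normalize_channels(unenriched, experiment$layout)
    emit(attr(enriched, "norm_factors"), "norm_factors_enriched.tsv")
    emit(attr(unenriched, "norm_factors"), "norm_factors_unenriched.tsv")
  } else {
    log_line("stage normalize: skipped")
  }

  sites <- NULL
  proteins <- NULL
  if (isTRUE(stages$rollup)) {
    log_line("stage rollup")
    enr_ratios <- condition_ratios(enriched, experiment$layout)
    unenr_ratios <- condition_ratios(unenriched, experiment$layout)
    log_line("records dropped for missing reference: enriched ",
             attr(enr_ratios, "dropped_records"), ", unenriched ",
             attr(unenr_ratios, "dropped_records"))
    sites <- rollup_sites(enr_ratios, proteome$database)
    proteins <- rollup_proteins(unenr_ratios)
    emit(sites, "site_quant.tsv")
    emit(proteins, "protein_quant.tsv")
  } else {
    log_line("stage rollup: skipped")
  }

  calls <- NULL
  if (isTRUE(stages$calling)) {
    if (is.null(sites)) {
      abort("calling stage requires site_quant from the rollup stage; enable 'rollup'")
    }
    log_line("stage calling")
    calls <- call_reactivity(sites, proteins, params)
    emit(calls, "reactivity_calls.tsv")
    emit(summarize_calls(calls, proteome$annotations), "call_summary.tsv")
  } else {
    log_line("stage calling: skipped")
  }

  ligand_calls <- NULL
  cross <- NULL
  if (isTRUE(stages$ligand)) {
    log_line("stage ligand")
    addback <- simulate_atp_addback(config, proteome)
    emit(addback$layout, "addback.layout", write_layout)
    for (px in unique(addback$layout$plex_id)) {
      emit(addback$enriched[addback$enriched$plex_id == px, ],
           paste0("addback_enriched_", px, ".tsv"),
           function(x, p) write_quant_table(x, p, addback$layout))
    }
    ligand_calls <- call_ligand_sensitivity(
      addback$enriched, addback$layout, proteome$database,
      threshold = ligand_threshold, normalize = isTRUE(stages$normalize)
    )
    cross <- cross_state_sensitivity(ligand_calls, cross_states[[1]],
                                     cross_states[[2]],
                                     threshold = ligand_threshold)
    emit(ligand_calls, "ligand_calls.tsv")
    emit(cross, "cross_state_calls.tsv")
  } else {
    log_line("stage ligand: skipped")
  }

  enrich <- NULL
  if (isTRUE(stages$enrichment)) {
    if (is.null(calls)) {
      abort("enrichment stage requires reactivity_calls from the calling stage; enable 'calling'")
    }
    log_line("stage enrichment")
    background <- unique(sites$accession)
    hits <- unique(calls$accession[calls$verdict == "reactivity_change"])
    enrich <- class_enrichment(hits, background, proteome$annotations)
    emit(enrich, "enrichment.tsv")
  } else {
    log_line("stage enrichment: skipped")
  }

  recovery <- NULL
  if (isTRUE(stages$score)) {
    if (is.null(calls)) {
      abort("score stage requires reactivity_calls from the calling stage; enable 'calling'")
    }
    log_line("stage score")
    recovery <- score_against_truth(proteome$truth, calls = calls,
                                    ligand_calls = ligand_calls,
                                    cross_state = cross,
                                    proteins = proteins)
    emit(recovery, "recovery.tsv")
  } else {
    log_line("stage score: skipped")
  }

  cfg_flat <- lapply(unclass(config), function(x) {
    if (is.list(x)) unlist(x) else x
  })
  jsonlite::write_json(cfg_flat, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(out_dir, "params.json"))
  manifest <- tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written)),
    bytes = unname(file.size(written))
  ) %>% arrange(.data$file)
  write_table(manifest, file.path(out_dir, "manifest.tsv"))
  log_line("done; ", length(written), " artifacts")

  invisible(list(proteome = proteome, experiment = experiment,
                 sites = sites, proteins = proteins, calls = calls,
                 ligand_calls = ligand_calls, cross_state = cross,
                 enrichment = enrich, recovery = recovery,
                 manifest = manifest, out_dir = out_dir))
}

recovery_row <- function(type, planted_keys, recovered_keys, called_keys) {
  n_planted <- length(planted_keys)
  tp <- length(intersect(recovered_keys, planted_keys))
  fp <- length(setdiff(called_keys, planted_keys))
  n_called <- length(called_keys)
  tibble(
    effect_type = type,
    n_planted = n_planted,
    n_recovered = tp,
    n_called = n_called,
    n_false = fp,
    sensitivity = if (n_planted > 0) tp / n_planted else NA_real_,
    fdp = if (n_called > 0) fp / n_called else 0,
    fdp_defined = n_called > 0
  )
}

#' Score call sets against planted ground truth
#'
#' A planted effect counts as recovered when it is called in the planted
#' condition with the planted direction. False discoveries are calls at
#' (site, condition) pairs with no planted effect of that type. An empty
#' call set yields sensitivity 0 and a false discovery proportion reported
#' as 0 with `fdp_defined = FALSE`.
#'
#' @param truth A `ground_truth` (from the simulator or
#'   [read_ground_truth()]).
#' @param calls Optional `reactivity_calls`.
#' @param ligand_calls Optional `ligand_calls`.
#' @param cross_state Optional cross-state table from
#'   [cross_state_sensitivity()].
#' @param proteins Optional `protein_quant` for scoring planted expression
#'   effects.
#' @param fc_threshold Fold gate used to score expression recovery
#'   (default 2).
#' @return Tibble of class `recovery_report`, one row per effect type
#'   (`reactivity`, `expression`, `expression_confound`, `atp`,
#'   `atp_cross_state` as available): planted/recovered/false counts,
#'   `sensitivity`, `fdp`, `fdp_defined`. For `expression_confound` the
#'   `sensitivity` column is the fraction of sites on expression-shifted
#'   proteins correctly *not* called as reactivity changes.
#' @export
score_against_truth <- function(truth, calls = NULL, ligand_calls = NULL,
                                cross_state = NULL, proteins = NULL,
                                fc_threshold = 2) {
  stopifnot(inherits(truth, "ground_truth"))
  rows <- list()
  lfc <- log2(fc_threshold)
  keyfun <- function(a, b) paste(a, b, sep = "\r")

  if (!is.null(calls)) {
    unknown <- setdiff(unique(calls$site_id), truth$sites$site_id)
    if (length(unknown) > 0) {
      abort(paste0("call set references site(s) absent from ground truth: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    hits <- calls[calls$verdict == "reactivity_change", ]
    planted <- keyfun(truth$reactivity$site_id, truth$reactivity$condition)
    planted_dir <- ifelse(truth$reactivity$effect_log2 >= 0, "higher",
                          "lower")
    hit_keys <- keyfun(hits$site_id, hits$condition)
    m <- match(planted, hit_keys)
    recovered <- planted[!is.na(m) & hits$direction[m] == planted_dir]
    rows$reactivity <- recovery_row("reactivity", planted, recovered,
                                    hit_keys)

    # sites on expression-shifted proteins (no reactivity planted there):
    # fraction correctly labeled expression_coupled or no_change
    conf <- inner_join(as_tibble(calls), truth$expression,
                       by = c("accession", "condition"))
    conf <- anti_join(conf, truth$reactivity,
                      by = c("site_id", "condition"))
    conf <- conf[conf$verdict != "insufficient_evidence", ]
    n_conf <- nrow(conf)
    n_ok <- sum(conf$verdict %in% c("expression_coupled", "no_change"))
    rows$confound <- tibble(
      effect_type = "expression_confound",
      n_planted = n_conf, n_recovered = n_ok,
      n_called = n_conf, n_false = n_conf - n_ok,
      sensitivity = if (n_conf > 0) n_ok / n_conf else NA_real_,
      fdp = if (n_conf > 0) (n_conf - n_ok) / n_conf else 0,
      fdp_defined = n_conf > 0
    )
  }

  if (!is.null(proteins)) {
    prot_fc <- as_tibble(proteins) %>%
      filter(.data$condition != truth$reference_condition) %>%
      group_by(.data$accession, .data$condition) %>%
      summarise(log2fc = median(.data$log2_ratio), .groups = "drop")
    called <- prot_fc[abs(prot_fc$log2fc) >= lfc, ]
    planted <- keyfun(truth$expression$accession, truth$expression$condition)
    called_keys <- keyfun(called$accession, called$condition)
    dir_called <- ifelse(called$log2fc >= 0, 1, -1)
    planted_dir <- ifelse(truth$expression$effect_log2 >= 0, 1, -1)
    m <- match(planted, called_keys)
    recovered <- planted[!is.na(m) & dir_called[m] == planted_dir]
    rows$expression <- recovery_row("expression", planted, recovered,
                                    called_keys)
  }

  if (!is.null(ligand_calls)) {
    atp <- truth$atp
    expand <- bind_rows(lapply(seq_len(nrow(atp)), function(i) {
      st <- if (is.na(atp$state[[i]])) truth$atp_states else atp$state[[i]]
      tibble(site_id = atp$site_id[[i]], state = st,
             effect_log2 = atp$effect_log2[[i]])
    }))
    sens <- ligand_calls[ligand_calls$sensitive, ]
    planted <- keyfun(expand$site_id, expand$state)
    planted_dir <- ifelse(expand$effect_log2 < 0, "decreased", "increased")
    called_keys <- keyfun(sens$site_id, sens$state)
    m <- match(planted, called_keys)
    recovered <- planted[!is.na(m) & sens$direction[m] == planted_dir]
    rows$atp <- recovery_row("atp", planted, recovered, called_keys)
  }

  if (!is.null(cross_state)) {
    state_x <- attr(cross_state, "state_x") %||% "D8C"
    planted <- unique(truth$atp$site_id[!is.na(truth$atp$state) &
                                          truth$atp$state == state_x])
    called_keys <- cross_state$site_id[cross_state$flagged]
    recovered <- intersect(called_keys, planted)
    rows$atp_cross <- recovery_row("atp_cross_state", planted, recovered,
                                   called_keys)
  }

  out <- bind_rows(rows)
  structure(out, class = unique(c("recovery_report", class(out))))
}
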