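# Evidence-tiered calling of state-dependent cysteine reactivity changes,
# deconvolved from protein abundance.

#' Parameters for reactivity calling
#'
#' Defaults encode the profiling rule used throughout: a change requires a
#' greater than `fc_threshold`-fold signal difference relative to the
#' reference (activated) state, on a protein with at least
#' `min_cys_peptides` quantified cysteine peptides, or with a single
#' quantified peptide plus matching unenriched proteomics data.
#'
#' @param fc_threshold Fold-change gate (> 1; default 2, i.e. |log2| >= 1).
#'   Applied to both the raw site ratio and the abundance-corrected ratio.
#' @param min_cys_peptides Distinct cysteine peptides required on the
#'   protein for the multi-peptide evidence tier (default 2).
#' @param baseline_mode `"auto"` uses the unenriched protein log2FC when
#'   the protein was quantified there and otherwise falls back to the
#'   leave-one-out median of the protein's other cysteine sites;
#'   `"unenriched_protein"` and `"median_cysteine"` force one source.
#' @param conditions Comparison conditions (default: every non-reference
#'   condition present in the data).
#' @param reference Reference condition (default `"D2"`).
#' @return List of class `call_params`.
#' @export
call_params <- function(fc_threshold = 2, min_cys_peptides = 2L,
                        baseline_mode = c("auto", "unenriched_protein",
                                          "median_cysteine"),
                        conditions = NULL, reference = "D2") {
  baseline_mode <- match.arg(baseline_mode)
  if (!is.finite(fc_threshold) || fc_threshold <= 1) {
    abort("fc_threshold must be finite and > 1")
  }
  if (min_cys_peptides < 1L) abort("min_cys_peptides must be >= 1")
  if (!is.null(conditions) && reference %in% conditions) {
    abort("reference condition cannot be a comparison condition")
  }
  structure(list(fc_threshold = fc_threshold,
                 min_cys_peptides = as.integer(min_cys_peptides),
                 baseline_mode = baseline_mode,
                 conditions = conditions,
                 reference = reference),
            class = "call_params")
}

#' Call state-dependent cysteine reactivity changes
#'
#' Per site and comparison condition, the raw log2 fold change is the
#' cross-donor median of the site's ratios. The abundance baseline is the
#' protein's unenriched log2FC when available, else the leave-one-out
#' median of the protein's other quantified cysteine sites (at least two
#' others required). Verdicts:
#' \describe{
#'   \item{`reactivity_change`}{both `|raw|` and `|corrected|` reach
#'     `log2(fc_threshold)`; direction follows the sign of the raw ratio.}
#'   \item{`expression_coupled`}{`|raw|` reaches the gate but the baseline
#'     explains it (`|corrected|` below the gate).}
#'   \item{`no_change`}{`|raw|` below the gate.}
#'   \item{`insufficient_evidence`}{the evidence tier cannot be
#'     established (single-peptide protein without unenriched data) or no
#'     baseline exists in either mode.}
#' }
#' Composite (multi-cysteine) sites are excluded from calling.
#'
#' @param sites A `site_quant` from [rollup_sites()].
#' @param proteins A `protein_quant` from [rollup_proteins()], or `NULL`
#'   when no unenriched experiment exists.
#' @param params A [call_params()] object.
#' @return Tibble of class `reactivity_calls`, one row per site x
#'   condition: `site_id`, `accession`, `condition`, `raw_log2fc`,
#'   `baseline_log2fc`, `baseline_source`, `corrected_log2fc`, `direction`,
#'   `verdict`, `evidence_tier`, `n_peptides`, `n_donors_observed`.
#' @export
call_reactivity <- function(sites, proteins = NULL, params = call_params()) {
  if (is.null(sites) || nrow(sites) == 0L) abort("empty site input")
  stopifnot(inherits(params, "call_params"))
  ref <- params$reference
  x <- as_tibble(sites) %>% filter(!.data$composite)
  conditions <- params$conditions %||%
    setdiff(unique(x$condition), ref)
  x <- x %>% filter(.data$condition %in% conditions)
  if (nrow(x) == 0L) abort("no comparison-condition site data to call")

  raw <- x %>%
    group_by(.data$site_id, .data$accession, .data$condition) %>%
    summarise(raw_log2fc = median(.data$log2_ratio),
              n_donors_observed = n_distinct(.data$donor),
              .groups = "drop")
  n_pep <- distinct(as_tibble(sites)[, c("site_id", "n_peptides")])
  raw <- left_join(raw, n_pep, by = "site_id")

  cys_pep <- attr(sites, "cys_peptides")
  if (is.null(cys_pep)) {
    # fall back: approximate protein-level peptide support from site support
    cys_pep <- as_tibble(sites) %>%
      distinct(.data$site_id, .data$accession, .data$n_peptides) %>%
      group_by(.data$accession) %>%
      summarise(n_cys_peptides = sum(.data$n_peptides), .groups = "drop")
  }
  raw <- left_join(raw, cys_pep, by = "accession")
  raw$n_cys_peptides[is.na(raw$n_cys_peptides)] <- 1L

  # protein abundance baseline from the unenriched experiment
  if (!is.null(proteins) && nrow(proteins) > 0L) {
    prot_fc <- as_tibble(proteins) %>%
      filter(.data$condition %in% conditions) %>%
      group_by(.data$accession, .data$condition) %>%
      summarise(protein_log2fc = median(.data$log2_ratio), .groups = "drop")
    raw <- left_join(raw, prot_fc, by = c("accession", "condition"))
  } else {
    raw$protein_log2fc <- NA_real_
  }

  # leave-one-out median of the protein's other quantified sites
  loo <- raw %>%
    group_by(.data$accession, .data$condition) %>%
    mutate(
      n_sites_prot = n(),
      loo_log2fc = {
        v <- .data$raw_log2fc
        if (length(v) >= 3L) {
          vapply(seq_along(v), function(i) median(v[-i]), numeric(1))
        } else {
          rep(NA_real_, length(v))
        }
      }
    ) %>%
    ungroup()

  mode <- params$baseline_mode
  use_prot <- switch(mode,
    auto = !is.na(loo$protein_log2fc),
    unenriched_protein = !is.na(loo$protein_log2fc),
    median_cysteine = rep(FALSE, nrow(loo))
  )
  use_loo <- switch(mode,
    auto = !use_prot & !is.na(loo$loo_log2fc),
    unenriched_protein = rep(FALSE, nrow(loo)),
    median_cysteine = !is.na(loo$loo_log2fc)
  )
  baseline <- ifelse(use_prot, loo$protein_log2fc,
                     ifelse(use_loo, loo$loo_log2fc, NA_real_))
  baseline_source <- ifelse(use_prot, "unenriched_protein",
                            ifelse(use_loo, "median_cysteine", "none"))

  has_proteome <- !is.na(loo$protein_log2fc)
  tier <- ifelse(loo$n_cys_peptides >= params$min_cys_peptides,
                 "multi_peptide",
                 ifelse(has_proteome, "single_peptide_with_proteome",
                        "insufficient"))

  lfc_gate <- log2(params$fc_threshold)
  corrected <- loo$raw_log2fc - baseline
  verdict <- rep("no_change", nrow(loo))
  verdict[abs(loo$raw_log2fc) >= lfc_gate] <- "expression_coupled"
  verdict[abs(loo$raw_log2fc) >= lfc_gate &
            !is.na(corrected) & abs(corrected) >= lfc_gate] <-
    "reactivity_change"
  verdict[tier == "insufficient" | is.na(baseline)] <- "insufficient_evidence"

  out <- tibble(
    site_id = loo$site_id,
    accession = loo$accession,
    condition = loo$condition,
    raw_log2fc = loo$raw_log2fc,
    baseline_log2fc = baseline,
    baseline_source = baseline_source,
    corrected_log2fc = corrected,
    direction = ifelse(loo$raw_log2fc >= 0, "higher", "lower"),
    verdict = verdict,
    evidence_tier = ifelse(tier == "insufficient", NA_character_, tier),
    n_peptides = loo$n_peptides,
    n_donors_observed = loo$n_donors_observed
  )
  structure(out, params = params,
            class = unique(c("reactivity_calls", class(out))))
}

#' Summarize reactivity calls
#'
#' Counts of higher/lower reactivity changes per comparison condition,
#' optionally split by annotation class (classes may overlap, in which
#' case per-class counts need not sum to the totals).
#'
#' @param calls A `reactivity_calls` tibble.
#' @param annotations Optional `annotation_set`.
#' @return Tibble with `condition`, `direction`, `n` (and `class` when
#'   `annotations` is given, including an `"all"` pseudo-class with the
#'   unsplit totals).
#' @export
summarize_calls <- function(calls, annotations = NULL) {
  hits <- as_tibble(calls) %>% filter(.data$verdict == "reactivity_change")
  grid <- expand.grid(condition = unique(calls$condition),
                      direction = c("higher", "lower"),
                      stringsAsFactors = FALSE)
  totals <- hits %>%
    count(.data$condition, .data$direction) %>%
    right_join(grid, by = c("condition", "direction")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) %>%
    arrange(.data$condition, .data$direction)
  if (is.null(annotations)) {
    return(as_tibble(totals))
  }
  per_class <- bind_rows(lapply(names(annotations), function(cl) {
    hits %>%
      filter(.data$accession %in% annotations[[cl]]) %>%
      count(.data$condition, .data$direction) %>%
      right_join(grid, by = c("condition", "direction")) %>%
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n), class = cl)
  }))
  bind_rows(mutate(totals, class = "all"), per_class) %>%
    select("class", "condition", "direction", "n") %>%
    arrange(.data$class, .data$condition, .data$direction)
}
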