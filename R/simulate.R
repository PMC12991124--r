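# Synthetic multi-plex TMT experiments (enriched + unenriched), ATP
# add-back experiments, and metabolomics/tracing tables with planted
# ground truth. The generator's defaults encode the study design it
# emulates: five T cell states (activated D2; acute D4A/D8A; chronic
# D4C/D8C) in a 10-plex with two channels per state, one plex per donor,
# five donors; a 16-channel ATP add-back across D2/D8A/D8C; four-donor
# metabolite panels.

PEPTIDE_ALPHABET <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                      "P", "Q", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. All randomness in
#' the `simulate_*` functions flows from `seed` (each generator uses a
#' fixed small offset of it, so the proteome, the experiments, and the
#' metabolite tables are jointly reproducible).
#'
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param conditions Cell states profiled (first five-state default).
#' @param reference_condition Ratio denominator state (default `"D2"`).
#' @param channels_per_condition Reporter channels per state per plex.
#' @param n_donors Donors (= plexes) in the main experiment.
#' @param cys_sites_mean Mean cysteine sites per protein (>= 1 enforced).
#' @param peptides_per_site_mean Mean distinct peptide forms per site
#'   (1..3; extra forms emulate missed cleavages).
#' @param unenriched_peptides_mean Mean cysteine-free peptides per protein
#'   feeding the unenriched experiment.
#' @param noise_sd_log2 Log2 measurement noise SD (log-normal reporter
#'   error).
#' @param donor_sd_log2 SD of per-(protein, condition, donor) biological
#'   offsets — donor-to-donor variability that does not cancel in ratios.
#' @param missing_rate Expected fraction of missing intensity cells.
#' @param missing_mode `"intensity"` (logistic in log2 intensity, the MS
#'   detection-limit behavior) or `"mcar"`.
#' @param planted_expression List `fraction`, `effect_log2`: protein
#'   abundance shifts (random sign, one random non-reference condition
#'   each).
#' @param planted_reactivity List `fraction`, `effect_log2`: site-specific
#'   reactivity shifts, planted on proteins without expression effects so
#'   every planted effect is identifiable at zero noise.
#' @param planted_atp List `fraction`, `effect_log2`, `state_specific`:
#'   ATP-occluded sites; the (negative) occlusion applies in treated
#'   channels, in all states or only in `atp_specific_state`.
#' @param atp_states States in the add-back experiment.
#' @param atp_specific_state State carrying the occlusion when
#'   `state_specific` is `TRUE` (default `"D8C"`).
#' @param addback_replicates Named integer vector: control/treated channel
#'   pairs per state (defaults summing to a 16-channel plex).
#' @param n_addback_donors Donors (= plexes) in the add-back experiment.
#' @param atp_class_odds Odds multiplier linking ATP-occluded proteins to
#'   the `nucleotide_binding` annotation class (1 = independence).
#' @param class_base_rates Baseline membership probabilities for the
#'   annotation classes.
#' @param n_metabolites,metab_conditions,n_metab_donors,metab_noise_sd,
#'   metab_missing_rate,planted_metab Metabolite-panel settings.
#' @param cell_volumes Named mean cell volumes (fL) per state.
#' @param cell_count_mean Mean cells per metabolite sample.
#' @param tracer_p_nat Natural 13C abundance used by the tracing
#'   simulator.
#' @param seed Integer seed (mandatory).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    n_proteins = 500L,
    conditions = c("D2", "D4A", "D4C", "D8A", "D8C"),
    reference_condition = "D2",
    channels_per_condition = 2L,
    n_donors = 5L,
    cys_sites_mean = 2,
    peptides_per_site_mean = 1.6,
    unenriched_peptides_mean = 4,
    noise_sd_log2 = 0.25,
    donor_sd_log2 = 0.1,
    missing_rate = 0.2,
    missing_mode = c("intensity", "mcar"),
    planted_expression = list(fraction = 0.05, effect_log2 = 2),
    planted_reactivity = list(fraction = 0.05, effect_log2 = 2),
    planted_atp = list(fraction = 0.05, effect_log2 = -2,
                       state_specific = TRUE),
    atp_states = c("D2", "D8A", "D8C"),
    atp_specific_state = "D8C",
    addback_replicates = c(D2 = 2L, D8A = 3L, D8C = 3L),
    n_addback_donors = 2L,
    atp_class_odds = 4,
    class_base_rates = c(mitochondrial = 0.15, nucleotide_binding = 0.2),
    n_metabolites = 150L,
    metab_conditions = c("D2", "D8A", "D8C"),
    n_metab_donors = 4L,
    metab_noise_sd = 0.2,
    metab_missing_rate = 0.03,
    planted_metab = list(fraction = 0.1, effect_log2 = 1),
    cell_volumes = c(D2 = 600, D8A = 350, D8C = 450),
    cell_count_mean = 2e6,
    tracer_p_nat = 0.0107,
    seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  missing_mode <- match.arg(missing_mode)
  for (pl in list(planted_expression, planted_reactivity, planted_atp,
                  planted_metab)) {
    if (pl$fraction < 0 || pl$fraction > 1) {
      abort("planted fractions must lie in [0, 1]")
    }
    if (!is.finite(pl$effect_log2)) abort("effect magnitudes must be finite")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    abort("missing_rate must lie in [0, 1]")
  }
  if (!reference_condition %in% conditions) {
    abort("reference_condition must be one of conditions")
  }
  if (!all(atp_states %in% conditions)) {
    abort("atp_states must be a subset of conditions")
  }
  if (!setequal(names(addback_replicates), atp_states)) {
    abort("addback_replicates must be named by atp_states")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

rand_peptide <- function(len) {
  paste0(paste(sample(PEPTIDE_ALPHABET, len - 1L, replace = TRUE),
               collapse = ""),
         sample(c("K", "R"), 1L))
}

rand_cys_peptide <- function(len) {
  body <- sample(PEPTIDE_ALPHABET, len - 1L, replace = TRUE)
  c_pos <- sample(2:(len - 2L), 1L)
  body[c_pos] <- "C"
  list(seq = paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L)),
       c_pos = c_pos)
}

#' Simulate a proteome with planted effects
#'
#' Generates tryptic-style protein sequences in which every target
#' cysteine sits inside a 6–25-residue peptide bounded by K/R, assigns
#' annotation classes, and plants the ground-truth effects: protein
#' abundance shifts, site-specific reactivity shifts, and ATP-occluded
#' sites. Membership in the `nucleotide_binding` class is linked to ATP
#' occlusion by a configurable odds multiplier (`atp_class_odds = 1`
#' makes them independent). Expression and reactivity effects are planted
#' on disjoint protein sets so that every planted effect is individually
#' recoverable at zero noise.
#'
#' @param config A [simulation_config()].
#' @return List of class `sim_proteome`: `database` (a `protein_db`),
#'   `annotations` (an `annotation_set`), `truth` (a `ground_truth` list),
#'   `enriched_peptides` and `unenriched_peptides` (design tables used by
#'   the experiment simulators).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  accs <- sprintf("P%05d", seq_len(n))
  n_sites <- pmax(1L, rpois(n, config$cys_sites_mean))
  # distinct peptide forms per site in 1..3 with the configured mean
  q <- min(1, max(0, (config$peptides_per_site_mean - 1) / 2))

  seqs <- character(n)
  site_acc <- list(); site_res <- list()
  enr_acc <- list(); enr_seq <- list(); enr_off <- list(); enr_res <- list()
  un_acc <- list(); un_seq <- list()
  for (i in seq_len(n)) {
    k <- n_sites[[i]]
    n_fill <- max(k + 1L, rpois(1L, config$unenriched_peptides_mean))
    fillers <- vapply(sample(6:25, n_fill, replace = TRUE), rand_peptide,
                      character(1))
    cys <- lapply(sample(8:20, k, replace = TRUE), rand_cys_peptide)
    # interleave: F1 S1 F2 S2 ... F_{k+1}, extra fillers appended
    pieces <- character(2L * k)
    pieces[2L * seq_len(k) - 1L] <- fillers[seq_len(k)]
    pieces[2L * seq_len(k)] <- vapply(cys, `[[`, character(1), "seq")
    pieces <- c(pieces, fillers[(k + 1L):n_fill])
    seqs[[i]] <- paste(pieces, collapse = "")

    piece_starts <- cumsum(c(1L, nchar(pieces)))
    site_residue <- integer(k)
    forms_seq <- vector("list", k)
    forms_off <- vector("list", k)
    forms_site <- vector("list", k)
    for (s in seq_len(k)) {
      cys_piece <- 2L * s  # position of the site peptide among pieces
      site_residue[[s]] <- piece_starts[[cys_piece]] + cys[[s]]$c_pos - 1L
      n_forms <- 1L + rbinom(1L, 2L, q)
      fs <- cys[[s]]$seq
      fo <- cys[[s]]$c_pos
      if (n_forms >= 2L) {
        fs <- c(fs, paste0(pieces[[cys_piece - 1L]], cys[[s]]$seq))
        fo <- c(fo, nchar(pieces[[cys_piece - 1L]]) + cys[[s]]$c_pos)
      }
      if (n_forms >= 3L) {
        fs <- c(fs, paste0(cys[[s]]$seq, pieces[[cys_piece + 1L]]))
        fo <- c(fo, cys[[s]]$c_pos)
      }
      forms_seq[[s]] <- fs
      forms_off[[s]] <- fo
      forms_site[[s]] <- rep(s, length(fs))
    }
    site_acc[[i]] <- rep(accs[[i]], k)
    site_res[[i]] <- site_residue
    fseq <- unlist(forms_seq); foff <- unlist(forms_off)
    fsite <- unlist(forms_site)
    enr_acc[[i]] <- rep(accs[[i]], length(fseq))
    enr_seq[[i]] <- fseq
    enr_off[[i]] <- foff
    enr_res[[i]] <- site_residue[fsite]
    un_acc[[i]] <- rep(accs[[i]], n_fill)
    un_seq[[i]] <- fillers
  }
  database <- protein_db(setNames(seqs, accs))
  site_acc <- unlist(site_acc); site_res <- unlist(site_res)
  sites <- tibble(accession = site_acc, residue = site_res,
                  site_id = paste0(site_acc, "_C", site_res))
  enr_acc <- unlist(enr_acc); enr_res <- unlist(enr_res)
  enriched <- tibble(accession = enr_acc, sequence = unlist(enr_seq),
                     offsets = as.character(unlist(enr_off)),
                     site_id = paste0(enr_acc, "_C", enr_res))
  unenriched <- tibble(accession = unlist(un_acc), sequence = unlist(un_seq),
                       offsets = "")

  non_ref <- setdiff(config$conditions, config$reference_condition)

  # expression effects
  n_expr <- round(config$planted_expression$fraction * n)
  expr_prot <- sample(accs, n_expr)
  expression <- tibble(
    accession = expr_prot,
    condition = sample(non_ref, n_expr, replace = TRUE),
    effect_log2 = sample(c(-1, 1), n_expr, replace = TRUE) *
      config$planted_expression$effect_log2
  )

  # reactivity effects: on proteins without expression effects
  eligible_sites <- sites[!sites$accession %in% expr_prot, ]
  n_react <- min(round(config$planted_reactivity$fraction * nrow(sites)),
                 nrow(eligible_sites))
  react_idx <- sample(nrow(eligible_sites), n_react)
  reactivity <- tibble(
    site_id = eligible_sites$site_id[react_idx],
    accession = eligible_sites$accession[react_idx],
    condition = sample(non_ref, n_react, replace = TRUE),
    effect_log2 = sample(c(-1, 1), n_react, replace = TRUE) *
      config$planted_reactivity$effect_log2
  )

  # ATP-occluded sites
  n_atp <- round(config$planted_atp$fraction * nrow(sites))
  atp_idx <- sample(nrow(sites), n_atp)
  atp <- tibble(
    site_id = sites$site_id[atp_idx],
    accession = sites$accession[atp_idx],
    state = if (isTRUE(config$planted_atp$state_specific)) {
      rep(config$atp_specific_state, n_atp)
    } else {
      rep(NA_character_, n_atp)
    },
    effect_log2 = rep(config$planted_atp$effect_log2, n_atp)
  )

  # annotation classes; nucleotide binding linked to ATP occlusion by odds
  occluded_prot <- accs %in% atp$accession
  p0 <- config$class_base_rates[["nucleotide_binding"]]
  odds <- config$atp_class_odds
  p1 <- odds * p0 / (1 - p0 + odds * p0)
  nb <- runif(n) < ifelse(occluded_prot, p1, p0)
  mito <- runif(n) < config$class_base_rates[["mitochondrial"]]
  annotations <- annotation_set(list(
    mitochondrial = accs[mito],
    nucleotide_binding = accs[nb]
  ))

  truth <- structure(list(
    expression = expression,
    reactivity = reactivity,
    atp = atp,
    sites = sites[, c("site_id", "accession", "residue")],
    proteins = tibble(accession = accs),
    conditions = config$conditions,
    reference_condition = config$reference_condition,
    atp_states = config$atp_states
  ), class = "ground_truth")

  structure(list(
    database = database, annotations = annotations, truth = truth,
    enriched_peptides = enriched, unenriched_peptides = unenriched
  ), class = "sim_proteome")
}

# intensity-dependent (logistic in log2 intensity) or MCAR missingness,
# scaled so the expected missing fraction equals `rate`; guarantees every
# record keeps at least one observed channel.
apply_missingness <- function(records, log2_int, rate, mode) {
  if (rate <= 0) return(records)
  if (mode == "intensity") {
    w <- plogis((median(log2_int) - log2_int) / 1.5)
    p <- pmin(rate * w / mean(w), 0.999)
  } else {
    p <- rep(rate, length(log2_int))
  }
  miss <- runif(length(p)) < p
  records$intensity[miss] <- NA_real_
  # never silence a record completely
  key <- paste(records$plex_id, records$accession, records$sequence,
               records$offsets, sep = "\r")
  obs_per_rec <- tapply(!is.na(records$intensity), key, any)
  dead <- names(obs_per_rec)[!obs_per_rec]
  if (length(dead) > 0) {
    for (kd in dead) {
      idx <- which(key == kd)
      revive <- idx[which.max(log2_int[idx])]
      records$intensity[revive] <- 2^log2_int[revive]
    }
  }
  records
}

effect_lookup <- function(rows, ids, conditions, id_col, cond_col = "condition") {
  m <- matrix(0, length(ids), length(conditions),
              dimnames = list(ids, conditions))
  if (nrow(rows) > 0) {
    keep <- !is.na(rows[[cond_col]])
    m[cbind(match(rows[[id_col]][keep], ids),
            match(rows[[cond_col]][keep], conditions))] <-
      rows$effect_log2[keep]
  }
  m
}

#' Simulate the multi-plex enriched + unenriched TMT experiment
#'
#' One plex per donor, every condition in every plex. Intensity model (log2
#' scale): protein base + peptide ionization offset + condition abundance
#' offset + (for enriched peptides) site reactivity base and condition
#' offset + per-(protein, condition, donor) biological offset + Normal
#' measurement noise. Missingness is applied after noise.
#'
#' @param config A [simulation_config()].
#' @param proteome Output of [simulate_proteome()].
#' @return List: `enriched`, `unenriched` (both `peptide_quant`), `layout`
#'   (a `plex_layout`).
#' @export
simulate_experiment <- function(config, proteome) {
  set.seed(config$seed + 1L)
  conds <- config$conditions
  cpc <- config$channels_per_condition
  n_chan <- length(conds) * cpc
  if (n_chan > length(TMT10_CHANNELS)) {
    labels <- paste0("ch", seq_len(n_chan))
  } else {
    labels <- TMT10_CHANNELS[seq_len(n_chan)]
  }
  layout <- plex_layout(bind_rows(lapply(seq_len(config$n_donors), function(d) {
    tibble(plex_id = paste0("donor", d), channel = labels,
           condition = rep(conds, each = cpc),
           replicate = rep(seq_len(cpc), times = length(conds)),
           treatment = "none")
  })), reference_condition = config$reference_condition)

  truth <- proteome$truth
  accs <- truth$proteins$accession
  site_ids <- truth$sites$site_id
  e_mat <- effect_lookup(truth$expression, accs, conds, "accession")
  r_mat <- effect_lookup(truth$reactivity, site_ids, conds, "site_id")
  donor_eff <- array(
    rnorm(length(accs) * length(conds) * config$n_donors, 0,
          config$donor_sd_log2),
    dim = c(length(accs), length(conds), config$n_donors)
  )
  base_prot <- setNames(rnorm(length(accs), 16, 1.5), accs)

  ch <- as_tibble(layout)
  ch$donor_idx <- as.integer(sub("donor", "", ch$plex_id))
  ch$cond_idx <- match(ch$condition, conds)

  build <- function(peptides, enriched) {
    npe <- nrow(peptides)
    nch <- nrow(ch)
    i <- rep(seq_len(npe), times = nch)
    j <- rep(seq_len(nch), each = npe)
    pep_off <- rnorm(npe, 0, 1)
    prot_idx <- match(peptides$accession, accs)
    log2_i <- base_prot[prot_idx[i]] + pep_off[i] +
      e_mat[cbind(prot_idx[i], ch$cond_idx[j])] +
      donor_eff[cbind(prot_idx[i], ch$cond_idx[j], ch$donor_idx[j])]
    if (enriched) {
      site_idx <- match(peptides$site_id, site_ids)
      site_base <- rnorm(length(site_ids), 0, 0.5)
      log2_i <- log2_i + site_base[site_idx[i]] +
        r_mat[cbind(site_idx[i], ch$cond_idx[j])]
    }
    if (config$noise_sd_log2 > 0) {
      log2_i <- log2_i + rnorm(length(log2_i), 0, config$noise_sd_log2)
    }
    rec <- tibble(
      plex_id = ch$plex_id[j],
      accession = peptides$accession[i],
      sequence = peptides$sequence[i],
      offsets = peptides$offsets[i],
      channel = ch$channel[j],
      intensity = 2^log2_i
    )
    rec <- apply_missingness(rec, log2_i, config$missing_rate,
                             config$missing_mode)
    peptide_quant(rec, enriched = enriched)
  }

  enriched <- build(proteome$enriched_peptides, TRUE)
  unenriched <- build(proteome$unenriched_peptides, FALSE)
  list(enriched = enriched, unenriched = unenriched, layout = layout)
}

#' Simulate the ATP add-back experiment
#'
#' A 16-channel plex per add-back donor covering the configured states in
#' paired control / +ATP arms. ATP-occluded sites receive their (negative)
#' occlusion offset in treated channels only — in every state, or only in
#' the configured state when the occlusion is state-specific.
#'
#' @param config A [simulation_config()].
#' @param proteome Output of [simulate_proteome()].
#' @return List: `enriched` (a `peptide_quant`), `layout` (a
#'   `plex_layout`).
#' @export
simulate_atp_addback <- function(config, proteome) {
  set.seed(config$seed + 2L)
  states <- config$atp_states
  reps <- config$addback_replicates[states]
  n_chan <- 2L * sum(reps)
  if (n_chan > length(TMT16_CHANNELS)) {
    labels <- paste0("ch", seq_len(n_chan))
  } else {
    labels <- TMT16_CHANNELS[seq_len(n_chan)]
  }
  one_plex <- bind_rows(lapply(states, function(st) {
    tibble(condition = st,
           replicate = rep(seq_len(reps[[st]]), times = 2L),
           treatment = rep(c("none", "ATP"), each = reps[[st]]))
  }))
  layout <- plex_layout(bind_rows(lapply(seq_len(config$n_addback_donors),
    function(d) {
      tibble(plex_id = paste0("ab_donor", d), channel = labels,
             condition = one_plex$condition, replicate = one_plex$replicate,
             treatment = one_plex$treatment)
    })), reference_condition = config$reference_condition)

  truth <- proteome$truth
  accs <- truth$proteins$accession
  site_ids <- truth$sites$site_id
  conds <- config$conditions
  e_mat <- effect_lookup(truth$expression, accs, conds, "accession")
  r_mat <- effect_lookup(truth$reactivity, site_ids, conds, "site_id")
  o_mat <- matrix(0, length(site_ids), length(states),
                  dimnames = list(site_ids, states))
  if (nrow(truth$atp) > 0) {
    for (rix in seq_len(nrow(truth$atp))) {
      row <- truth$atp[rix, ]
      st <- if (is.na(row$state)) states else row$state
      o_mat[row$site_id, st] <- row$effect_log2
    }
  }

  peptides <- proteome$enriched_peptides
  npe <- nrow(peptides)
  base_prot <- setNames(rnorm(length(accs), 16, 1.5), accs)
  pep_off <- rnorm(npe, 0, 1)
  site_base <- rnorm(length(site_ids), 0, 0.5)
  donor_eff <- array(
    rnorm(length(accs) * length(states) * config$n_addback_donors, 0,
          config$donor_sd_log2),
    dim = c(length(accs), length(states), config$n_addback_donors)
  )

  ch <- as_tibble(layout)
  ch$donor_idx <- as.integer(sub("ab_donor", "", ch$plex_id))
  ch$state_idx <- match(ch$condition, states)
  ch$cond_idx <- match(ch$condition, conds)
  nch <- nrow(ch)
  i <- rep(seq_len(npe), times = nch)
  j <- rep(seq_len(nch), each = npe)
  prot_idx <- match(peptides$accession, accs)
  site_idx <- match(peptides$site_id, site_ids)
  log2_i <- base_prot[prot_idx[i]] + pep_off[i] + site_base[site_idx[i]] +
    e_mat[cbind(prot_idx[i], ch$cond_idx[j])] +
    r_mat[cbind(site_idx[i], ch$cond_idx[j])] +
    o_mat[cbind(site_idx[i], ch$state_idx[j])] *
      (ch$treatment[j] == "ATP") +
    donor_eff[cbind(prot_idx[i], ch$state_idx[j], ch$donor_idx[j])]
  if (config$noise_sd_log2 > 0) {
    log2_i <- log2_i + rnorm(length(log2_i), 0, config$noise_sd_log2)
  }
  rec <- tibble(
    plex_id = ch$plex_id[j],
    accession = peptides$accession[i],
    sequence = peptides$sequence[i],
    offsets = peptides$offsets[i],
    channel = ch$channel[j],
    intensity = 2^log2_i
  )
  rec <- apply_missingness(rec, log2_i, config$missing_rate,
                           config$missing_mode)
  list(enriched = peptide_quant(rec, enriched = TRUE), layout = layout)
}

#' Simulate a metabolite/lipid feature table with cell metadata
#'
#' Planted fold changes are defined on the *per-volume* abundance scale;
#' measured intensities are per-volume abundance times sampled biovolume
#' (cell count x mean cell volume), so cell-volume normalization is
#' required to recover the planted effects.
#'
#' @param config A [simulation_config()].
#' @return List: `table` (a `feature_table`), `truth` (tibble
#'   `feature_id`, `condition`, `effect_log2`).
#' @export
simulate_feature_table <- function(config) {
  set.seed(config$seed + 3L)
  conds <- config$metab_conditions
  nd <- config$n_metab_donors
  nf <- config$n_metabolites
  feature_ids <- sprintf("M%04d", seq_len(nf))
  samples <- tibble(
    sample_id = paste(rep(conds, each = nd), rep(seq_len(nd), length(conds)),
                      sep = "_"),
    condition = rep(conds, each = nd),
    donor = rep(seq_len(nd), length(conds)),
    cell_count = round(rnorm(length(conds) * nd, config$cell_count_mean,
                             config$cell_count_mean * 0.05)),
    mean_cell_volume = config$cell_volumes[rep(conds, each = nd)] *
      rnorm(length(conds) * nd, 1, 0.02)
  )
  non_ref <- setdiff(conds, config$reference_condition)
  n_eff <- round(config$planted_metab$fraction * nf)
  eff_feat <- sample(feature_ids, n_eff)
  truth <- tibble(
    feature_id = eff_feat,
    condition = sample(non_ref, n_eff, replace = TRUE),
    effect_log2 = sample(c(-1, 1), n_eff, replace = TRUE) *
      config$planted_metab$effect_log2
  )
  e_mat <- effect_lookup(truth, feature_ids, conds, "feature_id")
  base <- rnorm(nf, 10, 1.5)
  ns <- nrow(samples)
  log2_pv <- matrix(base, nf, ns) +
    e_mat[, match(samples$condition, conds)] +
    matrix(rnorm(nf * ns, 0, config$metab_noise_sd), nf, ns)
  values <- 2^log2_pv *
    matrix(samples$cell_count * samples$mean_cell_volume, nf, ns,
           byrow = TRUE)
  if (config$metab_missing_rate > 0) {
    miss <- matrix(runif(nf * ns) < config$metab_missing_rate, nf, ns)
    values[miss] <- NA_real_
  }
  dimnames(values) <- list(feature_ids, samples$sample_id)
  list(table = feature_table(values, samples), truth = truth)
}

#' Simulate isotope-tracing isotopologue data
#'
#' True mass isotopologue distributions (a condition-dependent m+2-labeled
#' fraction, emulating reduced oxidative TCA-cycle labeling in the
#' chronically stimulated state) are forward-convolved with the binomial
#' natural-abundance matrix, noised, and scaled to intensities.
#'
#' @param config A [simulation_config()].
#' @param labeled_fraction Named per-condition true m+2 labeled fraction.
#' @param frac_noise_sd SD of Normal noise on observed fractions.
#' @return List: `observed` (tibble `metabolite`, `condition`, `donor`,
#'   `mass_shift`, `intensity`), `true_mids` (same keys with `fraction`),
#'   `carbons` (named integer vector), `p_nat`.
#' @export
simulate_tracing <- function(config,
                             labeled_fraction = c(D2 = 0.45, D8A = 0.40,
                                                  D8C = 0.20),
                             frac_noise_sd = 0.005) {
  set.seed(config$seed + 4L)
  carbons <- c(fumarate = 4L, malate = 4L, aspartate = 4L, citrate = 6L,
               succinate = 4L, oxoglutarate = 5L)
  conds <- intersect(names(labeled_fraction), config$metab_conditions)
  nd <- 3L
  obs <- list()
  tru <- list()
  for (met in names(carbons)) {
    nC <- carbons[[met]]
    m <- build_correction_matrix(nC, p_nat = config$tracer_p_nat)
    for (cond in conds) {
      for (d in seq_len(nd)) {
        lf <- min(1, max(0, labeled_fraction[[cond]] * rnorm(1, 1, 0.05)))
        mid <- numeric(nC + 1L)
        mid[1L] <- 1 - lf
        mid[3L] <- lf
        observed_frac <- as.numeric(m %*% mid) +
          rnorm(nC + 1L, 0, frac_noise_sd)
        observed_frac <- pmax(observed_frac, 0)
        total <- 2^rnorm(1, 20, 0.5)
        obs[[length(obs) + 1L]] <- tibble(
          metabolite = met, condition = cond, donor = d,
          mass_shift = 0:nC, intensity = observed_frac * total
        )
        tru[[length(tru) + 1L]] <- tibble(
          metabolite = met, condition = cond, donor = d,
          mass_shift = 0:nC, fraction = mid
        )
      }
    }
  }
  list(observed = bind_rows(obs), true_mids = bind_rows(tru),
       carbons = carbons, p_nat = config$tracer_p_nat)
}

#' Write / read a ground-truth file
#'
#' Long tab-separated format holding every planted effect plus the full
#' site and protein universes, sufficient to score any downstream call set
#' without access to the simulator state.
#'
#' @param truth A `ground_truth` list.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  rows <- bind_rows(
    tibble(type = "expression", accession = truth$expression$accession,
           site_id = NA_character_, condition = truth$expression$condition,
           effect_log2 = truth$expression$effect_log2,
           residue = NA_integer_),
    tibble(type = "reactivity", accession = truth$reactivity$accession,
           site_id = truth$reactivity$site_id,
           condition = truth$reactivity$condition,
           effect_log2 = truth$reactivity$effect_log2,
           residue = NA_integer_),
    tibble(type = "atp", accession = truth$atp$accession,
           site_id = truth$atp$site_id, condition = truth$atp$state,
           effect_log2 = truth$atp$effect_log2, residue = NA_integer_),
    tibble(type = "site", accession = truth$sites$accession,
           site_id = truth$sites$site_id, condition = NA_character_,
           effect_log2 = NA_real_, residue = truth$sites$residue),
    tibble(type = "protein", accession = truth$proteins$accession,
           site_id = NA_character_, condition = NA_character_,
           effect_log2 = NA_real_, residue = NA_integer_)
  )
  header <- tibble(type = "meta",
                   accession = paste(truth$conditions, collapse = ";"),
                   site_id = paste(truth$atp_states, collapse = ";"),
                   condition = truth$reference_condition,
                   effect_log2 = NA_real_, residue = NA_integer_)
  write_table(bind_rows(header, rows), path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tab <- read_table(path)
  meta <- tab[tab$type == "meta", ]
  pick <- function(ty) tab[tab$type == ty, ]
  structure(list(
    expression = pick("expression")[, c("accession", "condition",
                                        "effect_log2")],
    reactivity = pick("reactivity")[, c("site_id", "accession", "condition",
                                        "effect_log2")],
    atp = tibble(site_id = pick("atp")$site_id,
                 accession = pick("atp")$accession,
                 state = pick("atp")$condition,
                 effect_log2 = pick("atp")$effect_log2),
    sites = pick("site")[, c("site_id", "accession", "residue")],
    proteins = pick("protein")[, "accession"],
    conditions = strsplit(meta$accession, ";")[[1]],
    reference_condition = meta$condition,
    atp_states = strsplit(meta$site_id, ";")[[1]]
  ), class = "ground_truth")
}
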