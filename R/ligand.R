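# ATP add-back ligand sensitivity, the cross-state differential-sensitivity
# rule, and covalent-inhibitor engagement by competition.

#' Call ATP (or other ligand) sensitivity from an add-back experiment
#'
#' Within each plex and state, treated and control channels are paired by
#' replicate index and the per-record delta is the median over pairs of
#' `log2(treated / control)`. Pairing the arms inside a plex removes
#' channel loading effects, since the add-back is a paired lysate-level
#' perturbation. Record deltas are rolled up to sites (median over
#' peptides) and then aggregated across plexes/donors by the median.
#' Decreased probe labeling upon ATP (`direction = "decreased"`) indicates
#' nucleotide-proximal occlusion.
#'
#' @param records Enriched `peptide_quant` records from the add-back
#'   experiment.
#' @param layout The add-back `plex_layout`; each state must carry both a
#'   `"none"` and a treated arm. States missing one arm are skipped with a
#'   warning.
#' @param database A `protein_db` for site assignment.
#' @param threshold Fold-change gate on `|delta|` (default 2).
#' @param treatment Treated-arm label (default `"ATP"`).
#' @param normalize Normalize channels first (default `TRUE`).
#' @return Tibble of class `ligand_calls`: `site_id`, `accession`,
#'   `residue`, `composite`, `state`, `delta_log2`, `sensitive`,
#'   `direction`, `n_peptides`, `n_donors_observed`.
#' @export
call_ligand_sensitivity <- function(records, layout, database, threshold = 2,
                                    treatment = "ATP", normalize = TRUE) {
  if (normalize) records <- normalize_channels(records, layout)
  lay <- as_tibble(layout)[, c("plex_id", "channel", "condition",
                               "replicate", "treatment")]
  arms <- lay %>%
    distinct(.data$condition, .data$treatment) %>%
    count(.data$condition) %>%
    filter(.data$n < 2L)
  if (nrow(arms) > 0) {
    warn(paste0("state(s) missing a control or treated arm, skipped: ",
                paste(arms$condition, collapse = ", ")))
    lay <- lay[!lay$condition %in% arms$condition, ]
  }
  x <- inner_join(as_tibble(records), lay, by = c("plex_id", "channel"))
  x <- x[!is.na(x$intensity), ]
  ctrl <- x %>%
    filter(.data$treatment == "none") %>%
    select(all_of(record_key), "condition", "replicate",
           ctrl_intensity = "intensity")
  trt <- x %>%
    filter(.data$treatment == !!treatment) %>%
    select(all_of(record_key), "condition", "replicate",
           trt_intensity = "intensity")
  pairs <- inner_join(ctrl, trt,
                      by = c(record_key, "condition", "replicate"))
  if (nrow(pairs) == 0L) abort("no paired control/treated observations")
  rec_delta <- pairs %>%
    mutate(pair_delta = log2(.data$trt_intensity / .data$ctrl_intensity)) %>%
    group_by(across(all_of(c(record_key, "condition")))) %>%
    summarise(delta = median(.data$pair_delta), .groups = "drop")

  sites <- map_peptides_to_sites(rec_delta, database)
  y <- inner_join(rec_delta, sites, by = c("accession", "sequence", "offsets"))
  site_plex <- y %>%
    group_by(.data$site_id, .data$accession, .data$residue, .data$composite,
             .data$condition, .data$plex_id) %>%
    summarise(delta = median(.data$delta), .groups = "drop")
  out <- site_plex %>%
    group_by(.data$site_id, .data$accession, .data$residue, .data$composite,
             state = .data$condition) %>%
    summarise(delta_log2 = median(.data$delta),
              n_donors_observed = n_distinct(.data$plex_id),
              .groups = "drop")
  n_pep <- y %>%
    group_by(.data$site_id) %>%
    summarise(n_peptides = n_distinct(.data$sequence), .groups = "drop")
  out <- inner_join(out, n_pep, by = "site_id") %>%
    mutate(
      sensitive = abs(.data$delta_log2) >= log2(threshold),
      direction = ifelse(.data$delta_log2 < 0, "decreased", "increased")
    )
  structure(out, threshold = threshold,
            class = unique(c("ligand_calls", class(out))))
}

#' Cross-state differential ligand sensitivity
#'
#' Flags sites whose ligand response differs between two states by more
#' than `threshold`-fold, i.e. `|delta_X - delta_Y| >= log2(threshold)` —
#' algebraically the "ratio of fold changes between the states exceeds the
#' threshold" rule. Exchanging the states flips the sign of the difference
#' but never the flag.
#'
#' @param calls A `ligand_calls` tibble covering both states.
#' @param state_x,state_y States to contrast (defaults `"D8C"` vs `"D2"`).
#' @param threshold Fold-change gate on the delta difference (default 2).
#' @return Tibble: `site_id`, `accession`, `delta_x`, `delta_y`,
#'   `cross_state_delta`, `flagged`.
#' @export
cross_state_sensitivity <- function(calls, state_x = "D8C", state_y = "D2",
                                    threshold = 2) {
  x <- as_tibble(calls)
  for (s in c(state_x, state_y)) {
    if (!s %in% x$state) abort(paste0("state absent from calls: ", s))
  }
  dx <- x %>%
    filter(.data$state == state_x) %>%
    select("site_id", "accession", delta_x = "delta_log2")
  dy <- x %>%
    filter(.data$state == state_y) %>%
    select("site_id", delta_y = "delta_log2")
  out <- inner_join(dx, dy, by = "site_id") %>%
    mutate(
      cross_state_delta = .data$delta_x - .data$delta_y,
      flagged = abs(.data$cross_state_delta) >= log2(threshold)
    )
  structure(out, state_x = state_x, state_y = state_y, threshold = threshold,
            class = unique(c("cross_state_calls", class(out))))
}

#' Covalent-inhibitor engagement by competition
#'
#' Pretreatment with a covalent ligand blocks probe labeling at engaged
#' sites; the engagement fraction is `1 - treated/control`, clamped to
#' [0, 1]. A site is called engaged when labeling drops at least
#' `threshold`-fold (`treated/control <= 1/threshold`).
#'
#' @param competition Data frame with columns `site_id`, `control`,
#'   `treated` (site-level signal in the two arms, linear scale).
#' @param threshold Fold-loss gate (default 2).
#' @return Tibble: `site_id`, `ratio`, `engagement`, `engaged`, `clamped`
#'   (`TRUE` when treated exceeded control and the fraction was clamped to
#'   0).
#' @export
engagement_by_competition <- function(competition, threshold = 2) {
  x <- as_tibble(competition)
  for (col in c("site_id", "control", "treated")) {
    if (!col %in% names(x)) {
      abort(paste0("competition table lacks column '", col, "'"))
    }
  }
  if (any(x$control <= 0, na.rm = TRUE)) {
    abort("control signal must be positive")
  }
  ratio <- x$treated / x$control
  tibble(
    site_id = x$site_id,
    ratio = ratio,
    engagement = pmin(1, pmax(0, 1 - ratio)),
    engaged = ratio <= 1 / threshold,
    clamped = ratio > 1
  )
}
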