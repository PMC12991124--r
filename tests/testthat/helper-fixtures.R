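# Fixture builders shared across test files. Everything is constructed in
# code; nothing binary is read from disk.

# Single-plex layout: conditions x replicates, reference D2 included.
make_layout <- function(conditions = c("D2", "D8C"), reps = 2L,
                        plex = "donor1", treatments = "none",
                        reference = "D2") {
  plex_layout(tibble::tibble(
    plex_id = plex,
    channel = paste0("ch", seq_len(length(conditions) * reps *
                                     length(treatments))),
    condition = rep(conditions, each = reps * length(treatments)),
    replicate = rep(rep(seq_len(reps), each = length(treatments)),
                    times = length(conditions)),
    treatment = rep(treatments, times = length(conditions) * reps)
  ), reference_condition = reference)
}

# Long-format records from a wide matrix: rows = records, cols = channels.
make_records <- function(mat, accession, sequence, offsets = "",
                         plex = "donor1", enriched = FALSE) {
  channels <- colnames(mat)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    tibble::tibble(
      plex_id = plex,
      accession = accession[[i]],
      sequence = sequence[[i]],
      offsets = if (length(offsets) == 1L) offsets else offsets[[i]],
      channel = channels,
      intensity = unname(mat[i, ])
    )
  })
  peptide_quant(dplyr::bind_rows(rows), enriched = enriched)
}

# Hand-built site_quant with the attribute call_reactivity() consumes.
make_site_quant <- function(df, cys_peptides = NULL) {
  df <- tibble::as_tibble(df)
  if (!"composite" %in% names(df)) df$composite <- FALSE
  if (!"residue" %in% names(df)) df$residue <- NA_integer_
  if (!"n_peptides" %in% names(df)) df$n_peptides <- 1L
  if (is.null(cys_peptides)) {
    cys_peptides <- df %>%
      dplyr::distinct(accession, site_id) %>%
      dplyr::count(accession, name = "n_cys_peptides")
  }
  structure(df, cys_peptides = cys_peptides,
            class = unique(c("site_quant", class(df))))
}

make_protein_quant <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"n_peptides" %in% names(df)) df$n_peptides <- 1L
  structure(df, class = unique(c("protein_quant", class(df))))
}

# Independent, deliberately literal re-implementation of the calling rule
# (plain loops), used as the oracle for call_reactivity().
reference_reactivity_calls <- function(sites, proteins, fc = 2,
                                       min_pep = 2L, reference = "D2") {
  lfc <- log2(fc)
  sites <- sites[!sites$composite, ]
  cysp <- attr(sites, "cys_peptides")
  conds <- setdiff(unique(sites$condition), reference)
  out <- list()
  for (sid in unique(sites$site_id)) {
    sb <- sites[sites$site_id == sid, ]
    acc <- sb$accession[[1]]
    for (cond in conds) {
      v <- sb$log2_ratio[sb$condition == cond]
      if (length(v) == 0L) next
      raw <- median(v)
      pb <- proteins[proteins$accession == acc &
                       proteins$condition == cond, ]
      prot_fc <- if (nrow(pb) > 0) median(pb$log2_ratio) else NA_real_
      others <- sites[sites$accession == acc & sites$condition == cond &
                        sites$site_id != sid, ]
      oth <- vapply(split(others$log2_ratio, others$site_id), median,
                    numeric(1))
      loo <- if (length(oth) >= 2L) median(oth) else NA_real_
      baseline <- if (!is.na(prot_fc)) prot_fc else loo
      ncys <- cysp$n_cys_peptides[cysp$accession == acc]
      if (length(ncys) == 0L) ncys <- 1L
      tier <- if (ncys >= min_pep) {
        "multi_peptide"
      } else if (!is.na(prot_fc)) {
        "single_peptide_with_proteome"
      } else {
        NA_character_
      }
      verdict <- if (is.na(tier) || is.na(baseline)) {
        "insufficient_evidence"
      } else if (abs(raw) < lfc) {
        "no_change"
      } else if (abs(raw - baseline) >= lfc) {
        "reactivity_change"
      } else {
        "expression_coupled"
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        site_id = sid, condition = cond, raw_log2fc = raw,
        verdict = verdict,
        direction = if (raw >= 0) "higher" else "lower",
        evidence_tier = tier
      )
    }
  }
  dplyr::bind_rows(out)
}

# Small simulation config with quiet defaults overridable per test.
quick_config <- function(..., seed) {
  args <- utils::modifyList(list(n_proteins = 60L, n_donors = 3L,
                                 seed = seed),
                            list(...))
  do.call(simulation_config, args)
}
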