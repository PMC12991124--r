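# Channel normalization, condition-vs-reference ratios, and rollup of
# peptides to cysteine sites and proteins.

record_key <- c("plex_id", "accession", "sequence", "offsets")

#' Normalize reporter channels within each plex
#'
#' Rescales every channel of a plex by a single factor so that the channel
#' totals agree, emulating equal protein content per sample. Totals are
#' computed over complete-case records only (records observed in every
#' channel of the plex), so that missing values cannot bias the column
#' sums; the factors are then applied to all records.
#'
#' @param records A `peptide_quant` tibble.
#' @param layout The matching `plex_layout`.
#' @return The rescaled records, with a `norm_factors` attribute (tibble
#'   `plex_id`, `channel`, `factor`).
#' @export
normalize_channels <- function(records, layout) {
  out <- records
  factor_tabs <- list()
  for (px in unique(layout$plex_id)) {
    channels <- layout$channel[layout$plex_id == px]
    sub <- records[records$plex_id == px, ]
    if (nrow(sub) == 0L) abort(paste0("no records for plex ", px))
    obs <- sub %>%
      filter(.data$channel %in% channels) %>%
      group_by(across(all_of(record_key))) %>%
      summarise(n_obs = sum(!is.na(.data$intensity)), .groups = "drop") %>%
      filter(.data$n_obs == length(channels))
    if (nrow(obs) == 0L) {
      abort(paste0("plex ", px,
                   " has no complete-case record for normalization"))
    }
    totals <- sub %>%
      semi_join(obs, by = record_key) %>%
      group_by(.data$channel) %>%
      summarise(total = sum(.data$intensity), .groups = "drop")
    totals <- totals[match(channels, totals$channel), ]
    if (any(is.na(totals$total)) || any(totals$total == 0)) {
      bad <- channels[is.na(totals$total) | totals$total == 0]
      abort(paste0("zero total intensity in channel(s) ",
                   paste(bad, collapse = ", "), " of plex ", px))
    }
    f <- mean(totals$total) / totals$total
    idx <- out$plex_id == px
    out$intensity[idx] <- out$intensity[idx] *
      f[match(out$channel[idx], channels)]
    factor_tabs[[px]] <- tibble(plex_id = px, channel = channels, factor = f)
  }
  attr(out, "norm_factors") <- bind_rows(factor_tabs)
  attr(out, "enriched") <- attr(records, "enriched")
  out
}

#' Per-record condition-vs-reference log2 ratios
#'
#' For each record, the reference value is the geometric mean of its
#' observed reference-condition channels (arithmetic mean in log2 space);
#' each channel then yields a log2 ratio against that value, and the
#' condition ratio is the median over that condition's channels. Records
#' with no observed reference channel are dropped (counted in the
#' `dropped_records` attribute). Only untreated (`treatment == "none"`)
#' channels participate; treated arms are handled by the
#' ligand-sensitivity functions.
#'
#' @param records Normalized `peptide_quant` records.
#' @param layout The matching `plex_layout`.
#' @return Tibble with one row per (record, condition):
#'   `plex_id`, `accession`, `sequence`, `offsets`, `condition`,
#'   `log2_ratio`. `plex_id` doubles as the donor identifier (one plex per
#'   donor).
#' @export
condition_ratios <- function(records, layout) {
  ref <- layout_reference(layout)
  lay <- as_tibble(layout)[, c("plex_id", "channel", "condition", "treatment")]
  x <- inner_join(as_tibble(records), lay, by = c("plex_id", "channel"))
  x <- x[x$treatment == "none" & !is.na(x$intensity), ]
  n_records <- nrow(distinct(x[, record_key]))
  x$log2_int <- log2(x$intensity)

  refs <- x %>%
    filter(.data$condition == ref) %>%
    group_by(across(all_of(record_key))) %>%
    summarise(ref_log2 = mean(.data$log2_int), .groups = "drop")
  x <- inner_join(x, refs, by = record_key)
  dropped <- n_records - nrow(distinct(x[, record_key]))

  out <- x %>%
    mutate(chan_ratio = .data$log2_int - .data$ref_log2) %>%
    group_by(across(all_of(c(record_key, "condition")))) %>%
    summarise(log2_ratio = median(.data$chan_ratio), .groups = "drop")
  attr(out, "dropped_records") <- dropped
  attr(out, "enriched") <- attr(records, "enriched")
  out
}

# Locate each distinct (accession, sequence, offsets) peptide in the
# database, resolving repeated matches by first exact occurrence, and
# assign 1-based protein residue numbers and site identifiers.
map_peptides_to_sites <- function(peptides, database) {
  peptides <- distinct(peptides[, c("accession", "sequence", "offsets")])
  missing_acc <- setdiff(unique(peptides$accession), names(database))
  if (length(missing_acc) > 0) {
    abort(paste0("accession(s) absent from database: ",
                 paste(missing_acc, collapse = ", ")))
  }
  prot <- unclass(database)[peptides$accession]
  pos <- mapply(function(s, p) regexpr(p, s, fixed = TRUE)[[1]],
                prot, peptides$sequence, USE.NAMES = FALSE)
  if (any(pos < 0L)) {
    bad <- peptides$sequence[pos < 0L]
    abort(paste0("peptide(s) not found in their protein sequence: ",
                 paste(unique(bad), collapse = ", ")))
  }
  offs <- parse_offsets(peptides$offsets)
  n_sites <- lengths(offs)
  if (any(n_sites == 0L)) {
    abort("cannot roll up peptides without modified offsets")
  }
  residues <- mapply(function(p, o) p + o - 1L, pos, offs, SIMPLIFY = FALSE)
  for (i in seq_along(residues)) {
    res_aa <- substring(prot[[i]], residues[[i]], residues[[i]])
    if (any(res_aa != "C")) {
      abort(paste0("mapped residue is not a cysteine for peptide ",
                   peptides$sequence[[i]], " in ", peptides$accession[[i]]))
    }
  }
  peptides$site_id <- vapply(seq_len(nrow(peptides)), function(i) {
    paste0(peptides$accession[[i]], "_",
           paste0("C", residues[[i]], collapse = "_"))
  }, character(1))
  peptides$residue <- vapply(residues, function(r) {
    if (length(r) == 1L) r else NA_integer_
  }, integer(1))
  peptides$composite <- n_sites > 1L
  peptides
}

#' Roll peptide ratios up to cysteine sites
#'
#' Residue numbers are assigned by locating each peptide's first exact
#' occurrence in its protein sequence; site identifiers follow the
#' `ACCESSION_C<residue>` convention. The site value per (condition, donor)
#' is the median of the contributing peptide ratios. Peptides carrying more
#' than one modified cysteine map to a composite site id (joined residue
#' numbers, `composite = TRUE`) and are excluded from single-site calling
#' downstream.
#'
#' @param ratios Output of [condition_ratios()] on enriched records.
#' @param database A `protein_db`.
#' @return Tibble of class `site_quant`: `site_id`, `accession`, `residue`,
#'   `composite`, `condition`, `donor`, `log2_ratio`, `n_peptides` (distinct
#'   base sequences supporting the site). Attribute `cys_peptides` holds the
#'   per-protein count of distinct quantified cysteine peptides used for
#'   evidence tiers.
#' @export
rollup_sites <- function(ratios, database) {
  sites <- map_peptides_to_sites(ratios, database)
  x <- inner_join(as_tibble(ratios), sites,
                  by = c("accession", "sequence", "offsets"))
  out <- x %>%
    group_by(.data$site_id, .data$accession, .data$residue, .data$composite,
             .data$condition, donor = .data$plex_id) %>%
    summarise(log2_ratio = median(.data$log2_ratio), .groups = "drop")
  n_pep <- x %>%
    group_by(.data$site_id) %>%
    summarise(n_peptides = n_distinct(.data$sequence), .groups = "drop")
  out <- inner_join(out, n_pep, by = "site_id")
  cys_peptides <- sites %>%
    group_by(.data$accession) %>%
    summarise(n_cys_peptides = n_distinct(.data$sequence), .groups = "drop")
  structure(out, cys_peptides = cys_peptides,
            class = unique(c("site_quant", class(out))))
}

#' Roll unenriched peptide ratios up to proteins
#'
#' Protein value per (condition, donor) is the median of its peptide
#' ratios; order of input peptides is irrelevant.
#'
#' @param ratios Output of [condition_ratios()] on unenriched records.
#' @return Tibble of class `protein_quant`: `accession`, `condition`,
#'   `donor`, `log2_ratio`, `n_peptides`.
#' @export
rollup_proteins <- function(ratios) {
  x <- as_tibble(ratios)
  out <- x %>%
    group_by(.data$accession, .data$condition, donor = .data$plex_id) %>%
    summarise(log2_ratio = median(.data$log2_ratio), .groups = "drop")
  n_pep <- x %>%
    group_by(.data$accession) %>%
    summarise(n_peptides = n_distinct(.data$sequence), .groups = "drop")
  out <- inner_join(out, n_pep, by = "accession")
  structure(out, class = unique(c("protein_quant", class(out))))
}

#' Intersect two site quantification sets
#'
#' Inner join on `site_id`, reporting how many sites are exclusive to each
#' set — the "only cysteines quantified in both datasets" filter used when
#' comparing two experiments.
#'
#' @param a,b `site_quant` tibbles (or any data frames with a `site_id`
#'   column).
#' @return List with elements `both` (inner join, suffixes `_a`/`_b` on
#'   shared value columns) and `counts` (`n_a`, `n_b`, `n_both`,
#'   `n_a_only`, `n_b_only`).
#' @export
intersect_sites <- function(a, b) {
  ids_a <- unique(a$site_id)
  ids_b <- unique(b$site_id)
  shared <- intersect(ids_a, ids_b)
  both <- inner_join(
    as_tibble(a)[a$site_id %in% shared, ],
    as_tibble(b)[b$site_id %in% shared, ],
    by = intersect(
      intersect(names(a), names(b)),
      c("site_id", "accession", "residue", "composite", "condition", "donor",
        "state")
    ),
    suffix = c("_a", "_b")
  )
  list(
    both = both,
    counts = tibble(
      n_a = length(ids_a), n_b = length(ids_b),
      n_both = length(shared),
      n_a_only = length(setdiff(ids_a, ids_b)),
      n_b_only = length(setdiff(ids_b, ids_a))
    )
  )
}
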