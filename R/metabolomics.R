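# Cell-volume-normalized metabolomics and stable-isotope tracing:
# natural-abundance correction and isotopologue fractions.

#' Construct a metabolite/lipid feature table
#'
#' @param values Numeric matrix, features x samples, rownames = feature
#'   ids, colnames = sample ids; nonnegative intensities, `NA` = missing.
#' @param samples Data frame with one row per sample: `sample_id`,
#'   `condition`, `donor`, `cell_count`, `mean_cell_volume` (fL).
#' @return List of class `feature_table` with elements `values`, `samples`.
#' @export
feature_table <- function(values, samples) {
  samples <- as_tibble(samples)
  required <- c("sample_id", "condition", "donor", "cell_count",
                "mean_cell_volume")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("sample metadata missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!identical(colnames(values), samples$sample_id)) {
    abort("colnames(values) must equal samples$sample_id, in order")
  }
  if (any(values < 0, na.rm = TRUE)) abort("intensities must be nonnegative")
  structure(list(values = values, samples = samples),
            class = "feature_table")
}

#' Cell-volume normalization of a feature table
#'
#' Cells in different states differ in size, so raw per-sample intensities
#' are divided by the sampled biovolume: `cell_count * mean_cell_volume`
#' (units intensity per fL). Dividing by `mean_cell_volume` alone is
#' available for workflows whose intensities are already per cell.
#'
#' @param ft A `feature_table`.
#' @param mode `"biovolume"` (default) or `"volume"`.
#' @return The normalized `feature_table` (attribute `normalized` records
#'   the mode).
#' @export
normalize_cell_volume <- function(ft, mode = c("biovolume", "volume")) {
  mode <- match.arg(mode)
  s <- ft$samples
  bad <- is.na(s$cell_count) | is.na(s$mean_cell_volume)
  if (mode == "volume") bad <- is.na(s$mean_cell_volume)
  if (any(bad)) {
    abort(paste0("missing cell metadata for sample(s): ",
                 paste(s$sample_id[bad], collapse = ", ")))
  }
  if (any(s$cell_count <= 0) || any(s$mean_cell_volume <= 0)) {
    abort("cell_count and mean_cell_volume must be positive")
  }
  divisor <- switch(mode,
    biovolume = s$cell_count * s$mean_cell_volume,
    volume = s$mean_cell_volume
  )
  out <- ft
  out$values <- sweep(ft$values, 2, divisor, "/")
  attr(out, "normalized") <- mode
  out
}

#' Complete-case filter for a feature table
#'
#' Keeps only features quantified in all samples (all replicates), the
#' filter applied before multivariate analyses of metabolite and lipid
#' panels.
#'
#' @param ft A `feature_table`.
#' @return The filtered `feature_table`.
#' @export
filter_complete_features <- function(ft) {
  keep <- rowSums(is.na(ft$values)) == 0L
  out <- ft
  out$values <- ft$values[keep, , drop = FALSE]
  out
}

#' Natural-abundance correction matrix for carbon isotopologues
#'
#' Column `j` (0-based) is the mass-shift distribution of a molecule with
#' `j` tracer-labeled carbons: the tracer carbons contribute
#' `Binomial(j, tracer_purity)` heavy atoms and the remaining `n - j`
#' carbons contribute `Binomial(n - j, p_nat)` naturally occurring 13C.
#' Because only the molecule's own carbons shift its mass, every column
#' sums to exactly 1 (no truncation is needed). Carbon-only correction:
#' H/N/O isotopes and resolution effects are out of scope.
#'
#' @param n_carbons Number of carbons in the metabolite (>= 0).
#' @param p_nat Natural 13C abundance (default 0.0107).
#' @param tracer_purity Isotopic purity of the tracer (default 1.0).
#' @return `(n+1) x (n+1)` matrix; entry `(i, j)` is the probability that
#'   a molecule with `j - 1` labeled carbons is observed at mass shift
#'   `i - 1`.
#' @export
build_correction_matrix <- function(n_carbons, p_nat = 0.0107,
                                    tracer_purity = 1.0) {
  if (n_carbons < 0) abort("n_carbons must be >= 0")
  if (p_nat < 0 || p_nat > 1 || tracer_purity < 0 || tracer_purity > 1) {
    abort("p_nat and tracer_purity must lie in [0, 1]")
  }
  n <- as.integer(n_carbons)
  m <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    nat <- dbinom(0:(n - j), n - j, p_nat)
    lab <- dbinom(0:j, j, tracer_purity)
    col <- numeric(n + 1L)
    for (a in 0:j) {
      idx <- a + 0:(n - j) + 1L
      col[idx] <- col[idx] + lab[a + 1L] * nat
    }
    m[, j + 1L] <- col
  }
  dimnames(m) <- list(paste0("m", 0:n), paste0("x", 0:n))
  attr(m, "p_nat") <- p_nat
  attr(m, "tracer_purity") <- tracer_purity
  m
}

#' Correct an observed isotopologue pattern for natural abundance
#'
#' Solves `matrix %*% x = observed` for the tracer-derived mass
#' isotopologue distribution under a nonnegativity constraint (nonnegative
#' least squares, so measurement noise cannot produce negative fractions),
#' then renormalizes to sum 1.
#'
#' @param observed Numeric vector of observed intensities (or fractions)
#'   at mass shifts `m+0 ... m+n`.
#' @param correction Matrix from [build_correction_matrix()].
#' @return Numeric vector of class `mid` (corrected fractions, summing to
#'   1) with attribute `carbon_count`.
#' @export
correct_mid <- function(observed, correction) {
  n1 <- nrow(correction)
  if (length(observed) != n1) {
    abort("observed vector length must match the correction matrix")
  }
  if (all(observed == 0, na.rm = TRUE) || any(is.na(observed))) {
    abort("observed pattern must be nonzero and complete")
  }
  if (n1 == 1L) {
    x <- 1
  } else {
    x <- pracma::lsqnonneg(correction, as.numeric(observed))$x
  }
  if (sum(x) == 0) abort("correction produced an all-zero solution")
  x <- x / sum(x)
  structure(as.numeric(x), names = paste0("m", 0:(n1 - 1L)),
            carbon_count = n1 - 1L, class = "mid")
}

#' Isotopologue fraction and mean enrichment
#'
#' `label_fraction(mid, k)` is the corrected fraction at mass shift `m+k`;
#' `mean_enrichment(mid)` is the average fraction of labeled carbons,
#' `sum(k * f_k) / n`.
#'
#' @param mid A `mid` vector (fractions `m+0 ... m+n`).
#' @param k Mass shift of interest (0-based).
#' @return A fraction in [0, 1].
#' @export
label_fraction <- function(mid, k) {
  n <- length(mid) - 1L
  if (k < 0 || k > n) abort(paste0("k must lie in 0..", n))
  unname(mid[[k + 1L]])
}

#' @rdname label_fraction
#' @export
mean_enrichment <- function(mid) {
  n <- length(mid) - 1L
  if (n == 0L) return(0)
  sum((0:n) * as.numeric(mid)) / n
}
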