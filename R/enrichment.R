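# Annotation-class enrichment, volcano-style differential statistics,
# cross-layer fold-change correlation, and complete-case PCA reporting.

#' Annotation-class enrichment among hit proteins
#'
#' One-sided hypergeometric (upper tail) test of over-representation of
#' each annotation class among the hits, against a stated background
#' (typically every protein with at least one quantified site).
#' Benjamini-Hochberg adjustment across classes.
#'
#' @param hits Character vector of hit accessions (must be a subset of
#'   `background`).
#' @param background Character vector of background accessions.
#' @param annotations An `annotation_set` (class -> accessions; classes are
#'   intersected with the background before testing).
#' @return Tibble of class `enrichment_result`: `class`, `k_hits_in_class`,
#'   `n_hits`, `K_class_in_background`, `N_background`, `odds_ratio`,
#'   `p_one_sided`, `p_adjusted`.
#' @export
class_enrichment <- function(hits, background, annotations) {
  hits <- unique(as.character(hits))
  background <- unique(as.character(background))
  if (length(background) == 0L) abort("empty background")
  extra <- setdiff(hits, background)
  if (length(extra) > 0) {
    abort(paste0("hit(s) outside the background: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  N <- length(background)
  n <- length(hits)
  rows <- lapply(names(annotations), function(cl) {
    members <- intersect(annotations[[cl]], background)
    K <- length(members)
    k <- length(intersect(members, hits))
    # upper-tail P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / ((n - k) * (K - k))
    tibble(class = cl, k_hits_in_class = k, n_hits = n,
           K_class_in_background = K, N_background = N,
           odds_ratio = or, p_one_sided = p)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_one_sided, method = "BH")
  structure(out, class = unique(c("enrichment_result", class(out))))
}

# Vectorized Welch (unequal-variance) two-sided t test. Degenerate inputs
# are defined rather than refused: zero pooled standard error gives p = 1
# when the means agree and p = 0 otherwise.
welch_t <- function(ma, mb, va, vb, na, nb) {
  se2 <- va / na + vb / nb
  t_stat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(
    se2 > 0,
    se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
    NA_real_
  )
  p <- ifelse(se2 > 0, 2 * pt(-abs(t_stat), df),
              ifelse(ma == mb, 1, 0))
  list(t = t_stat, df = df, p = p)
}

#' Volcano-style differential table
#'
#' Per feature: `log2fc = mean(groupA) - mean(groupB)` and a two-sided
#' Welch t test across replicates. The significance flag reproduces the
#' usual volcano gates — unadjusted p below `p_cutoff` *and* fold change
#' beyond `fc_cutoff` — and a Benjamini-Hochberg column is always emitted
#' alongside.
#'
#' @param mat Numeric matrix of log2 values, features x samples, with
#'   rownames (feature ids) and colnames (sample ids). `NA` = missing.
#' @param group_a,group_b Column names (or indices) of the two groups.
#' @param p_cutoff Unadjusted p gate (default 0.05).
#' @param fc_cutoff Fold-change gate on the linear scale (default 1.5).
#' @return Tibble of class `differential_result`: `feature_id`, `log2fc`,
#'   `t_statistic`, `p_value`, `p_adjusted`, `significant`, `n_a`, `n_b`.
#'   Features with fewer than two observations in a group get `NA` p and
#'   flag; the fold change is still reported when both means exist.
#' @export
differential_table <- function(mat, group_a, group_b, p_cutoff = 0.05,
                               fc_cutoff = 1.5) {
  a <- mat[, group_a, drop = FALSE]
  b <- mat[, group_b, drop = FALSE]
  na <- rowSums(!is.na(a))
  nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE)
  mb <- rowMeans(b, na.rm = TRUE)
  va <- apply(a, 1, var, na.rm = TRUE)
  vb <- apply(b, 1, var, na.rm = TRUE)
  log2fc <- ifelse(na >= 1 & nb >= 1, ma - mb, NA_real_)
  ok <- na >= 2 & nb >= 2
  w <- welch_t(ma, mb, va, vb, na, nb)
  p <- ifelse(ok, w$p, NA_real_)
  t_stat <- ifelse(ok, w$t, NA_real_)
  significant <- ifelse(is.na(p) | is.na(log2fc), NA,
                        p < p_cutoff & abs(log2fc) > log2(fc_cutoff))
  out <- tibble(
    feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    log2fc = unname(log2fc),
    t_statistic = unname(t_stat),
    p_value = unname(p),
    p_adjusted = unname(p.adjust(p, method = "BH")),
    significant = unname(significant),
    n_a = unname(as.integer(na)), n_b = unname(as.integer(nb))
  )
  structure(out, p_cutoff = p_cutoff, fc_cutoff = fc_cutoff,
            class = unique(c("differential_result", class(out))))
}

#' Fold-change correlation between two omic layers
#'
#' Inner join of two fold-change tables on a shared identifier, Pearson
#' correlation, and ordinary least-squares regression of layer B on layer
#' A — the comparison restricted to features quantified in both layers.
#'
#' @param layer_a,layer_b Data frames with columns `id` and `log2fc`.
#' @return List: `r`, `slope`, `intercept`, `n`, and the matched tibble
#'   (`matched`).
#' @export
fc_correlation <- function(layer_a, layer_b) {
  for (d in list(layer_a, layer_b)) {
    if (!all(c("id", "log2fc") %in% names(d))) {
      abort("each layer needs columns 'id' and 'log2fc'")
    }
  }
  m <- inner_join(as_tibble(layer_a), as_tibble(layer_b), by = "id",
                  suffix = c("_a", "_b"))
  m <- m[stats::complete.cases(m$log2fc_a, m$log2fc_b), ]
  if (nrow(m) < 3L) abort("fewer than 3 matched ids")
  fit <- lm(log2fc_b ~ log2fc_a, data = m)
  list(
    r = cor(m$log2fc_a, m$log2fc_b),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n = nrow(m),
    matched = m
  )
}

#' Complete-case principal component report
#'
#' Features with any missing value are removed (the complete-case filter:
#' only features quantified in all samples enter the decomposition), the
#' samples-by-features matrix is column-centered (no unit-variance scaling
#' by default, since inputs share a common log2 scale), and components are
#' taken from its singular value decomposition. Component signs are fixed
#' by making the largest-magnitude loading positive, so reports are
#' reproducible. The top and bottom `n_top` loadings per component are
#' tabulated for annotation.
#'
#' @param mat Numeric matrix, features x samples, rownames = feature ids.
#' @param n_components Number of components to keep (default: full rank).
#' @param n_top Loadings reported per extreme per component (default 5).
#' @param scale. Also scale features to unit variance (default `FALSE`).
#' @return List of class `pca_report`: `scores` (samples x components),
#'   `loadings` (features x components), `variance_explained`,
#'   `top_loadings` (tibble `component`, `feature_id`, `loading`, `end`),
#'   `n_features_used`.
#' @export
pca_report <- function(mat, n_components = NULL, n_top = 5L,
                       scale. = FALSE) {
  if (ncol(mat) < 2L) abort("PCA needs at least 2 samples")
  cc <- rowSums(is.na(mat)) == 0L
  m <- mat[cc, , drop = FALSE]
  if (nrow(m) < 1L) abort("no complete-case features")
  x <- scale(t(m), center = TRUE, scale = scale.)
  sv <- svd(x)
  rank <- sum(sv$d > max(sv$d) * 1e-12)
  k <- min(n_components %||% rank, rank)
  u <- sv$u[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(d, nrow = k)
  dimnames(scores) <- list(colnames(mat), paste0("PC", seq_len(k)))
  dimnames(v) <- list(rownames(m), paste0("PC", seq_len(k)))
  var_explained <- sv$d^2 / sum(sv$d^2)
  top <- bind_rows(lapply(seq_len(k), function(j) {
    ord <- order(v[, j])
    nt <- min(n_top, nrow(v))
    bind_rows(
      tibble(component = paste0("PC", j),
             feature_id = rownames(v)[rev(tail(ord, nt))],
             loading = v[rev(tail(ord, nt)), j], end = "high"),
      tibble(component = paste0("PC", j),
             feature_id = rownames(v)[head(ord, nt)],
             loading = v[head(ord, nt), j], end = "low")
    )
  }))
  structure(
    list(scores = scores, loadings = v,
         variance_explained = var_explained[seq_len(k)],
         variance_explained_full = var_explained,
         top_loadings = top, n_features_used = nrow(m)),
    class = "pca_report"
  )
}
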