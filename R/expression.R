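# Count filtering, TMM normalization and PCA/clustering QC.

#' Filter lowly expressed features
#'
#' Keeps a feature iff it has at least `min_count` counts in at least
#' `min_samples` samples, evaluated jointly over all samples (the filter the
#' larval study applied before differential expression).
#'
#' @param m a [count_matrix()].
#' @param min_count,min_samples thresholds (both >= 1).
#' @return the filtered [count_matrix()]; warns (does not error) when no
#'   feature survives.
#' @export
filter_low_counts <- function(m, min_count = 5L, min_samples = 5L) {
  stopifnot(inherits(m, "count_matrix"))
  if (min_count < 1L || min_samples < 1L)
    stop("filter_low_counts: thresholds must be >= 1", call. = FALSE)
  keep <- rowSums(m$counts >= min_count) >= min_samples
  if (!any(keep)) warning("filter_low_counts: no feature passes the filter")
  count_matrix(m$counts[keep, , drop = FALSE], m$design)
}

# TMM scaling factors.  Reference = sample whose 75th percentile of
# count/libsize is closest to the mean 75th percentile; per-sample factor =
# 2^(trimmed mean of M values), with 30% trimming on M and 5% on A;
# factors renormalized to geometric mean 1.  The mean is unweighted so that
# scaling a sample's counts (which scales its library identically) cancels
# exactly.
.tmm_factors <- function(counts, m_trim = 0.3, a_trim = 0.05) {
  libs <- colSums(counts)
  if (any(libs == 0))
    stop("normalize_log_cpm: zero library size", call. = FALSE)
  q75 <- apply(counts, 2, function(y) quantile(y / sum(y), 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  yr <- counts[, ref]; nr <- libs[ref]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    yk <- counts[, k]; nk <- libs[k]
    ok <- yk > 0 & yr > 0
    if (!any(ok)) return(1)
    m_val <- log2((yk[ok] / nk) / (yr[ok] / nr))
    a_val <- 0.5 * log2((yk[ok] / nk) * (yr[ok] / nr))
    keep_m <- m_val >= quantile(m_val, m_trim) &
      m_val <= quantile(m_val, 1 - m_trim)
    keep_a <- a_val >= quantile(a_val, a_trim) &
      a_val <= quantile(a_val, 1 - a_trim)
    keep <- keep_m & keep_a
    if (!any(keep)) return(1)
    2^mean(m_val[keep])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' TMM-normalized log2 CPM
#'
#' Computes trimmed-mean-of-M-values scaling factors (M-trim 30%, A-trim 5%,
#' reference chosen by the 75th-percentile rule, factors renormalized to
#' geometric mean 1) and returns
#' \eqn{\log_2(10^6 \cdot y / (N \cdot f) + 1)}.
#'
#' @param m a [count_matrix()].
#' @return list with `logcpm` (matrix), `factors` (named numeric),
#'   `lib_sizes` (named numeric).
#' @export
normalize_log_cpm <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- m$counts
  libs <- colSums(counts)
  f <- .tmm_factors(counts)
  eff <- libs * f
  logcpm <- log2(sweep(counts, 2, eff, `/`) * 1e6 + 1)
  list(logcpm = logcpm, factors = f, lib_sizes = libs)
}

#' PCA and Euclidean-distance clustering of samples
#'
#' Projects samples (columns of the log-expression matrix) onto principal
#' components and clusters them by average linkage on the Euclidean distance
#' between expression vectors — the QC view the larval study used to show
#' each caste grouping separately.
#'
#' @param logexpr numeric matrix, features x samples.
#' @return list with `scores` (samples x PCs), `explained_var` (per-PC
#'   variance), `dist` (symmetric matrix), `hclust` (average-linkage tree).
#' @export
project_pca_and_cluster <- function(logexpr) {
  if (ncol(logexpr) < 2)
    stop("project_pca_and_cluster: need at least 2 samples", call. = FALSE)
  if (all(apply(logexpr, 1, function(r) diff(range(r)) == 0)))
    stop("project_pca_and_cluster: constant matrix, PCA undefined",
         call. = FALSE)
  pca <- prcomp(t(logexpr), center = TRUE, scale. = FALSE)
  d <- dist(t(logexpr))
  hc <- hclust(d, method = "average")
  list(scores = pca$x, explained_var = pca$sdev^2,
       dist = as.matrix(d), hclust = hc)
}
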