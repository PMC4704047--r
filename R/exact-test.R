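# Negative-binomial exact test and common-dispersion estimation.

# scale each sample's counts to a common (geometric-mean) library and round
.equalize <- function(counts, libsizes) {
  common <- exp(mean(log(libsizes)))
  round(sweep(counts, 2, common / libsizes, `*`))
}

# conditional pmf of group-A's sum given the total s, under NB with common
# dispersion phi and per-sample mean mu (equalized libraries)
.cond_pmf <- function(s, nA, nB, mu, phi) {
  a <- 0:s
  if (phi <= 0) {
    lp <- dbinom(a, s, nA / (nA + nB), log = TRUE)
  } else {
    lp <- dnbinom(a, size = nA / phi, mu = nA * mu, log = TRUE) +
      dnbinom(s - a, size = nB / phi, mu = nB * mu, log = TRUE)
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Exact negative-binomial test for a two-group comparison
#'
#' Two-sided p-value from the conditional distribution of group A's
#' library-equalized count sum given the total, under a negative binomial
#' with common dispersion \eqn{\phi} (variance \eqn{\mu + \phi\mu^2});
#' the smaller tail (including the observed outcome) is doubled and capped
#' at 1.  At \eqn{\phi = 0} the conditional law is exactly binomial.
#'
#' @param countsA,countsB integer count vectors (one per sample).
#' @param libsizesA,libsizesB library sizes, parallel to the counts.
#' @param dispersion common NB dispersion, >= 0.
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(countsA, countsB, libsizesA, libsizesB,
                          dispersion) {
  if (dispersion < 0)
    stop("nb_exact_test: dispersion must be >= 0", call. = FALSE)
  if (!length(countsA) || !length(countsB))
    stop("nb_exact_test: both groups must be non-empty", call. = FALSE)
  counts <- matrix(c(countsA, countsB), nrow = 1)
  eq <- .equalize(counts, c(libsizesA, libsizesB))
  nA <- length(countsA); nB <- length(countsB)
  sA <- sum(eq[seq_len(nA)]); sB <- sum(eq[-seq_len(nA)])
  s <- sA + sB
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  pmf <- .cond_pmf(s, nA, nB, mu, dispersion)
  lower <- sum(pmf[seq_len(sA + 1)])
  upper <- sum(pmf[(sA + 1):(s + 1)])
  min(1, 2 * min(lower, upper))
}

# conditional NB log-likelihood of counts y given their sum, for one group
# (qCML): log P depends on phi only through r = 1/phi
.cond_loglik_group <- function(y, phi) {
  if (phi <= 0) return(0)
  r <- 1 / phi
  k <- length(y)
  sum(lgamma(y + r)) - k * lgamma(r) + lgamma(k * r) - lgamma(sum(y) + k * r)
}

#' Estimate the common dispersion by conditional maximum likelihood
#'
#' Equalizes libraries (scaling + rounding to the geometric-mean library),
#' then maximizes the summed conditional negative-binomial log-likelihood of
#' the within-group counts given each group's sum, by bounded 1-D search
#' over the dispersion.
#'
#' @param m a [count_matrix()].
#' @param groups factor/character of group labels per sample (defaults to
#'   the design's caste).
#' @return the dispersion estimate \eqn{\hat\phi \ge 0}.
#' @export
estimate_common_dispersion <- function(m, groups = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  groups <- groups %||% m$design$caste
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("estimate_common_dispersion: need >= 2 groups with >= 2 samples",
         call. = FALSE)
  counts <- m$counts
  if (all(counts == 0))
    stop("estimate_common_dispersion: all-zero matrix", call. = FALSE)
  eq <- .equalize(counts, colSums(counts))
  idx <- split(seq_along(groups), groups)
  obj <- function(phi) {
    tot <- 0
    for (cols in idx) {
      sub <- eq[, cols, drop = FALSE]
      keep <- rowSums(sub) > 0
      if (!any(keep)) next
      tot <- tot + sum(apply(sub[keep, , drop = FALSE], 1,
                             .cond_loglik_group, phi = phi))
    }
    tot
  }
  opt <- optimize(obj, interval = c(1e-6, 4), maximum = TRUE,
                  tol = 1e-4)
  phi_hat <- opt$maximum
  # boundary: likelihood non-increasing near zero means Poisson fits best
  if (phi_hat < 5e-4 || obj(1e-6) >= opt$objective - 1e-8) phi_hat <- 0
  phi_hat
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment: on sorted p-values,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, returned in the original
#' order and capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("adjust_fdr: p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
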