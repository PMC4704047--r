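# Length-bias-corrected gene-set enrichment (weighted-resampling null) and
# the Fisher-exact methylation-overlap test.

#' Length-dependent selection weights
#'
#' Estimates the probability of a gene being selected (e.g. called a miRNA
#' target) as a monotone function of gene length: genes are binned by
#' length quantiles, the per-bin selection fraction is fitted by isotonic
#' regression in the direction of the observed length-selection trend, and
#' the fitted values — renormalized to mean 1 over the universe — become
#' per-gene sampling weights for the enrichment null.
#'
#' @param selected character vector of selected gene IDs.
#' @param universe character vector, superset of `selected`.
#' @param lengths named numeric vector of gene lengths (bases); genes
#'   without a length are dropped with a warning.
#' @param n_bins number of length bins (default 20).
#' @return named numeric vector of weights over (the retained) universe,
#'   mean 1.
#' @export
compute_length_weights <- function(selected, universe, lengths,
                                   n_bins = 20L) {
  if (!all(selected %in% universe))
    stop("compute_length_weights: selected must be a subset of universe",
         call. = FALSE)
  has_len <- universe %in% names(lengths)
  if (!all(has_len)) {
    warning("compute_length_weights: dropping ", sum(!has_len),
            " gene(s) without length")
    universe <- universe[has_len]
    selected <- intersect(selected, universe)
  }
  len <- lengths[universe]
  if (any(len <= 0))
    stop("compute_length_weights: lengths must be positive", call. = FALSE)
  sel <- universe %in% selected
  flat <- setNames(rep(1, length(universe)), universe)
  if (sum(sel) < 2) return(flat)
  brk <- unique(quantile(len, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 3) return(flat)
  # no detectable length-selection association: weights stay constant
  # (fitting the monotone curve to pure noise would fabricate a trend)
  assoc <- suppressWarnings(
    stats::cor.test(len, as.numeric(sel), method = "spearman",
                    exact = FALSE))
  if (is.na(assoc$p.value) || assoc$p.value >= 0.01) return(flat)
  bin <- cut(len, brk, include.lowest = TRUE)
  prop <- tapply(sel, bin, mean)
  mid <- tapply(len, bin, median)
  ok <- !is.na(prop)
  prop <- prop[ok]; mid <- mid[ok]
  if (length(prop) < 2) return(flat)
  increasing <- suppressWarnings(
    stats::cor(mid, prop, method = "spearman")) >= 0
  if (is.na(increasing)) return(flat)
  iso <- if (increasing) isoreg(mid, prop) else isoreg(mid, -prop)
  fit <- if (increasing) iso$yf else -iso$yf
  fit <- pmax(fit, 1e-4)
  w <- fit[match(bin, names(prop))]
  w <- w / mean(w)
  setNames(unname(w), universe)
}

#' Gene-set over-representation test with a weighted-resampling null
#'
#' For each term, the null distribution of the overlap with the selected
#' set is obtained by repeatedly sampling `|selected|` genes from the
#' universe without replacement, with per-gene probabilities proportional
#' to the length weights; p = (1 + #\{draws with overlap >= observed\}) /
#' (n_perm + 1), so p is never 0.  With uniform weights this converges to
#' the hypergeometric upper tail.  Terms with fewer than `min_size`
#' annotated genes in the universe are skipped; q-values by [adjust_fdr()]
#' over the tested terms.
#'
#' @param terms named list mapping term IDs to gene ID vectors.
#' @param selected selected gene set.
#' @param universe gene universe.
#' @param weights per-gene weights over the universe (default uniform),
#'   e.g. from [compute_length_weights()].
#' @param n_perm number of null draws (>= 100).
#' @param seed integer seed for the resampling null.
#' @param min_size minimum annotated-term size.
#' @return data.frame with columns `term`, `n_annotated`, `n_selected`,
#'   `p`, `q`.
#' @export
enrichment_test <- function(terms, selected, universe, weights = NULL,
                            n_perm = 10000L, seed = 1L, min_size = 5L) {
  if (n_perm < 100L)
    stop("enrichment_test: n_perm must be >= 100", call. = FALSE)
  selected <- intersect(selected, universe)
  k <- length(selected)
  nu <- length(universe)
  if (is.null(weights)) weights <- setNames(rep(1, nu), universe)
  w <- weights[universe]
  if (any(is.na(w)))
    stop("enrichment_test: weights missing for some universe genes",
         call. = FALSE)
  term_idx <- lapply(terms, function(g) which(universe %in% g))
  annotated <- lengths(term_idx)
  keep <- annotated >= min_size
  term_idx <- term_idx[keep]
  if (length(term_idx) == 0) {
    return(data.frame(term = character(0), n_annotated = integer(0),
                      n_selected = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  sel_idx <- which(universe %in% selected)
  obs <- vapply(term_idx, function(ix) length(intersect(ix, sel_idx)),
                integer(1))
  set.seed(seed)
  member <- matrix(FALSE, nrow = length(term_idx), ncol = nu)
  for (t in seq_along(term_idx)) member[t, term_idx[[t]]] <- TRUE
  exceed <- integer(length(term_idx))
  for (b in seq_len(n_perm)) {
    # weighted sampling without replacement via the exponential race
    draw <- order(rexp(nu) / w)[seq_len(k)]
    null_ov <- as.integer(member[, draw, drop = FALSE] %*% rep(1L, k))
    exceed <- exceed + (null_ov >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  data.frame(term = names(term_idx),
             n_annotated = annotated[keep],
             n_selected = obs,
             p = p, q = adjust_fdr(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect per-method enriched term sets
#'
#' The second combination approach: run enrichment on each prediction
#' method's targets separately and keep only the terms enriched under every
#' method.
#'
#' @param term_sets list (length >= 2) of character vectors of enriched
#'   term IDs, named by method.
#' @return data.frame with `term` and `methods` (provenance, comma-joined);
#'   warns when the intersection is empty.
#' @export
combine_by_go_intersection <- function(term_sets) {
  if (length(term_sets) < 2)
    stop("combine_by_go_intersection: need >= 2 term sets", call. = FALSE)
  common <- Reduce(intersect, term_sets)
  if (length(common) == 0) {
    warning("combine_by_go_intersection: empty intersection")
    return(data.frame(term = character(0), methods = character(0),
                      stringsAsFactors = FALSE))
  }
  nm <- names(term_sets) %||% paste0("set", seq_along(term_sets))
  data.frame(term = sort(common),
             methods = paste(nm, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Fisher-exact overlap of miRNA targets and methylated genes
#'
#' Builds the 2x2 table of target status by methylation status over the
#' universe and computes the one-sided under-representation p (lower
#' hypergeometric tail of the overlap), the two-sided p (sum of table
#' probabilities not exceeding the observed one), and the odds ratio
#' (ad)/(bc), Haldane-corrected by 0.5 iff any cell is zero.
#'
#' @param targets,methylated gene sets, both subsets of `universe`.
#' @param universe the gene universe.
#' @return object of class `overlap_table`: list with `table` (2x2 matrix),
#'   `odds_ratio`, `p_under`, `p_two_sided`.
#' @export
fisher_overlap <- function(targets, methylated, universe) {
  if (length(universe) == 0)
    stop("fisher_overlap: empty universe", call. = FALSE)
  if (!all(targets %in% universe) || !all(methylated %in% universe))
    stop("fisher_overlap: sets must be subsets of the universe",
         call. = FALSE)
  targets <- unique(targets); methylated <- unique(methylated)
  N <- length(universe)
  nT <- length(targets); nM <- length(methylated)
  a <- length(intersect(targets, methylated))
  b <- nT - a
  cc <- nM - a
  d <- N - nT - nM + a
  p_under <- phyper(a, nM, N - nM, nT)
  support <- max(0, nT + nM - N):min(nT, nM)
  probs <- dhyper(support, nM, N - nM, nT)
  p_obs <- dhyper(a, nM, N - nM, nT)
  p_two <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(target = c("yes", "no"),
                                methylated = c("yes", "no")))
  structure(list(table = tab, odds_ratio = or, p_under = p_under,
                 p_two_sided = p_two), class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat("2x2 overlap (target x methylated):\n")
  print(x$table)
  cat(sprintf("odds ratio %.4g | one-sided (under) p %.3g | two-sided p %.3g\n",
              x$odds_ratio, x$p_under, x$p_two_sided))
  invisible(x)
}
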