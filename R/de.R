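# Pairwise differential expression, the three-way pattern partition, and
# PCR-concordance arithmetic.

.split_comparison <- function(comparison) {
  parts <- strsplit(comparison, "_vs_")[[1]]
  if (length(parts) != 2)
    stop("comparison must look like 'first_vs_second'", call. = FALSE)
  parts
}

#' Pairwise differential expression by the NB exact test
#'
#' For one caste pair: log2 fold change of the second caste relative to the
#' first (on TMM-normalized CPM means with pseudocount 1), exact NB p-value
#' at the common dispersion, BH q-value within the comparison, and a call
#' direction (`up`/`down` = second caste higher/lower, `ns` otherwise).
#'
#' @param m a filtered [count_matrix()] containing both castes.
#' @param comparison string `"first_vs_second"`, e.g. `"queen_vs_worker"`.
#' @param fdr call threshold on the BH q-value (default 0.01).
#' @param dispersion common dispersion; estimated from all castes of `m`
#'   via [estimate_common_dispersion()] when `NULL`.
#' @return data.frame with columns `feature`, `comparison`, `logFC`, `p`,
#'   `q`, `direction`.
#' @export
test_differential_expression <- function(m, comparison, fdr = 0.01,
                                         dispersion = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  castes <- .split_comparison(comparison)
  idxA <- which(m$design$caste == castes[1])
  idxB <- which(m$design$caste == castes[2])
  if (length(idxA) < 2 || length(idxB) < 2)
    stop("test_differential_expression: each caste needs >= 2 replicates",
         call. = FALSE)
  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(m)
  counts <- m$counts
  eff <- colSums(counts) * .tmm_factors(counts)
  cpm <- sweep(counts, 2, eff, `/`) * 1e6
  meanA <- rowMeans(cpm[, idxA, drop = FALSE])
  meanB <- rowMeans(cpm[, idxB, drop = FALSE])
  logFC <- log2((meanB + 1) / (meanA + 1))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(counts[i, idxA], counts[i, idxB],
                  eff[idxA], eff[idxB], dispersion)
  }, numeric(1))
  q <- adjust_fdr(p)
  direction <- ifelse(q < fdr & logFC > 0, "up",
                      ifelse(q < fdr & logFC < 0, "down", "ns"))
  data.frame(feature = rownames(counts), comparison = comparison,
             logFC = logFC, p = p, q = q, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression across all caste pairs
#'
#' Runs [test_differential_expression()] for every pairwise comparison
#' (BH adjustment within each comparison separately), with the common
#' dispersion estimated once.
#'
#' @inheritParams test_differential_expression
#' @return row-bound data.frame over all comparisons.
#' @export
test_all_comparisons <- function(m, fdr = 0.01, dispersion = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(m)
  comps <- caste_comparisons(unique(m$design$caste))
  do.call(rbind, lapply(comps, function(cmp) {
    test_differential_expression(m, cmp, fdr = fdr, dispersion = dispersion)
  }))
}

#' Three-way expression pattern partition
#'
#' Assigns each feature a three-letter pattern over the pairwise
#' comparisons: each slot names the caste with significantly higher
#' expression in that comparison (its initial, e.g. D/Q/W) or `"."` for no
#' change.  The marginal identity holds by construction: the up-count of a
#' caste in one comparison equals the sum of pattern counts whose slot for
#' that comparison carries the caste's letter.
#'
#' @param de the output of [test_all_comparisons()] (all comparisons
#'   present for every feature).
#' @return list with `counts` (named integer vector, pattern -> feature
#'   count) and `features` (data.frame feature/pattern); slot order follows
#'   [caste_comparisons()].
#' @export
pattern_partition <- function(de) {
  comps <- unique(de$comparison)
  feats <- unique(de$feature)
  wide <- lapply(comps, function(cmp) {
    sub <- de[de$comparison == cmp, , drop = FALSE]
    if (!setequal(sub$feature, feats))
      stop("pattern_partition: comparison ", cmp,
           " does not cover all features", call. = FALSE)
    sub[match(feats, sub$feature), , drop = FALSE]
  })
  castes <- unique(unlist(lapply(comps, .split_comparison)))
  if (length(comps) != choose(length(castes), 2))
    stop("pattern_partition: need all pairwise comparisons", call. = FALSE)
  initial <- function(x) toupper(substr(x, 1, 1))
  slots <- vapply(seq_along(comps), function(j) {
    cs <- .split_comparison(comps[j])
    ifelse(wide[[j]]$direction == "up", initial(cs[2]),
           ifelse(wide[[j]]$direction == "down", initial(cs[1]), "."))
  }, character(length(feats)))
  if (length(feats) == 1) slots <- matrix(slots, nrow = 1)
  pattern <- apply(slots, 1, paste, collapse = "")
  counts <- table(pattern)
  list(counts = setNames(as.integer(counts), names(counts)),
       features = data.frame(feature = feats, pattern = pattern,
                             stringsAsFactors = FALSE))
}

#' Concordance between sequencing calls and an independent validation panel
#'
#' Splits the sequencing calls into changed (non-`ns`) and unchanged (`ns`)
#' subsets and reports, for each, the fraction with the identical call in
#' the validation set — the arithmetic behind a "31 of 36 changes validated,
#' an 86% validation rate" style statement.
#'
#' @param seq_calls,pcr_calls data.frames with columns `id`, `comparison`,
#'   `call` (values `up`/`down`/`ns`), indexed by (id, comparison).
#' @return list with `changed` and `unchanged`, each holding `n`,
#'   `concordant`, `rate` (proportion, `NA` when the denominator is empty,
#'   with `flagged = TRUE`) and `pct` (rate rounded to integer percent).
#' @export
pcr_concordance <- function(seq_calls, pcr_calls) {
  key <- function(d) paste(d$id, d$comparison, sep = "\r")
  j <- match(key(seq_calls), key(pcr_calls))
  if (any(is.na(j)))
    stop("pcr_concordance: validation calls missing for some conditions",
         call. = FALSE)
  agree <- seq_calls$call == pcr_calls$call[j]
  one <- function(mask) {
    n <- sum(mask)
    conc <- sum(agree & mask)
    rate <- if (n > 0) conc / n else NA_real_
    list(n = n, concordant = conc, rate = rate,
         pct = if (n > 0) round(100 * rate) else NA_integer_,
         flagged = n == 0)
  }
  list(changed = one(seq_calls$call != "ns"),
       unchanged = one(seq_calls$call == "ns"))
}
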