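# Correlation refinement of consensus pairs and bipartite network summaries.

#' Pearson correlation of candidate miRNA-target pairs
#'
#' Correlates each pair's miRNA and target log-expression across all
#' samples; the p-value comes from the t transform with n-2 degrees of
#' freedom, two-sided.  Pairs with zero variance in either vector, or with
#' a feature absent from the expression matrices, are excluded and reported
#' with a reason code.
#'
#' @param pairs data.frame with `mirna` and `gene` columns (e.g. from
#'   [consensus_pairs()]).
#' @param mirna_logexpr,mrna_logexpr normalized log-expression matrices
#'   (features x samples) sharing the same ordered sample set, e.g. the
#'   `logcpm` of [normalize_log_cpm()].
#' @return list with `tested` (data.frame mirna/gene/r/p) and `excluded`
#'   (data.frame mirna/gene/reason).
#' @export
correlate_pairs <- function(pairs, mirna_logexpr, mrna_logexpr) {
  if (!identical(colnames(mirna_logexpr), colnames(mrna_logexpr)))
    stop("correlate_pairs: sample sets of the two matrices differ",
         call. = FALSE)
  n <- ncol(mirna_logexpr)
  present <- pairs$mirna %in% rownames(mirna_logexpr) &
    pairs$gene %in% rownames(mrna_logexpr)
  excluded <- data.frame(mirna = pairs$mirna[!present],
                         gene = pairs$gene[!present],
                         reason = rep("feature_absent", sum(!present)),
                         stringsAsFactors = FALSE)
  pairs <- pairs[present, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(list(tested = data.frame(mirna = character(0),
                                    gene = character(0), r = numeric(0),
                                    p = numeric(0)),
                excluded = excluded))
  }
  x <- mirna_logexpr[pairs$mirna, , drop = FALSE]
  y <- mrna_logexpr[pairs$gene, , drop = FALSE]
  sx <- apply(x, 1, stats::sd); sy <- apply(y, 1, stats::sd)
  zero <- sx == 0 | sy == 0
  if (any(zero)) {
    excluded <- rbind(excluded, data.frame(
      mirna = pairs$mirna[zero], gene = pairs$gene[zero],
      reason = rep("zero_variance", sum(zero)), stringsAsFactors = FALSE))
  }
  pairs <- pairs[!zero, , drop = FALSE]
  x <- x[!zero, , drop = FALSE]; y <- y[!zero, , drop = FALSE]
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  r <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  list(tested = data.frame(mirna = pairs$mirna, gene = pairs$gene,
                           r = unname(r), p = unname(p),
                           stringsAsFactors = FALSE),
       excluded = excluded)
}

#' FDR-filter correlated pairs and assign interaction signs
#'
#' BH adjustment over all tested pairs jointly; pairs with q below the
#' threshold are kept and signed by the sign of r (an exactly zero r is
#' excluded rather than arbitrarily signed).
#'
#' @param correlated the `tested` data.frame of [correlate_pairs()].
#' @param fdr q-value threshold (default 0.05).
#' @return data.frame with columns `mirna`, `gene`, `r`, `p`, `q`, `sign`
#'   (`positive`/`negative`).
#' @export
filter_and_sign <- function(correlated, fdr = 0.05) {
  if (nrow(correlated) == 0) {
    return(cbind(correlated,
                 data.frame(q = numeric(0), sign = character(0))))
  }
  correlated$q <- adjust_fdr(correlated$p)
  kept <- correlated[correlated$q < fdr & correlated$r != 0, , drop = FALSE]
  kept$sign <- ifelse(kept$r > 0, "positive", "negative")
  rownames(kept) <- NULL
  kept
}

#' Bipartite interaction-network summary
#'
#' Tallies the kept correlated pairs as a bipartite miRNA-gene network:
#' edge counts by sign, node counts, per-node degrees, per-node sign
#' profiles (positive/negative/both), maximum-degree nodes, and — when a
#' differential-expression table is supplied — the fraction of target genes
#' differentially expressed in at least one comparison.
#'
#' @param kept the output of [filter_and_sign()].
#' @param de optional [test_all_comparisons()] output for the mRNA matrix.
#' @return list with `edges`, `summary` (named list of scalar tallies),
#'   `mirna_nodes`, `gene_nodes` (data.frames id/degree/sign_profile).
#' @export
build_network_stats <- function(kept, de = NULL) {
  node_table <- function(ids, signs) {
    if (length(ids) == 0) {
      return(data.frame(id = character(0), degree = integer(0),
                        sign_profile = character(0),
                        stringsAsFactors = FALSE))
    }
    sp <- vapply(split(signs, ids), function(s) {
      hasp <- any(s == "positive"); hasn <- any(s == "negative")
      if (hasp && hasn) "both" else if (hasp) "positive" else "negative"
    }, character(1))
    deg <- table(ids)
    data.frame(id = names(deg), degree = as.integer(deg),
               sign_profile = sp[names(deg)], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  mn <- node_table(kept$mirna, kept$sign)
  gn <- node_table(kept$gene, kept$sign)
  summary <- list(
    n_edges = nrow(kept),
    n_mirnas = nrow(mn),
    n_genes = nrow(gn),
    n_positive = sum(kept$sign == "positive"),
    n_negative = sum(kept$sign == "negative"),
    max_degree_mirna = if (nrow(mn)) mn$id[which.max(mn$degree)] else NA,
    max_degree_mirna_k = if (nrow(mn)) max(mn$degree) else 0L,
    max_degree_gene = if (nrow(gn)) gn$id[which.max(gn$degree)] else NA,
    max_degree_gene_k = if (nrow(gn)) max(gn$degree) else 0L
  )
  if (!is.null(de) && nrow(gn)) {
    de_feats <- unique(de$feature[de$direction != "ns"])
    summary$frac_targets_de <- mean(gn$id %in% de_feats)
  }
  list(edges = kept, summary = summary, mirna_nodes = mn, gene_nodes = gn)
}
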