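# Planted-truth recovery metrics for a pipeline run on synthetic data.

.truth_df <- function(x) {
  # truth components arrive either as data.frames (in memory) or as lists
  # of parallel columns (JSON round trip)
  if (is.data.frame(x)) x else as.data.frame(x, stringsAsFactors = FALSE)
}

#' Recovery of planted truth by a pipeline run
#'
#' Compares a [run_pipeline()] result against the generator's planted
#' truth.  Differential-expression recovery is scored on the mRNA matrix,
#' per (feature, comparison) condition: sensitivity is the fraction of
#' planted conditions (restricted to filter-surviving features) called at
#' the DE threshold with the planted direction; the empirical FDR is the
#' fraction of calls on non-planted features, with coupled genes excluded
#' from both tallies (their shared latent factor makes them neither planted
#' DE nor null).  Coupling recovery is scored on the kept network edges.
#'
#' @param res a [run_pipeline()] result.
#' @param truth the generator truth (`synth_dataset()$truth` or the parsed
#'   `truth.json`).
#' @return named list of metrics: `de_sensitivity`, `de_fdr`, `de_n_planted`,
#'   `de_n_called`, `coupling_sensitivity`, `coupling_fdp`,
#'   `coupling_sign_accuracy`, `n_planted_pairs`, `target_sensitivity`,
#'   `decoy_consensus_rate`.
#' @export
recovery_metrics <- function(res, truth) {
  cp <- .truth_df(truth$coupled_pairs)

  ## differential expression (mRNA side)
  de <- res$de_mrna
  filtered <- rownames(res$mrna_filtered$counts)
  called <- de[de$direction != "ns" & !(de$feature %in% cp$gene), ,
               drop = FALSE]
  tp <- 0L; fp <- 0L; n_planted <- 0L
  for (cmp in names(truth$de_features)) {
    tf <- .truth_df(truth$de_features[[cmp]])
    if (nrow(tf) == 0) next
    tf <- tf[tf$feature %in% filtered & !grepl("^mir", tf$feature), ,
             drop = FALSE]
    n_planted <- n_planted + nrow(tf)
    cc <- called[called$comparison == cmp, , drop = FALSE]
    hit <- cc$feature %in% tf$feature &
      cc$direction == tf$expected[match(cc$feature, tf$feature)]
    tp <- tp + sum(hit, na.rm = TRUE)
    fp <- fp + sum(!cc$feature %in% tf$feature)
  }

  ## coupling recovery on the kept network
  planted_keys <- paste(cp$mirna, cp$gene)
  edges <- res$network$edges
  kept_keys <- paste(edges$mirna, edges$gene)
  found <- planted_keys %in% kept_keys
  m <- match(kept_keys, planted_keys)
  rec <- !is.na(m)
  sign_ok <- (edges$sign[rec] == "negative") == (cp$sign[m[rec]] == -1L)

  ## consensus target recovery
  cons_keys <- paste(res$consensus$mirna, res$consensus$gene)
  n_possible <- nrow(res$mirna_filtered$counts) *
    length(res$inputs$annotation$genes$gene_id)

  list(
    de_sensitivity = tp / n_planted,
    de_fdr = if (nrow(called)) fp / nrow(called) else 0,
    de_n_planted = n_planted,
    de_n_called = nrow(called),
    coupling_sensitivity = mean(found),
    coupling_fdp = if (nrow(edges)) mean(!rec) else 0,
    coupling_sign_accuracy = if (any(rec)) mean(sign_ok) else NA_real_,
    n_planted_pairs = length(planted_keys),
    target_sensitivity = mean(planted_keys %in% cons_keys),
    decoy_consensus_rate = sum(!cons_keys %in% planted_keys) /
      max(1, n_possible - length(planted_keys))
  )
}
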