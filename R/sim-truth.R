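#' Planted ground truth for a synthetic dataset
#'
#' Draws the identity layer of the simulation: which features carry a caste
#' effect (and in which direction), which (miRNA, gene) pairs are coupled
#' (and with which sign).  Sequence-level truth (planted site offsets) is
#' filled in by [synth_sequences()]; methylation labels by
#' [plant_methylation()].
#'
#' Coupled pairs are disjoint on both sides, and coupled features never carry
#' a planted caste effect: the coupling latent factor is caste-balanced by
#' construction, so differential expression and coupling are orthogonal
#' planted signals.
#'
#' @param config a [sim_config()].
#' @return a list of class `synth_truth` with elements `mirna_ids`,
#'   `gene_ids`, `coupled_pairs` (data.frame mirna/gene/sign),
#'   `de_mirna`, `de_mrna` (data.frame feature/caste/direction),
#'   `de_features` (per-comparison data.frames of feature and expected
#'   direction), `planted_sites` (filled later), `methylated_genes`
#'   (filled later).
#' @export
synth_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$master_seed, 1L))
  mirna_ids <- sprintf("mir-%04d", seq_len(config$n_mirnas))
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  ncp <- config$n_coupled_pairs
  if (ncp > min(config$n_mirnas, config$n_genes))
    stop("synth_truth: n_coupled_pairs exceeds the number of available ",
         "miRNAs or genes for disjoint pairing", call. = FALSE)
  if (ncp > 0) {
    n_neg <- round(config$frac_negative_coupling * ncp)
    sign <- rep(1L, ncp)
    if (n_neg > 0) sign[sample.int(ncp, n_neg)] <- -1L
    coupled <- data.frame(mirna = sample(mirna_ids, ncp),
                          gene = sample(gene_ids, ncp),
                          sign = sign, stringsAsFactors = FALSE)
  } else {
    coupled <- data.frame(mirna = character(0), gene = character(0),
                          sign = integer(0), stringsAsFactors = FALSE)
  }
  castes <- unique(make_design(config)$caste)
  pick_de <- function(ids, exclude) {
    pool <- setdiff(ids, exclude)
    n_de <- round(config$de_fraction * length(ids))
    n_de <- min(n_de, length(pool))
    if (n_de == 0) {
      return(data.frame(feature = character(0), caste = character(0),
                        direction = integer(0), stringsAsFactors = FALSE))
    }
    data.frame(
      feature = sample(pool, n_de),
      caste = sample(castes, n_de, replace = TRUE),
      direction = sample(c(1L, -1L), n_de, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  de_mirna <- pick_de(mirna_ids, coupled$mirna)
  de_mrna <- pick_de(gene_ids, coupled$gene)

  comps <- caste_comparisons(castes)
  de_features <- lapply(comps, function(cmp) {
    fs <- strsplit(cmp, "_vs_")[[1]]
    both <- rbind(de_mirna, de_mrna)
    keep <- both$caste %in% fs
    both <- both[keep, , drop = FALSE]
    if (nrow(both) == 0) {
      return(data.frame(feature = character(0), expected = character(0),
                        stringsAsFactors = FALSE))
    }
    # direction is relative to the second caste of the comparison
    up_in_second <- (both$caste == fs[2] & both$direction > 0) |
      (both$caste == fs[1] & both$direction < 0)
    data.frame(feature = both$feature,
               expected = ifelse(up_in_second, "up", "down"),
               stringsAsFactors = FALSE)
  })
  names(de_features) <- comps

  structure(list(
    mirna_ids = mirna_ids, gene_ids = gene_ids,
    coupled_pairs = coupled,
    de_mirna = de_mirna, de_mrna = de_mrna,
    de_features = de_features,
    planted_sites = NULL, methylated_genes = NULL
  ), class = "synth_truth")
}

#' Canonical pairwise comparisons for a set of castes
#'
#' For the three-caste design the order is drone-vs-queen, drone-vs-worker,
#' queen-vs-worker; log fold changes are always reported for the second
#' caste relative to the first.
#'
#' @param castes character vector of caste labels.
#' @return character vector of `first_vs_second` comparison names.
#' @export
caste_comparisons <- function(castes) {
  if (setequal(castes, c("queen", "worker", "drone"))) {
    return(c("drone_vs_queen", "drone_vs_worker", "queen_vs_worker"))
  }
  cmb <- utils::combn(sort(castes), 2)
  apply(cmb, 2, function(x) paste(x[1], x[2], sep = "_vs_"))
}
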