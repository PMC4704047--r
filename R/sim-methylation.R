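#' Plant gene-body methylation labels with a target-status odds ratio
#'
#' Draws a methylated-gene set such that the marginal methylation fraction
#' is about `methylation_frac` and the odds of methylation for miRNA target
#' genes versus non-targets is about `methylation_target_or` (an odds ratio
#' below 1 plants the under-representation of targets among methylated
#' genes).
#'
#' @param config a [sim_config()].
#' @param truth a [synth_truth()]; its coupled-pair genes define the target
#'   set unless `targets` is supplied.
#' @param gene_ids the gene universe.
#' @param targets optional explicit target gene set (overrides `truth`).
#' @return character vector of methylated gene IDs (possibly empty).
#' @export
plant_methylation <- function(config, truth = NULL, gene_ids,
                              targets = NULL) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$methylation_frac
  rho <- config$methylation_target_or
  if (m == 0) return(character(0))
  if (m >= 1)
    stop("plant_methylation: methylation_frac must be < 1", call. = FALSE)
  if (is.null(targets)) {
    stopifnot(inherits(truth, "synth_truth"))
    targets <- unique(truth$coupled_pairs$gene)
  }
  targets <- intersect(targets, gene_ids)
  t_frac <- length(targets) / length(gene_ids)
  # p_t/(1-p_t) = rho * p_n/(1-p_n);  t*p_t + (1-t)*p_n = m
  p_t_of <- function(p_n) rho * p_n / (1 - p_n + rho * p_n)
  marginal <- function(p_n) t_frac * p_t_of(p_n) + (1 - t_frac) * p_n - m
  if (t_frac %in% c(0, 1)) {
    p_n <- p_t <- m
  } else {
    sol <- tryCatch(uniroot(marginal, c(1e-12, 1 - 1e-12), tol = 1e-12),
                    error = function(e) NULL)
    if (is.null(sol))
      stop("plant_methylation: infeasible (odds ratio, fraction) ",
           "combination", call. = FALSE)
    p_n <- sol$root
    p_t <- p_t_of(p_n)
    if (p_t < 0 || p_t > 1)
      stop("plant_methylation: infeasible (odds ratio, fraction) ",
           "combination", call. = FALSE)
  }
  set.seed(derive_seed(config$master_seed, 4L))
  p <- ifelse(gene_ids %in% targets, p_t, p_n)
  gene_ids[runif(length(gene_ids)) < p]
}

#' Generate a synthetic gene-to-term annotation map
#'
#' Terms get sizes drawn uniformly from `config$term_size_range` and member
#' genes sampled uniformly from the gene universe; a plain stand-in for a
#' GO/KEGG-style annotation used to exercise the enrichment stage.
#'
#' @param config a [sim_config()].
#' @param gene_ids gene universe.
#' @return named list mapping term IDs to character vectors of gene IDs.
#' @export
synth_term_map <- function(config, gene_ids) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$master_seed, 5L))
  rng <- config$term_size_range
  terms <- lapply(seq_len(config$n_terms), function(i) {
    size <- min(length(gene_ids), sample(rng[1]:rng[2], 1L))
    sort(sample(gene_ids, size))
  })
  names(terms) <- sprintf("TERM:%04d", seq_len(config$n_terms))
  terms
}
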