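#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  The defaults describe
#' the study design the package emulates: three honeybee castes (queen,
#' worker, drone) with five biological replicates each, negative-binomial
#' counts (variance \eqn{\mu + \phi\mu^2}), a planted fraction of 4-fold
#' differentially expressed features, planted miRNA-target couplings with a
#' target expression correlation of 0.95, and a planted odds ratio of 0.3 for
#' the methylation status of target genes.
#'
#' @param master_seed integer; single seed from which all stream seeds are
#'   derived.
#' @param n_castes,n_reps design size; `n_castes = 3` uses the caste labels
#'   queen/worker/drone.
#' @param n_mirnas,n_genes numbers of miRNA and mRNA features.
#' @param nb_dispersion negative-binomial dispersion \eqn{\phi} (variance
#'   \eqn{\mu + \phi\mu^2}); a scalar, or a vector recycled per feature.
#' @param de_fraction fraction of features (per matrix) given a caste effect.
#' @param de_log2fc planted log2 fold change magnitude (2 = 4-fold).
#' @param n_coupled_pairs number of planted (miRNA, gene) couplings; pairs
#'   are disjoint on both sides.
#' @param coupling_r target magnitude of the log-expression Pearson
#'   correlation of a coupled pair, in (-1, 1).
#' @param frac_negative_coupling fraction of couplings with negative sign.
#' @param utr_len length (bases) of annotated 3'UTRs.
#' @param frac_no_utr fraction of genes without an annotated 3'UTR, which
#'   exercises the 500-bp downstream fallback of the target-region extractor.
#' @param methylation_frac marginal fraction of methylated genes.
#' @param methylation_target_or planted odds ratio of methylation for target
#'   genes versus non-targets (< 1 plants under-representation).
#' @param mirna_len length of mature miRNA sequences.
#' @param mean_count_mirna,mean_count_mrna median expected count per feature
#'   at the nominal library size (log-normal across features, sdlog 1).
#' @param lib_size_mirna,lib_size_mrna nominal library sizes; realised sizes
#'   are log-normal around these (sdlog 0.2) to exercise normalization.
#' @param n_terms,term_size_range gene-set annotation generator: number of
#'   terms and the range of term sizes.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(master_seed = 1L,
                       n_castes = 3L, n_reps = 5L,
                       n_mirnas = 200L, n_genes = 3000L,
                       nb_dispersion = 0.1,
                       de_fraction = 0.05, de_log2fc = 2,
                       n_coupled_pairs = 60L, coupling_r = 0.95,
                       frac_negative_coupling = 0.3,
                       utr_len = 200L, frac_no_utr = 0.2,
                       methylation_frac = 1 / 6,
                       methylation_target_or = 0.3,
                       mirna_len = 22L,
                       mean_count_mirna = 150, mean_count_mrna = 80,
                       lib_size_mirna = 1e6, lib_size_mrna = 5e6,
                       n_terms = 40L, term_size_range = c(10L, 200L)) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    n_castes = as.integer(n_castes), n_reps = as.integer(n_reps),
    n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
    nb_dispersion = nb_dispersion,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    n_coupled_pairs = as.integer(n_coupled_pairs), coupling_r = coupling_r,
    frac_negative_coupling = frac_negative_coupling,
    utr_len = as.integer(utr_len), frac_no_utr = frac_no_utr,
    methylation_frac = methylation_frac,
    methylation_target_or = methylation_target_or,
    mirna_len = as.integer(mirna_len),
    mean_count_mirna = mean_count_mirna, mean_count_mrna = mean_count_mrna,
    lib_size_mirna = lib_size_mirna, lib_size_mrna = lib_size_mrna,
    n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range)
  )
  counts <- c("n_castes", "n_reps", "n_mirnas", "n_genes", "utr_len",
              "mirna_len", "n_terms")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("sim_config: '", nm, "' must be a positive count", call. = FALSE)
  }
  if (cfg$n_coupled_pairs < 0L ||
      cfg$n_coupled_pairs > cfg$n_mirnas * cfg$n_genes)
    stop("sim_config: n_coupled_pairs out of range", call. = FALSE)
  props <- c("de_fraction", "frac_negative_coupling", "methylation_frac",
             "frac_no_utr")
  for (nm in props) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("sim_config: '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (abs(cfg$coupling_r) >= 1)
    stop("sim_config: |coupling_r| must be < 1", call. = FALSE)
  if (any(cfg$nb_dispersion < 0))
    stop("sim_config: nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$methylation_target_or <= 0)
    stop("sim_config: methylation_target_or must be positive", call. = FALSE)
  if (cfg$mirna_len < 18L || cfg$mirna_len > 30L)
    stop("sim_config: mirna_len must be in 18..30", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Sample design for the caste experiment
#'
#' Lays out `n_castes * n_reps` samples with caste and replicate labels.
#' With three castes the labels are queen, worker, drone — the design of the
#' larval study this package emulates (five biological replicates per caste,
#' each a pool of five larvae).
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns `sample`, `caste`, `replicate`, one row
#'   per sample, in deterministic order.
#' @export
make_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_castes < 2L || config$n_reps < 2L)
    stop("make_design: need at least 2 castes and 2 replicates", call. = FALSE)
  castes <- if (config$n_castes == 3L) {
    c("queen", "worker", "drone")
  } else {
    sprintf("caste%d", seq_len(config$n_castes))
  }
  data.frame(
    sample = sprintf("%s_r%d", rep(castes, each = config$n_reps),
                     rep(seq_len(config$n_reps), config$n_castes)),
    caste = rep(castes, each = config$n_reps),
    replicate = rep(seq_len(config$n_reps), config$n_castes),
    stringsAsFactors = FALSE
  )
}
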