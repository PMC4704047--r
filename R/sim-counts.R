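# Negative-binomial count simulation with planted caste effects and planted
# miRNA-gene couplings.

# Calibrate the latent-factor loading (log2 scale) so the expected
# log-expression Pearson correlation of a coupled pair is ~ r.  With
# loadings a_x^2 = c * v_x and a_y^2 = c * v_y (v = per-feature noise
# variance of log2 counts), the correlation is c / (c + 1), so c = r/(1-r).
# v depends on a through the counts' harmonic mean, hence the fixed point.
.calibrate_loading <- function(mu0, phi, r) {
  cc <- r / (1 - r)
  ln2 <- log(2)
  a2 <- cc * (1 / mu0 + phi) / ln2^2
  for (it in 1:40) {
    # E[1/2^(a f)] for f ~ N(0,1); capped because the log-CPM pseudocount
    # saturates shot noise at the low-count tail anyway
    inflate <- min(exp(a2 * ln2^2 / 2), 4)
    v <- (inflate / mu0 + phi) / ln2^2
    a2_new <- cc * v
    if (abs(a2_new - a2) < 1e-10) break
    a2 <- a2_new
  }
  sqrt(a2)
}

#' Simulate miRNA and mRNA count matrices
#'
#' Counts are negative-binomial with variance \eqn{\mu + \phi\mu^2}.
#' Planted DE features get a multiplicative effect of
#' \eqn{2^{\pm de\_log2fc}} in their assigned caste.  Each coupled
#' (miRNA, gene) pair shares a per-sample standard-normal latent factor on
#' the log2-mean scale, scaled by a numerically calibrated loading so that
#' the expected log-expression correlation is about `coupling_r` and signed
#' per the truth.  The factor is centred within each caste, so coupling
#' introduces no between-caste signal.  Library sizes are log-normal around
#' the nominal values to exercise normalization.
#'
#' @param config a [sim_config()].
#' @param design the output of [make_design()] for the same config.
#' @param truth the matching [synth_truth()].
#' @return a list with `mirna` and `mrna`, each a [count_matrix()].
#' @export
synth_counts <- function(config, design, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synth_truth"))
  if (!all(c("sample", "caste") %in% names(design)))
    stop("synth_counts: design must have sample and caste columns",
         call. = FALSE)
  bad <- c(setdiff(truth$coupled_pairs$mirna, truth$mirna_ids),
           setdiff(truth$coupled_pairs$gene, truth$gene_ids))
  if (length(bad))
    stop("synth_counts: truth references unknown feature IDs", call. = FALSE)
  set.seed(derive_seed(config$master_seed, 3L))
  ns <- nrow(design)

  # one latent factor per coupled pair, caste-centred, unit variance
  ncp <- nrow(truth$coupled_pairs)
  latent <- NULL
  if (ncp > 0) {
    latent <- matrix(rnorm(ncp * ns), ncp, ns)
    for (ca in unique(design$caste)) {
      idx <- which(design$caste == ca)
      latent[, idx] <- latent[, idx, drop = FALSE] -
        rowMeans(latent[, idx, drop = FALSE])
    }
    shrink <- sqrt(1 - 1 / max(table(design$caste)))
    latent <- latent / shrink
  }

  gen_matrix <- function(ids, median_count, lib_nominal, de_df,
                         coupled_idx, coupled_sign) {
    nf <- length(ids)
    phi <- rep_len(config$nb_dispersion, nf)
    mu0 <- rlnorm(nf, log(median_count), 1)
    # coupled features get a comfortably expressed baseline so the planted
    # correlation is not drowned by shot noise at low counts
    mu0[coupled_idx > 0] <- pmax(mu0[coupled_idx > 0], 50)
    libs <- rlnorm(ns, log(lib_nominal), 0.2)
    log2mu <- outer(log2(mu0), log2(libs / lib_nominal), `+`)
    if (nrow(de_df)) {
      fi <- match(de_df$feature, ids)
      for (j in seq_len(nrow(de_df))) {
        cols <- which(design$caste == de_df$caste[j])
        log2mu[fi[j], cols] <- log2mu[fi[j], cols] +
          de_df$direction[j] * config$de_log2fc
      }
    }
    if (!is.null(latent)) {
      for (i in which(coupled_idx > 0)) {
        a <- .calibrate_loading(mu0[i], phi[i], abs(config$coupling_r))
        log2mu[i, ] <- log2mu[i, ] +
          coupled_sign[i] * a * latent[coupled_idx[i], ]
      }
    }
    mu <- 2^log2mu
    counts <- matrix(0L, nf, ns, dimnames = list(ids, design$sample))
    size <- 1 / pmax(phi, 1e-12)  # phi = 0 degenerates to Poisson
    for (s in seq_len(ns)) {
      counts[, s] <- rnbinom(nf, size = size, mu = mu[, s])
    }
    storage.mode(counts) <- "integer"
    count_matrix(counts, design)
  }

  cp <- truth$coupled_pairs
  mir_cidx <- match(truth$mirna_ids, cp$mirna); mir_cidx[is.na(mir_cidx)] <- 0L
  gene_cidx <- match(truth$gene_ids, cp$gene); gene_cidx[is.na(gene_cidx)] <- 0L
  mir_sign <- rep(1L, length(truth$mirna_ids))  # miRNA side carries +a f
  gene_sign <- ifelse(gene_cidx > 0, cp$sign[pmax(gene_cidx, 1L)], 1L)

  mirna <- gen_matrix(truth$mirna_ids, config$mean_count_mirna,
                      config$lib_size_mirna, truth$de_mirna,
                      mir_cidx, mir_sign)
  mrna <- gen_matrix(truth$gene_ids, config$mean_count_mrna,
                     config$lib_size_mrna, truth$de_mrna,
                     gene_cidx, gene_sign)
  list(mirna = mirna, mrna = mrna)
}
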