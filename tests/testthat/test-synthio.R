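# Synthetic-data generator: design, sequences, counts, methylation.

test_that("make_design lays out the caste experiment and is deterministic", {
  d <- make_design(sim_config())
  expect_equal(nrow(d), 15L)
  expect_equal(unname(table(d$caste)[c("queen", "worker", "drone")]),
               rep(5L, 3), ignore_attr = TRUE)
  d2 <- make_design(sim_config(master_seed = 99L))  # seed-independent
  expect_identical(d$caste, d2$caste)
  expect_equal(nrow(make_design(sim_config(n_castes = 2, n_reps = 2))), 4L)
  expect_error(sim_config(n_reps = 0), "positive count")
})

test_that("planted sites carry the seed complement; no-UTR genes lack a 3'UTR feature", {
  seqs <- synth_sequences(small_sim())
  tr <- seqs$truth
  expect_gt(nrow(tr$planted_sites), 0)
  for (j in seq_len(nrow(tr$planted_sites))) {
    m <- seqs$mirnas[[tr$planted_sites$mirna[j]]]
    region <- seqs$regions[[tr$planted_sites$gene[j]]]
    seed_rc <- beemirnet:::.rc_dna(chartr("U", "T", substr(m, 2, 8)))
    expect_true(grepl(seed_rc, region, fixed = TRUE))
  }
  ann <- seqs$annotation
  no_utr <- setdiff(ann$genes$gene_id, ann$utr3$gene_id)
  expect_gt(length(no_utr), 0)
  expect_true(all(no_utr %in% ann$cds$gene_id))
  # decoy regions carry no seed core of any coupled miRNA
  for (m_id in tr$coupled_pairs$mirna) {
    core <- beemirnet:::.rc_dna(chartr("U", "T",
                                       substr(seqs$mirnas[[m_id]], 2, 7)))
    partner <- tr$coupled_pairs$gene[tr$coupled_pairs$mirna == m_id]
    decoys <- seqs$regions[setdiff(names(seqs$regions), partner)]
    expect_false(any(grepl(core, decoys, fixed = TRUE)))
  }
})

test_that("the generator is byte-identical under one master seed", {
  d1 <- file.path(tempdir(), "gen_a"); d2 <- file.path(tempdir(), "gen_b")
  synth_dataset(small_sim(seed = 5L), d1)
  synth_dataset(small_sim(seed = 5L), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("counts approach the Poisson limit as dispersion vanishes", {
  cfg <- sim_config(master_seed = 3L, n_mirnas = 2L, n_genes = 1200L,
                    n_coupled_pairs = 0L, nb_dispersion = 0,
                    de_fraction = 0, mean_count_mrna = 500)
  cm <- synth_counts(cfg, make_design(cfg), synth_truth(cfg))$mrna
  # per-feature expected counts differ by sample only through library size;
  # rescale out the library factor, then pool variance/mean over features
  libs <- colSums(cm$counts)
  sc <- sweep(cm$counts, 2, mean(libs) / libs, `*`)
  ratio <- apply(sc, 1, stats::var) / rowMeans(sc)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("null features have equal caste means within sampling error", {
  cfg <- sim_config(master_seed = 8L, n_mirnas = 2L, n_genes = 400L,
                    n_coupled_pairs = 0L, de_fraction = 0,
                    mean_count_mrna = 200)
  cm <- synth_counts(cfg, make_design(cfg), synth_truth(cfg))$mrna
  libs <- colSums(cm$counts)
  sc <- sweep(cm$counts, 2, mean(libs) / libs, `*`)
  by_caste <- vapply(split(seq_len(ncol(sc)), cm$design$caste),
                     function(ix) rowMeans(sc[, ix, drop = FALSE]),
                     numeric(nrow(sc)))
  grand <- rowMeans(by_caste)
  rel_dev <- abs(by_caste - grand) / grand
  expect_lt(stats::median(rel_dev), 0.2)
})

test_that("planted couplings reach their target correlation (Monte Carlo)", {
  hits <- 0L; mean_r <- numeric(0)
  for (s in 1:100) {
    # enough background features that library sizes are stable
    cfg <- sim_config(master_seed = 1000L + s, n_mirnas = 30L,
                      n_genes = 100L, n_coupled_pairs = 3L,
                      de_fraction = 0)
    design <- make_design(cfg)
    tr <- synth_truth(cfg)
    cm <- synth_counts(cfg, design, tr)
    lm_mir <- normalize_log_cpm(cm$mirna)$logcpm
    lm_g <- normalize_log_cpm(cm$mrna)$logcpm
    r <- vapply(seq_len(nrow(tr$coupled_pairs)), function(j) {
      cor(lm_mir[tr$coupled_pairs$mirna[j], ],
          lm_g[tr$coupled_pairs$gene[j], ])
    }, numeric(1))
    signed_ok <- sign(r) == tr$coupled_pairs$sign
    hits <- hits + sum(abs(r) > 0.5 & signed_ok)
    mean_r <- c(mean_r, abs(r))
  }
  # empirical |r| > 0.5 in at least 95% of planted pairs across seeds
  expect_gte(hits / length(mean_r), 0.95)
  # calibration: mean |r| within 0.1 of the 0.95 target
  expect_lt(abs(mean(mean_r) - 0.95), 0.1)
})

test_that("plant_methylation respects the marginal fraction and odds ratio", {
  genes <- sprintf("g%05d", 1:4000)
  targets <- genes[1:600]
  cfg <- sim_config(master_seed = 2L, methylation_frac = 0.25,
                    methylation_target_or = 1)
  meth <- plant_methylation(cfg, gene_ids = genes, targets = targets)
  r_t <- mean(targets %in% meth)
  r_n <- mean(setdiff(genes, targets) %in% meth)
  expect_lt(abs(r_t - r_n), 0.06)  # ~3 binomial SE at these sizes
  expect_equal(mean(genes %in% meth), 0.25, tolerance = 0.05)

  cfg_or <- sim_config(master_seed = 2L, methylation_frac = 0.25,
                       methylation_target_or = 0.3)
  meth_or <- plant_methylation(cfg_or, gene_ids = genes, targets = targets)
  odds <- function(p) p / (1 - p)
  or_hat <- odds(mean(targets %in% meth_or)) /
    odds(mean(setdiff(genes, targets) %in% meth_or))
  expect_equal(or_hat, 0.3, tolerance = 0.35)

  cfg0 <- sim_config(master_seed = 2L, methylation_frac = 0)
  expect_identical(plant_methylation(cfg0, gene_ids = genes,
                                     targets = targets), character(0))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(coupling_r = 1), "coupling_r")
  expect_error(sim_config(de_fraction = 1.2), "0, 1")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(synth_sequences(sim_config(utr_len = 20)), "utr_len")
})
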