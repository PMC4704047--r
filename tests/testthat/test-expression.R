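# Filtering, TMM log-CPM, PCA/clustering, NB exact test, dispersion, BH.

test_that("the count filter applies the 5-in-5 rule at its boundary", {
  counts <- rbind(
    boundary = c(rep(5L, 5), rep(0L, 10)),   # exactly 5 samples at 5
    high4 = c(rep(100L, 4), rep(0L, 11)),    # high in only 4 samples
    zeros = rep(0L, 15),
    dense = rep(6L, 15))
  m <- toy_counts(counts)
  kept <- filter_low_counts(m)
  expect_setequal(rownames(kept$counts), c("boundary", "dense"))
  expect_identical(colnames(kept$counts), colnames(m$counts))
  expect_warning(filter_low_counts(toy_counts(rbind(z = rep(0L, 15)))),
                 "no feature")
  expect_error(filter_low_counts(m, min_count = 0), ">= 1")
})

test_that("TMM log-CPM: identical samples, doubling cancellation, geometric mean", {
  set.seed(4)
  base <- matrix(rnbinom(200 * 6, mu = 100, size = 10), 200, 6)
  m_same <- toy_counts(matrix(rep(base[, 1], 6), ncol = 6),
                       castes = rep(c("a", "b"), each = 3))
  nrm_same <- normalize_log_cpm(m_same)
  expect_equal(unname(nrm_same$factors), rep(1, 6))

  m1 <- toy_counts(base, castes = rep(c("a", "b"), each = 3))
  doubled <- base; doubled[, 3] <- doubled[, 3] * 2L
  m2 <- toy_counts(doubled, castes = rep(c("a", "b"), each = 3))
  n1 <- normalize_log_cpm(m1); n2 <- normalize_log_cpm(m2)
  # doubling a sample's counts doubles its library size: log-CPM invariant
  expect_equal(n2$logcpm[, 3], n1$logcpm[, 3], tolerance = 1e-9)
  expect_equal(exp(mean(log(n1$factors))), 1, tolerance = 1e-12)
})

test_that("PCA/clustering: duplicates merge first, variance is conserved", {
  set.seed(5)
  x <- matrix(rnorm(50 * 4), 50, 4)
  x <- cbind(x, x[, 4])  # duplicated sample
  colnames(x) <- paste0("s", 1:5)
  qc <- project_pca_and_cluster(x)
  expect_equal(qc$dist["s4", "s5"], 0)
  expect_setequal(abs(qc$hclust$merge[1, ]), c(4, 5))
  # explained variances sum to the total variance of the centered data
  total_var <- sum(apply(t(x), 2, stats::var))
  expect_equal(sum(qc$explained_var), total_var, tolerance = 1e-12)
  # 3-sample toy with two near-identical castes: they merge first
  y <- cbind(a = c(1, 2, 3), b = c(1.01, 2.01, 3.01), c = c(9, 9, 9))
  qc3 <- project_pca_and_cluster(y)
  expect_setequal(abs(qc3$hclust$merge[1, ]), c(1, 2))
  expect_error(project_pca_and_cluster(matrix(1, 3, 3)), "constant")
})

test_that("NB exact test matches its enumeration and binomial oracles", {
  # identical per-sample counts and libsizes in both groups: p = 1
  expect_equal(nb_exact_test(c(5, 7, 9), c(5, 7, 9), rep(100, 3),
                             rep(100, 3), 0.1), 1)
  set.seed(6)
  # enumeration oracle on small totals (equal libsizes so equalization
  # leaves counts untouched)
  for (i in 1:25) {
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    cA <- rpois(nA, 3); cB <- rpois(nB, 3)
    if (sum(cA) + sum(cB) > 30 || sum(cA) + sum(cB) == 0) next
    phi <- sample(c(0, 0.05, 0.3, 1), 1)
    p_pkg <- nb_exact_test(cA, cB, rep(1e5, nA), rep(1e5, nB), phi)
    p_orc <- enum_nb_exact(cA, cB, phi)
    expect_equal(p_pkg, p_orc, tolerance = 1e-9)
  }
  # phi = 0 equals the exact binomial conditional test
  for (i in 1:20) {
    nA <- sample(2:5, 1); nB <- sample(2:5, 1)
    cA <- rpois(nA, 20); cB <- rpois(nB, 20)
    p_pkg <- nb_exact_test(cA, cB, rep(1e5, nA), rep(1e5, nB), 0)
    p_orc <- enum_nb_exact(cA, cB, 0)
    expect_equal(p_pkg, p_orc, tolerance = 1e-6)
  }
  expect_error(nb_exact_test(1:3, 1:3, rep(1, 3), rep(1, 3), -1),
               "dispersion")
})

test_that("NB exact test is symmetric and library-scale invariant", {
  set.seed(7)
  cA <- rpois(5, 40); cB <- rpois(4, 55)
  lA <- runif(5, 0.8e5, 1.2e5); lB <- runif(4, 0.8e5, 1.2e5)
  p1 <- nb_exact_test(cA, cB, lA, lB, 0.2)
  expect_equal(nb_exact_test(cB, cA, lB, lA, 0.2), p1, tolerance = 1e-12)
  # rescaling every library size by one constant changes nothing
  expect_equal(nb_exact_test(cA, cB, 3 * lA, 3 * lB, 0.2), p1,
               tolerance = 1e-12)
})

test_that("common dispersion: degenerate zero, Poisson data, recovery", {
  one <- toy_counts(matrix(7L, 1, 15))
  expect_equal(estimate_common_dispersion(one), 0)

  set.seed(8)
  pois <- toy_counts(matrix(rpois(800 * 15, 60), 800, 15))
  expect_lt(estimate_common_dispersion(pois), 0.05)

  nb <- toy_counts(matrix(rnbinom(2000 * 15, mu = 80, size = 1 / 0.2),
                          2000, 15))
  phi_hat <- estimate_common_dispersion(nb)
  expect_gt(phi_hat, 0.15); expect_lt(phi_hat, 0.25)

  expect_error(estimate_common_dispersion(toy_counts(matrix(0L, 3, 15))),
               "all-zero")
})

test_that("dispersion and exact test broadly agree with edgeR on shared data", {
  set.seed(9)
  counts <- matrix(rnbinom(500 * 10, mu = 100, size = 1 / 0.15), 500, 10)
  m <- toy_counts(counts, castes = rep(c("a", "b"), each = 5))
  phi_hat <- estimate_common_dispersion(m)
  y <- edgeR::DGEList(counts = m$counts,
                      group = m$design$caste)
  y <- edgeR::estimateCommonDisp(y)
  expect_equal(phi_hat, y$common.dispersion, tolerance = 0.25)
  et <- edgeR::exactTest(y, dispersion = phi_hat)
  p_pkg <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(counts[i, 1:5], counts[i, 6:10],
                  colSums(counts)[1:5], colSums(counts)[6:10], phi_hat)
  }, numeric(1))
  # different equalization and tail conventions: demand strong rank
  # agreement rather than numeric identity
  expect_gt(cor(log(p_pkg + 1e-300), log(et$table$PValue + 1e-300),
                method = "spearman"), 0.98)
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(adjust_fdr(0.037), 0.037)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p), brute_bh(p), tolerance = 1e-12)
    expect_equal(adjust_fdr(p), stats::p.adjust(p, "BH"),
                 tolerance = 1e-12)
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})
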