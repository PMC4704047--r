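# Length weights, resampling enrichment, term intersection, Fisher overlap.

test_that("length weights are flat under null selection and monotone under planted bias", {
  set.seed(19)
  genes <- sprintf("g%04d", 1:4000)
  lengths <- setNames(round(stats::rlnorm(4000, log(900), 0.6)), genes)
  sel_null <- sample(genes, 400)
  w_null <- compute_length_weights(sel_null, genes, lengths)
  expect_equal(mean(w_null), 1, tolerance = 1e-9)
  expect_lt(max(w_null) / min(w_null), 1.5)

  # selection probability proportional to length
  p_sel <- lengths / max(lengths)
  sel_bias <- genes[stats::runif(4000) < p_sel * 0.3]
  w_bias <- compute_length_weights(sel_bias, genes, lengths)
  o <- order(lengths)
  expect_true(all(diff(w_bias[o]) >= -1e-12))  # monotone non-decreasing
  expect_gt(w_bias[o][4000] / w_bias[o][1], 2)

  # degenerate: all lengths equal -> single bin -> unit weights
  w_one <- compute_length_weights(sel_null, genes,
                                  setNames(rep(100, 4000), genes))
  expect_true(all(w_one == 1))
  expect_warning(
    compute_length_weights("g0001", genes, lengths[-1]), "without length")
})

test_that("uniform-weight resampling p matches the hypergeometric tail", {
  set.seed(20)
  universe <- sprintf("u%03d", 1:80)
  selected <- sample(universe, 20)
  terms <- lapply(1:8, function(i) sample(universe, sample(6:25, 1)))
  names(terms) <- paste0("T", 1:8)
  n_perm <- 8000L
  res <- enrichment_test(terms, selected, universe, n_perm = n_perm,
                         seed = 101L)
  for (i in seq_len(nrow(res))) {
    nA <- res$n_annotated[i]; obs <- res$n_selected[i]
    p_hyper <- phyper(obs - 1, nA, 80 - nA, 20, lower.tail = FALSE)
    se <- sqrt(p_hyper * (1 - p_hyper) / n_perm)
    expect_lt(abs(res$p[i] - p_hyper), 3 * se + 2 / n_perm)
  }
  # a term holding every selected gene in a small universe: p near 1/(B+1)
  res_min <- enrichment_test(list(all = selected), selected,
                             c(selected, universe[1:5]), n_perm = 1000L,
                             seed = 3L)
  expect_lt(res_min$p, 5 / 1000)
  # zero observed overlap: p ~ 1
  res_zero <- enrichment_test(list(none = setdiff(universe, selected)[1:10]),
                              selected, universe, n_perm = 500L, seed = 4L)
  expect_gt(res_zero$p, 0.9)
  expect_error(enrichment_test(terms, selected, universe, n_perm = 50L),
               "n_perm")
  # determinism under one seed
  res2 <- enrichment_test(terms, selected, universe, n_perm = 500L,
                          seed = 101L)
  res3 <- enrichment_test(terms, selected, universe, n_perm = 500L,
                          seed = 101L)
  expect_identical(res2, res3)
})

test_that("term-set intersection keeps shared terms with provenance", {
  sets <- list(a = c("A", "B"), b = c("B", "C"), c = "B")
  out <- combine_by_go_intersection(sets)
  expect_equal(out$term, "B")
  expect_match(out$methods, "a,b,c")
  same <- combine_by_go_intersection(list(x = c("A", "B"), y = c("A", "B")))
  expect_setequal(same$term, c("A", "B"))
  expect_warning(dis <- combine_by_go_intersection(list(x = "A", y = "B")),
                 "empty")
  expect_equal(nrow(dis), 0L)
  expect_error(combine_by_go_intersection(list(x = "A")), ">= 2")
})

test_that("Fisher overlap: closed form, odds ratio, enumeration oracle", {
  universe <- sprintf("g%02d", 1:10)
  # 5 targets, 5 methylated, overlap 0: one-sided p = C(5,0)C(5,5)/C(10,5)
  ov <- fisher_overlap(universe[1:5], universe[6:10], universe)
  expect_equal(ov$p_under, 1 / 252, tolerance = 1e-12)
  expect_equal(unname(ov$table[1, 1]), 0L)

  # independence-scale table: odds ratio ~ 1
  set.seed(21)
  uni <- sprintf("u%03d", 1:60)
  ov1 <- fisher_overlap(uni[1:30], c(uni[1:15], uni[31:45]), uni)
  expect_equal(ov1$odds_ratio, 1, tolerance = 1e-12)

  # exhaustive-table oracle and agreement with fisher.test (universe <= 60)
  for (i in 1:40) {
    N <- sample(10:60, 1)
    nT <- sample(1:(N - 1), 1); nM <- sample(1:(N - 1), 1)
    u <- sprintf("x%03d", 1:N)
    t_set <- sample(u, nT); m_set <- sample(u, nM)
    ovr <- fisher_overlap(t_set, m_set, u)
    a <- length(intersect(t_set, m_set))
    orc <- enum_fisher(a, nM, nT, N)
    expect_equal(ovr$p_under, orc$under, tolerance = 1e-10)
    expect_equal(ovr$p_two_sided, orc$two, tolerance = 1e-10)
    ft <- stats::fisher.test(ovr$table)
    expect_equal(ovr$p_two_sided, ft$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_overlap("a", "b", character(0)), "universe")
})

test_that("raising the observed overlap never raises the over-representation p", {
  # over-representation p is the upper tail used by enrichment_test's null;
  # check monotonicity on a hypergeometric grid
  for (obs in 0:9) {
    p1 <- phyper(obs - 1, 10, 40, 15, lower.tail = FALSE)
    p2 <- phyper(obs, 10, 40, 15, lower.tail = FALSE)
    expect_lte(p2, p1)
  }
})

test_that("a planted odds ratio of 0.3 is detected downstream", {
  genes <- sprintf("g%04d", 1:3000)
  targets <- genes[1:500]
  hits <- 0L
  for (s in 1:30) {
    cfg <- sim_config(master_seed = 500L + s, methylation_frac = 1 / 6,
                      methylation_target_or = 0.3)
    meth <- plant_methylation(cfg, gene_ids = genes, targets = targets)
    ov <- fisher_overlap(targets, meth, genes)
    hits <- hits + (ov$p_under < 0.01)
  }
  expect_gte(hits / 30, 0.95)
})
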