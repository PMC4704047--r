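# Seed scanning, duplex energies, method profiles and the 2-of-3 consensus.

rc <- beemirnet:::.rc_dna
dna <- function(s) chartr("U", "T", s)

test_that("seed scanning reports the canonical site classes", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  seed78_rc <- rc(dna(substr(m, 2, 8)))            # rc of positions 2-8
  # embed at offset 10 (1-based), pad with a non-complementary background
  region <- paste0(strrep("C", 9), seed78_rc, strrep("C", 20))
  hits <- scan_seed_sites(m, region)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 10L)
  expect_equal(hits$seed_class, "7mer-m8")

  # A opposite position 1 and a 2-8 match: 8mer
  region8 <- paste0(strrep("C", 9), seed78_rc, "A", strrep("C", 20))
  hits8 <- scan_seed_sites(m, region8)
  expect_equal(hits8$seed_class, "8mer")

  # match of 2-7 with the A anchor but a position-8 mismatch: 7mer-A1
  core_rc <- rc(dna(substr(m, 2, 7)))
  regionA1 <- paste0(strrep("C", 9), "G", core_rc, "A", strrep("C", 20))
  hitsA1 <- scan_seed_sites(m, regionA1)
  expect_equal(hitsA1$seed_class, "7mer-A1")
  expect_equal(hitsA1$offset, 11L)

  expect_equal(nrow(scan_seed_sites(m, strrep("C", 60))), 0L)
  expect_error(scan_seed_sites("UGAGGUA", strrep("C", 30)), "8 nt")
})

test_that("duplex energy: perfect-duplex hand sum, bulge, unpairable input", {
  par <- nn_params()
  m <- "GCGGAUGC"             # GC ends: no terminal penalty
  site <- rc(dna(m))
  # hand sum from the embedded table: init + the 7 stack terms
  pairs <- c("GC", "CG", "GC", "GC", "AU", "UA", "GC", "CG")
  hand <- par$init + sum(vapply(1:7, function(i)
    par$stack[pairs[i], pairs[i + 1]], numeric(1)))
  expect_equal(duplex_delta_g(m, site), hand, tolerance = 1e-12)

  # one extra unpaired target base between stacks: exactly the
  # bulge-opening cost replaces the broken stack
  site_bulge <- paste0(substr(site, 1, 4), "A", substr(site, 5, 8))
  # the bulge sits between the pairs of miRNA positions 4 and 5, breaking
  # the GC/AU stack
  lost_stack <- par$stack["GC", "AU"]
  expect_equal(duplex_delta_g(m, site_bulge),
               hand - lost_stack + par$loop_open, tolerance = 1e-12)

  # no pair can form at all
  expect_equal(duplex_delta_g("AAAA", "CCCC"), Inf)
  expect_error(duplex_delta_g("ANAA", "UUUU"), "characters")
  expect_error(duplex_delta_g("AAAAAAAA", "UU"), "shorter")
})

test_that("duplex DP equals exhaustive enumeration on short sequences", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(3:6, 1); L <- sample(3:6, 1)
    m <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    for (w in c(1, 1.5)) {
      dp <- beemirnet:::.duplex_dp(
        beemirnet:::.encode_seq(m), beemirnet:::.encode_seq(s),
        nn_params()$stack, nn_params()$init, nn_params()$end_penalty,
        nn_params()$loop_open, nn_params()$loop_extend,
        nn_params()$max_loop, w, 8L)
      expect_equal(dp, enum_duplex_dg(m, s, nn_params(), w),
                   tolerance = 1e-9)
    }
  }
})

test_that("appending complementary bases never increases the duplex energy", {
  set.seed(14)
  for (i in 1:15) {
    m <- paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
    site <- rc(dna(m))
    prev <- Inf
    for (k in 8:12) {
      dg <- duplex_delta_g(substr(m, 1, k), rc(dna(substr(m, 1, k))))
      expect_lte(dg, prev + 1e-12)
      prev <- dg
    }
  }
})

test_that("free-energy thresholds accept at the boundary and reject above it", {
  m <- "GCGGAUGCGGAUCCGGAUGCAG"
  site <- rc(dna(m))
  region <- paste0(strrep("C", 10), site, strrep("C", 10))
  dg <- duplex_delta_g(m, site)
  make_profile <- function(threshold) {
    list(name = "custom", max_free_energy = threshold, seed_weight = 1,
         opening = FALSE)
  }
  mirnas <- c(mir = m)
  regions <- c(gene = region)
  # equality: a site exactly at the threshold is emitted
  expect_equal(nrow(predict_targets(mirnas, regions, make_profile(dg))), 1L)
  # just below the threshold magnitude: rejected
  expect_equal(nrow(predict_targets(mirnas, regions,
                                    make_profile(dg + 1e-6))), 1L)
  expect_equal(nrow(predict_targets(mirnas, regions,
                                    make_profile(dg - 1e-6))), 0L)
  # the stated profile thresholds behave as "accept iff deltaG <= -X"
  for (pn in names(method_profiles())) {
    th <- method_profiles()[[pn]]$max_free_energy
    out <- predict_targets(mirnas, regions, pn)
    if (nrow(out)) expect_true(all(out$deltaG <= th))
  }
  expect_error(predict_targets(mirnas, regions, "nonsense"), "unknown")
})

test_that("generated planted pairs pass all three profiles; decoys are rare", {
  seqs <- synth_sequences(small_sim(seed = 77L))
  tr <- seqs$truth
  regions <- extract_target_regions(seqs$annotation, seqs$genome)
  planted_keys <- paste(tr$planted_sites$mirna, tr$planted_sites$gene)
  for (pn in names(method_profiles())) {
    out <- predict_targets(seqs$mirnas, regions, pn)
    keys <- paste(out$mirna, out$gene)
    expect_true(all(planted_keys %in% keys), label = pn)
  }
  cons <- consensus_pairs(lapply(names(method_profiles()), function(pn)
    predict_targets(seqs$mirnas, regions, pn)))
  cons_keys <- paste(cons$mirna, cons$gene)
  expect_true(all(planted_keys %in% cons_keys))
  n_possible <- length(seqs$mirnas) * length(regions)
  decoy_rate <- sum(!cons_keys %in% planted_keys) /
    (n_possible - length(planted_keys))
  expect_lt(decoy_rate, 0.05)
})

test_that("the 2-of-3 consensus is correct for all membership patterns", {
  mk <- function(method, pairs) {
    if (length(pairs) == 0) {
      return(data.frame(mirna = character(0), gene = character(0),
                        method = character(0), offset = integer(0),
                        seed_class = character(0), deltaG = numeric(0)))
    }
    data.frame(mirna = "m1", gene = pairs, method = method, offset = 1L,
               seed_class = "7mer-m8", deltaG = -30,
               stringsAsFactors = FALSE)
  }
  # genes p000..p111 encode membership in (acc, align, hyb)
  patterns <- expand.grid(acc = 0:1, ali = 0:1, hyb = 0:1)
  genes <- sprintf("p%d%d%d", patterns$acc, patterns$ali, patterns$hyb)
  lists <- list(
    mk("accessibility", genes[patterns$acc == 1]),
    mk("alignment", genes[patterns$ali == 1]),
    mk("hybridization", genes[patterns$hyb == 1]))
  cons <- consensus_pairs(lists)
  expected <- genes[rowSums(patterns) >= 2]
  expect_setequal(cons$gene, expected)
  expect_equal(cons$n_methods[match(sort(expected), cons$gene)],
               sort(rowSums(patterns)[rowSums(patterns) >= 2]),
               ignore_attr = TRUE)
  # order invariance and kept+dropped = nominated
  cons_perm <- consensus_pairs(lists[c(3, 1, 2)])
  expect_equal(cons_perm, cons)
  nominated <- unique(unlist(lapply(lists, `[[`, "gene")))
  dropped <- setdiff(nominated, cons$gene)
  expect_setequal(c(cons$gene, dropped), nominated)
})
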