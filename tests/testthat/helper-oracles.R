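# Independent oracles used by the unit and acceptance tests.  Each is a
# deliberately naive implementation (brute force, enumeration, closed form)
# kept separate from the package's code paths.

# Benjamini-Hochberg step-up by the literal double-loop definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# Fisher one-/two-sided p by exhaustive enumeration over all feasible
# 2x2 tables at fixed margins (universe N, nM methylated, nT targets,
# observed overlap a); probability of a table from the explicit
# choose-form hypergeometric
enum_fisher <- function(a, nM, nT, N) {
  support <- max(0, nT + nM - N):min(nT, nM)
  pr <- vapply(support, function(x) {
    exp(lchoose(nM, x) + lchoose(N - nM, nT - x) - lchoose(N, nT))
  }, numeric(1))
  p_obs <- pr[match(a, support)]
  list(under = sum(pr[support <= a]),
       two = min(1, sum(pr[pr <= p_obs * (1 + 1e-7)])))
}

# conditional NB exact p by explicit lgamma-form pmf enumeration
# (doubled smaller tail, capped at 1) on already-equalized counts
enum_nb_exact <- function(countsA, countsB, phi) {
  nA <- length(countsA); nB <- length(countsB)
  sA <- sum(countsA); s <- sA + sum(countsB)
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  a <- 0:s
  if (phi <= 0) {
    lp <- lchoose(s, a) + a * log(nA / (nA + nB)) +
      (s - a) * log(nB / (nA + nB))
  } else {
    nb_lpmf <- function(x, size, mu) {
      lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
        size * log(size / (size + mu)) + x * log(mu / (size + mu))
    }
    lp <- nb_lpmf(a, nA / phi, nA * mu) + nb_lpmf(s - a, nB / phi, nB * mu)
  }
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  min(1, 2 * min(sum(pr[a <= sA]), sum(pr[a >= sA])))
}

# duplex minimum free energy by exhaustive enumeration of all monotone
# antiparallel matchings (gap per side bounded by params$max_loop),
# scored by direct summation of the same energy terms
enum_duplex_dg <- function(mirna_seq, site_seq, params = nn_params(),
                           seed_weight = 1) {
  code <- c(A = "A", C = "C", G = "G", U = "U", T = "U")
  m <- code[strsplit(toupper(mirna_seq), "")[[1]]]
  t_rev <- rev(code[strsplit(toupper(site_seq), "")[[1]]])
  pt <- function(a, b) {
    k <- paste0(a, b)
    if (k %in% c("AU", "UA", "GC", "CG", "GU", "UG")) k else NA_character_
  }
  n <- length(m); L <- length(t_rev)
  best <- Inf
  weak <- function(p) p %in% c("AU", "UA", "GU", "UG")
  score_chain <- function(chain) {
    p1 <- pt(m[chain[1, 1]], t_rev[chain[1, 2]])
    e <- params$init + if (weak(p1)) params$end_penalty else 0
    if (nrow(chain) > 1) {
      for (r in 2:nrow(chain)) {
        gi <- chain[r, 1] - chain[r - 1, 1] - 1
        gk <- chain[r, 2] - chain[r - 1, 2] - 1
        pa <- pt(m[chain[r - 1, 1]], t_rev[chain[r - 1, 2]])
        pb <- pt(m[chain[r, 1]], t_rev[chain[r, 2]])
        if (gi == 0 && gk == 0) {
          st <- params$stack[pa, pb]
          if (chain[r, 1] <= 8) st <- st * seed_weight
          e <- e + st
        } else {
          e <- e + params$loop_open + params$loop_extend * (gi + gk - 1)
        }
      }
    }
    pl <- pt(m[chain[nrow(chain), 1]], t_rev[chain[nrow(chain), 2]])
    e + if (weak(pl)) params$end_penalty else 0
  }
  recurse <- function(chain, i0, k0) {
    for (i in i0:n) {
      if (nrow(chain) > 0 && i - chain[nrow(chain), 1] - 1 > params$max_loop)
        break
      for (k in k0:L) {
        if (nrow(chain) > 0 &&
            k - chain[nrow(chain), 2] - 1 > params$max_loop) break
        if (is.na(pt(m[i], t_rev[k]))) next
        new_chain <- rbind(chain, c(i, k))
        e <- score_chain(new_chain)
        if (e < best) best <<- e
        if (i < n && k < L) recurse(new_chain, i + 1, k + 1)
      }
    }
  }
  if (n >= 1 && L >= 1) recurse(matrix(numeric(0), 0, 2), 1, 1)
  best
}

# quick count_matrix fixture
toy_counts <- function(counts, castes = NULL) {
  if (is.null(castes))
    castes <- rep(c("queen", "worker", "drone"),
                  each = ncol(counts) / 3)
  design <- data.frame(sample = paste0("s", seq_len(ncol(counts))),
                       caste = castes,
                       replicate = seq_len(ncol(counts)),
                       stringsAsFactors = FALSE)
  colnames(counts) <- design$sample
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  storage.mode(counts) <- "integer"
  count_matrix(counts, design)
}

# small simulation config shared by several tests
small_sim <- function(seed = 42L, ...) {
  sim_config(master_seed = seed, n_mirnas = 20L, n_genes = 80L,
             n_coupled_pairs = 8L, n_terms = 8L, ...)
}
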