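# miRNA target prediction: seed-site nomination, duplex free energy, three
# method profiles sharing one scanner/energy core, and the 2-of-3 consensus.

.BASE_CODE <- c(A = 0L, C = 1L, G = 2L, U = 3L, T = 3L)

.encode_seq <- function(s) {
  v <- .BASE_CODE[strsplit(toupper(s), "")[[1]]]
  if (any(is.na(v)))
    stop("sequence contains characters outside {A,C,G,U,T}", call. = FALSE)
  unname(v)
}

# target (DNA) characters pairing a given miRNA base; wobble adds G:U
.pairing_chars <- function(base, allow_gu) {
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  out <- wc[[base]]
  if (allow_gu) {
    if (base == "G") out <- c(out, "T")
    if (base == "U") out <- c(out, "G")
  }
  out
}

# regex (lookahead, overlapping) matching the reverse complement of
# mirna[from..to] in a DNA region
.seed_pattern <- function(mirna_chars, from, to, allow_gu) {
  cls <- vapply(rev(seq(from, to)), function(i) {
    ch <- .pairing_chars(mirna_chars[i], allow_gu)
    if (length(ch) == 1) ch else paste0("[", paste(ch, collapse = ""), "]")
  }, character(1))
  paste0("(?=", paste(cls, collapse = ""), ")")
}

# all seed sites of one miRNA across many regions; offsets are 1-based
# positions of the 6-mer core match (reverse complement of positions 2-7)
.scan_many <- function(mirna_seq, regions, allow_gu = FALSE) {
  mc <- strsplit(toupper(chartr("T", "U", mirna_seq)), "")[[1]]
  if (length(mc) < 8)
    stop("scan_seed_sites: miRNA must be at least 8 nt", call. = FALSE)
  pat <- .seed_pattern(mc, 2, 7, allow_gu)
  hits <- gregexpr(pat, regions, perl = TRUE)
  m8_chars <- .pairing_chars(mc[8], allow_gu)
  out <- lapply(seq_along(regions), function(g) {
    st <- hits[[g]]
    if (st[1] == -1L) return(NULL)
    st <- as.integer(st)
    r <- regions[[g]]
    m8 <- st > 1L & substr(rep(r, length(st)), st - 1L, st - 1L) %in% m8_chars
    a1 <- substring(r, st + 6L, st + 6L) == "A"
    keep <- m8 | a1
    if (!any(keep)) return(NULL)
    data.frame(gene = names(regions)[g], core_start = st[keep],
               m8 = m8[keep], a1 = a1[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), core_start = integer(0),
                      m8 = logical(0), a1 = logical(0),
                      stringsAsFactors = FALSE)
  }
  out$seed_class <- ifelse(out$m8 & out$a1, "8mer",
                           ifelse(out$m8, "7mer-m8", "7mer-A1"))
  out$offset <- ifelse(out$m8, out$core_start - 1L, out$core_start)
  out
}

#' Scan a target region for canonical seed sites
#'
#' Reports every offset where the region contains the reverse complement of
#' miRNA positions 2-8 (7mer-m8), of positions 2-7 with a target A opposite
#' position 1 (7mer-A1), or both (8mer).  T and U are interchangeable on
#' input; G:U wobble pairing in the seed is off unless `allow_gu = TRUE`.
#'
#' @param mirna_seq mature miRNA, 5'->3'.
#' @param region_seq target region, 5'->3'.
#' @param allow_gu allow G:U wobble in seed matching.
#' @return data.frame with columns `offset` (1-based start of the matched
#'   seed), `seed_class`.
#' @export
scan_seed_sites <- function(mirna_seq, region_seq, allow_gu = FALSE) {
  region <- chartr("U", "T", toupper(region_seq))
  hits <- .scan_many(mirna_seq, setNames(region, "region"), allow_gu)
  hits[order(hits$offset), c("offset", "seed_class")]
}

#' Duplex minimum free energy by nearest-neighbour dynamic programming
#'
#' Minimum free energy (kcal/mol) of the intermolecular duplex between a
#' miRNA and a target site context, allowing Watson-Crick and G:U pairs and
#' affine bulges/internal loops, including the initiation term and terminal
#' AU/GU penalties of the embedded parameter table.  A gapless perfect
#' duplex scores initiation + the sum of its stack terms (+ end penalties).
#'
#' @param mirna_seq miRNA, 5'->3' (RNA; T accepted).
#' @param site_seq target site context, 5'->3' (DNA or RNA).
#' @param params energy parameters, see [nn_params()].
#' @param seed_weight multiplier on stack terms wholly within the seed
#'   (miRNA positions 1-8); 1 for plain hybridization energy.
#' @return the free energy, or `Inf` when no base pair can form.
#' @export
duplex_delta_g <- function(mirna_seq, site_seq, params = nn_params(),
                           seed_weight = 1) {
  if (nchar(site_seq) < nchar(mirna_seq))
    stop("duplex_delta_g: site context shorter than the miRNA",
         call. = FALSE)
  .duplex_dp(.encode_seq(mirna_seq), .encode_seq(site_seq), params$stack,
             params$init, params$end_penalty, params$loop_open,
             params$loop_extend, params$max_loop, seed_weight, 8L)
}

#' The three target-prediction method profiles
#'
#' Three profiles emulating the published accessibility-, alignment- and
#' hybridization-based predictors as parameterizations of one shared
#' scanner/energy core, bounded by their stated free-energy thresholds:
#' accessibility at -10, alignment at -20 and hybridization at -27
#' kcal/mol (a site is accepted iff its score is at or below the
#' threshold).  The alignment profile up-weights seed stacks; the
#' accessibility profile adds a site-opening penalty proportional to the
#' GC fraction of the site's +/-15-nt context.
#'
#' @return named list of profile parameter lists.
#' @export
method_profiles <- function() {
  list(
    accessibility = list(name = "accessibility", max_free_energy = -10,
                         seed_weight = 1, opening = TRUE,
                         acc_kappa = 10, acc_window = 15L),
    alignment = list(name = "alignment", max_free_energy = -20,
                     seed_weight = 1.5, opening = FALSE),
    hybridization = list(name = "hybridization", max_free_energy = -27,
                         seed_weight = 1, opening = FALSE)
  )
}

#' Predict miRNA target sites under one method profile
#'
#' Nominates seed sites, scores each site's duplex energy in a local
#' context window under the profile's weighting, applies the profile's
#' opening penalty if any, keeps the best site per (miRNA, gene), and
#' emits the pair iff the score is at or below the profile's free-energy
#' threshold.
#'
#' @param mirnas named character vector of mature miRNA sequences (RNA).
#' @param regions named character vector of target-region sequences (DNA,
#'   transcript orientation), e.g. from [extract_target_regions()].
#' @param profile one of [method_profiles()], or its name.
#' @param params energy parameters.
#' @return data.frame with columns `mirna`, `gene`, `method`, `offset`,
#'   `seed_class`, `deltaG`.
#' @export
predict_targets <- function(mirnas, regions, profile,
                            params = nn_params()) {
  if (is.character(profile)) {
    profs <- method_profiles()
    if (!profile %in% names(profs))
      stop("predict_targets: unknown profile '", profile, "'",
           call. = FALSE)
    profile <- profs[[profile]]
  }
  regions <- chartr("U", "T", toupper(regions))
  res <- vector("list", length(mirnas))
  for (mi in seq_along(mirnas)) {
    mseq <- mirnas[[mi]]
    n <- nchar(mseq)
    menc <- .encode_seq(mseq)
    sites <- .scan_many(mseq, regions)
    if (nrow(sites) == 0) next
    dg <- numeric(nrow(sites))
    for (si in seq_len(nrow(sites))) {
      r <- regions[[sites$gene[si]]]
      j <- sites$core_start[si]
      ctx_lo <- max(1L, j - (n - 8L) - 8L)
      ctx_hi <- min(nchar(r), j + 9L)
      ctx <- substr(r, ctx_lo, ctx_hi)
      e <- .duplex_dp(menc, .encode_seq(ctx), params$stack, params$init,
                      params$end_penalty, params$loop_open,
                      params$loop_extend, params$max_loop,
                      profile$seed_weight, 8L)
      if (isTRUE(profile$opening)) {
        w <- profile$acc_window
        win <- substr(r, max(1L, j - 1L - w),
                      min(nchar(r), j + 6L + w))
        gc <- mean(strsplit(win, "")[[1]] %in% c("G", "C"))
        e <- e + profile$acc_kappa * gc
      }
      dg[si] <- e
    }
    sites$deltaG <- dg
    # best (lowest-energy) site per gene
    sites <- sites[order(sites$gene, sites$deltaG), , drop = FALSE]
    sites <- sites[!duplicated(sites$gene), , drop = FALSE]
    sites <- sites[sites$deltaG <= profile$max_free_energy, , drop = FALSE]
    if (nrow(sites)) {
      res[[mi]] <- data.frame(mirna = names(mirnas)[mi], gene = sites$gene,
                              method = profile$name, offset = sites$offset,
                              seed_class = sites$seed_class,
                              deltaG = sites$deltaG,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(mirna = character(0), gene = character(0),
                      method = character(0), offset = integer(0),
                      seed_class = character(0), deltaG = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Consensus pairs predicted by at least two of the three methods
#'
#' @param site_lists a list of `predict_targets()` outputs (one per
#'   method), or a single row-bound data.frame with a `method` column.
#' @param min_methods minimum number of distinct predicting methods.
#' @return data.frame with columns `mirna`, `gene`, `n_methods`, `methods`
#'   (comma-joined, sorted), independent of input order.
#' @export
consensus_pairs <- function(site_lists, min_methods = 2L) {
  sites <- if (is.data.frame(site_lists)) site_lists else
    do.call(rbind, site_lists)
  if (is.null(sites) || nrow(sites) == 0) {
    return(data.frame(mirna = character(0), gene = character(0),
                      n_methods = integer(0), methods = character(0),
                      stringsAsFactors = FALSE))
  }
  keyed <- split(sites$method, paste(sites$mirna, sites$gene, sep = "\r"))
  methods <- lapply(keyed, function(m) sort(unique(m)))
  keys <- do.call(rbind, strsplit(names(keyed), "\r", fixed = TRUE))
  out <- data.frame(mirna = keys[, 1], gene = keys[, 2],
                    n_methods = lengths(methods),
                    methods = vapply(methods, paste, character(1),
                                     collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[out$n_methods >= min_methods, , drop = FALSE]
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
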