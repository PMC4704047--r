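# Nearest-neighbour energy model for RNA/RNA duplexes.
#
# Stacking free energies (kcal/mol, 37 C) are Turner-style values for
# Watson-Crick stacks plus plausible values for G:U-containing stacks,
# stored as a 6x6 matrix indexed by the pair types AU, UA, GC, CG, GU, UG.
# Entry [p, q] is the energy of the stack whose 5'-side pair (on the miRNA
# strand) is p and whose 3'-side pair is q, i.e. the motif
# 5'-x1 x2-3' / 3'-y1 y2-5' with p = (x1, y1), q = (x2, y2).
# The matrix satisfies the physical symmetry E(p, q) = E(flip(q), flip(p)).

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

.build_stack_table <- function() {
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  keys <- function(p, q) {
    # the stack and its duplex-flip image are the same physical motif
    c(paste(p, q, sep = "|"), paste(flip(q), flip(p), sep = "|"))
  }
  vals <- c(
    # Watson-Crick / Watson-Crick (Turner-style)
    "AU|AU" = -0.93, "AU|UA" = -1.10, "UA|AU" = -1.33,
    "AU|GC" = -2.24, "AU|CG" = -2.08,
    "UA|GC" = -2.35, "UA|CG" = -2.11,
    "CG|GC" = -2.36, "GC|CG" = -3.42, "GC|GC" = -3.26,
    # one G:U pair
    "AU|GU" = -0.55, "AU|UG" = -1.36,
    "UA|GU" = -1.27, "UA|UG" = -1.00,
    "CG|GU" = -1.41, "CG|UG" = -2.11,
    "GC|GU" = -1.53, "GC|UG" = -2.51,
    # two G:U pairs
    "GU|GU" = -0.50, "GU|UG" = 0.47, "UG|GU" = -0.60
  )
  m <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  for (p in PAIR_TYPES) {
    for (q in PAIR_TYPES) {
      k <- intersect(keys(p, q), names(vals))
      if (length(k) == 0)
        stop("stack table incomplete for ", p, "/", q)
      m[p, q] <- vals[[k[1]]]
    }
  }
  m
}

#' Nearest-neighbour duplex energy parameters
#'
#' The embedded energy model used by [duplex_delta_g()] and the target
#' prediction profiles: stacking free energies for all Watson-Crick and G:U
#' dinucleotide stacks, a duplex initiation term, a terminal AU/GU penalty,
#' and affine bulge/internal-loop costs.  All energies in kcal/mol.
#'
#' @return a list with components `stack` (6x6 matrix over pair types
#'   AU, UA, GC, CG, GU, UG), `init`, `end_penalty`, `loop_open`,
#'   `loop_extend`, `max_loop`.
#' @export
nn_params <- function() {
  list(
    stack = .build_stack_table(),
    init = 4.09,         # duplex initiation
    end_penalty = 0.45,  # per terminal AU or GU pair
    loop_open = 3.8,     # bulge / internal loop opening
    loop_extend = 0.5,   # per unpaired base beyond the first
    max_loop = 12L       # bound on unpaired bases per side between stacks
  )
}

# pair type of (miRNA base a, target base b), NA if not pairable
.pair_code <- function(a, b) {
  k <- paste0(a, b)
  idx <- match(k, c("AU", "UA", "GC", "CG", "GU", "UG"))
  if (is.na(idx)) NA_character_ else PAIR_TYPES[idx]
}

.is_terminal_weak <- function(p) p %in% c("AU", "UA", "GU", "UG")

# Free energy of a gapless, fully complementary duplex of the first k bases
# of an miRNA (closed form: init + stacks + terminal penalties).  Used by the
# sequence generator to size planted sites; the DP of duplex_delta_g can only
# do better than this value.
.perfect_duplex_dg <- function(mirna_seq, k, params = nn_params()) {
  m <- strsplit(toupper(mirna_seq), "")[[1]][seq_len(k)]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  pairs <- vapply(m, function(a) .pair_code(a, comp[[a]]), character(1))
  dg <- params$init
  for (i in seq_len(k - 1)) dg <- dg + params$stack[pairs[i], pairs[i + 1]]
  dg <- dg + params$end_penalty * (.is_terminal_weak(pairs[1]) +
                                     .is_terminal_weak(pairs[k]))
  unname(dg)
}
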