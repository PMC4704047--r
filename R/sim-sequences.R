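# Sequence-level synthetic data: genome, annotation, mature miRNAs, planted
# target sites.  Coordinates are 0-based half-open internally; GFF3 output
# converts to 1-based inclusive.

.random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.rc_dna <- function(s) {
  vapply(s, function(x) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.rna_to_dna <- function(s) chartr("U", "T", toupper(s))

# random mature miRNA (RNA alphabet)
.random_mirna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

#' Generate genome, annotation and miRNA sequences with planted target sites
#'
#' Builds a synthetic genome and gene annotation (gene/mRNA/CDS/3'UTR plus
#' miRNA locus features), mature miRNA sequences, and plants, for every
#' coupled (miRNA, gene) pair of the truth, a target site in that gene's
#' target region: the reverse complement of the miRNA's 5' end, extended
#' 3'-ward until the gapless nearest-neighbour duplex energy of the planted
#' stretch is at or below -27 kcal/mol, so the site passes the strictest
#' prediction profile.  Target regions of all other genes are scrubbed of
#' seed cores for every coupled miRNA, so decoy pairs fail seed scanning.
#'
#' A `frac_no_utr` fraction of genes carries CDS but no annotated 3'UTR;
#' their target region is the 500 bases downstream of the stop codon, which
#' the layout keeps intergenic.
#'
#' @param config a [sim_config()].
#' @param truth a [synth_truth()] built from the same config (default:
#'   built internally).
#' @return a list with `genome` (named character, one string per
#'   chromosome), `mirnas` (named character, RNA), `annotation` (a
#'   `bee_annotation` list of coordinate tables, 0-based half-open),
#'   `regions` (named character: the realised target region of every gene,
#'   transcript orientation), `gene_meta` (data.frame with gene lengths),
#'   and `truth` with `planted_sites` filled in.
#' @export
synth_sequences <- function(config, truth = synth_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "synth_truth"))
  if (config$utr_len < 30L)
    stop("synth_sequences: utr_len must be >= 30", call. = FALSE)
  set.seed(derive_seed(config$master_seed, 2L))
  params <- nn_params()

  ## --- mature miRNA sequences -------------------------------------------
  n_mir <- config$n_mirnas
  len <- config$mirna_len
  mirnas <- vapply(seq_len(n_mir), function(i) .random_mirna(len),
                   character(1))
  names(mirnas) <- truth$mirna_ids
  coupled_mirnas <- truth$coupled_pairs$mirna
  # coupled miRNAs must support a -27 kcal/mol perfect duplex, and no
  # coupled miRNA's 6-mer core (positions 2-7) may occur inside another
  # coupled miRNA (keeps planted sites free of cross seed matches)
  accepted_seqs <- character(0)
  for (id in coupled_mirnas) {
    repeat {
      s <- .random_mirna(len)
      if (.perfect_duplex_dg(s, len, params) > -28) next
      core <- substr(s, 2, 7)
      clash <- any(vapply(accepted_seqs, function(o) {
        grepl(core, o, fixed = TRUE) || grepl(substr(o, 2, 7), s, fixed = TRUE)
      }, logical(1)))
      if (!clash) break
    }
    mirnas[[id]] <- s
    accepted_seqs <- c(accepted_seqs, s)
  }
  # planted length: smallest prefix whose perfect duplex reaches -27.2
  site_len <- setNames(integer(length(coupled_mirnas)), coupled_mirnas)
  for (id in coupled_mirnas) {
    ks <- 8:len
    dgs <- vapply(ks, function(k) .perfect_duplex_dg(mirnas[[id]], k, params),
                  numeric(1))
    k <- ks[which(dgs <= -27.2)[1]]
    if (is.na(k))
      stop("synth_sequences: failed to size a planted site", call. = FALSE)
    site_len[[id]] <- k
  }
  if (length(coupled_mirnas) &&
      config$utr_len < max(site_len) + 20L)
    stop("synth_sequences: utr_len too short to host a planted site",
         call. = FALSE)

  ## --- gene properties and layout ---------------------------------------
  ng <- config$n_genes
  gene_ids <- truth$gene_ids
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  has_intron <- runif(ng) < 0.6
  has_utr <- runif(ng) >= config$frac_no_utr
  cds_total <- pmin(pmax(round(rlnorm(ng, log(900), 0.5)), 300L), 4000L)
  intron_len <- ifelse(has_intron, 150L, 0L)
  exon1_len <- ifelse(has_intron, round(cds_total * 0.5), cds_total)
  exon2_len <- cds_total - ifelse(has_intron, exon1_len, cds_total)
  utr_here <- ifelse(has_utr, config$utr_len, 0L)
  gene_span <- exon1_len + intron_len + exon2_len + utr_here

  n_chrom <- max(1L, min(4L, ng %/% 500L + 1L))
  chrom_of <- sort(rep_len(seq_len(n_chrom), ng))
  chrom_names <- sprintf("chr%d", seq_len(n_chrom))

  host_every <- 15L  # a 3-kb intergenic miRNA host stretch every 15 genes
  g_start <- integer(ng); g_end <- integer(ng)
  host_gaps <- list()  # per-chrom list of (start, end)
  chrom_len <- setNames(integer(n_chrom), chrom_names)
  cursor <- 0L
  prev_chrom <- 0L
  for (i in seq_len(ng)) {
    if (chrom_of[i] != prev_chrom) {
      cursor <- 200L
      prev_chrom <- chrom_of[i]
    }
    # gap before gene i: must host the 500-bp fallback region of a
    # preceding (+, no-UTR) gene and/or of this gene when (-, no-UTR)
    need <- 50L
    if (i > 1 && chrom_of[i - 1] == chrom_of[i] &&
        strand[i - 1] == "+" && !has_utr[i - 1]) need <- need + 520L
    if (strand[i] == "-" && !has_utr[i]) need <- need + 520L
    gap <- need + sample.int(100L, 1L)
    if (i %% host_every == 0L) {
      host_gaps[[length(host_gaps) + 1L]] <-
        list(chrom = chrom_names[chrom_of[i]],
             start = cursor + gap, end = cursor + gap + 3000L)
      gap <- gap + 3000L
    }
    cursor <- cursor + gap
    g_start[i] <- cursor
    g_end[i] <- cursor + gene_span[i]
    cursor <- g_end[i]
    if (i == ng || chrom_of[i + 1] != chrom_of[i]) {
      chrom_len[chrom_of[i]] <- cursor + 600L
    }
  }

  ## --- feature coordinates (0-based half-open) --------------------------
  cds1 <- cds2 <- utr3 <- matrix(NA_integer_, ng, 2)
  region_iv <- matrix(NA_integer_, ng, 2)
  for (i in seq_len(ng)) {
    s <- g_start[i]
    if (strand[i] == "+") {
      # exon1 [s, s+e1) intron exon2 utr
      cds1[i, ] <- c(s, s + exon1_len[i])
      p <- s + exon1_len[i] + intron_len[i]
      if (has_intron[i]) cds2[i, ] <- c(p, p + exon2_len[i])
      ce <- p + exon2_len[i]  # 3' boundary of CDS
      if (has_utr[i]) {
        utr3[i, ] <- c(ce, ce + config$utr_len)
        region_iv[i, ] <- utr3[i, ]
      } else {
        region_iv[i, ] <- c(ce, ce + 500L)
      }
    } else {
      # genomic order: utr | exon2 | intron | exon1 ; transcript runs right
      # to left, stop codon 3' boundary at the left end of the CDS
      p <- s
      if (has_utr[i]) {
        utr3[i, ] <- c(p, p + config$utr_len)
        region_iv[i, ] <- utr3[i, ]
        p <- p + config$utr_len
      }
      cs <- p  # CDS genomic start
      if (has_intron[i]) {
        cds2[i, ] <- c(p, p + exon2_len[i])
        p <- p + exon2_len[i] + intron_len[i]
      }
      cds1[i, ] <- c(p, p + exon1_len[i])
      if (!has_utr[i]) region_iv[i, ] <- c(cs - 500L, cs)
    }
  }

  ## --- genome and target-region sequences -------------------------------
  genome_chars <- lapply(chrom_len, .random_bases)
  get_seg <- function(chrom_i, iv) {
    paste(genome_chars[[chrom_i]][(iv[1] + 1L):iv[2]], collapse = "")
  }
  regions <- character(ng)
  for (i in seq_len(ng)) {
    seg <- get_seg(chrom_of[i], region_iv[i, ])
    regions[i] <- if (strand[i] == "+") seg else .rc_dna(seg)
  }
  names(regions) <- gene_ids

  # plant sites
  partner_of_gene <- setNames(truth$coupled_pairs$mirna,
                              truth$coupled_pairs$gene)
  planted <- data.frame(mirna = character(0), gene = character(0),
                        offset = integer(0), length = integer(0),
                        stringsAsFactors = FALSE)
  site_iv <- setNames(vector("list", ng), gene_ids)  # in-region, 1-based
  if (nrow(truth$coupled_pairs)) {
    for (j in seq_len(nrow(truth$coupled_pairs))) {
      m_id <- truth$coupled_pairs$mirna[j]
      g_id <- truth$coupled_pairs$gene[j]
      gi <- match(g_id, gene_ids)
      k <- site_len[[m_id]]
      site <- .rc_dna(.rna_to_dna(substr(mirnas[[m_id]], 1, k)))
      lo <- 10L
      hi <- if (has_utr[gi]) config$utr_len - k - 10L else 90L
      if (hi < lo)
        stop("synth_sequences: target region too short to host a planted ",
             "site", call. = FALSE)
      o <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      substr(regions[gi], o + 1L, o + k) <- site
      site_iv[[g_id]] <- c(o + 1L, o + k)
      planted <- rbind(planted, data.frame(
        mirna = m_id, gene = g_id, offset = o + 1L, length = k,
        stringsAsFactors = FALSE))
    }
  }

  # scrub decoy regions: no 6-mer seed core of any coupled miRNA outside
  # its own planted site
  if (length(coupled_mirnas)) {
    cores <- vapply(coupled_mirnas, function(id) {
      .rc_dna(.rna_to_dna(substr(mirnas[[id]], 2, 7)))
    }, character(1))
    mutate_cycle <- c(A = "C", C = "G", G = "T", T = "A")
    for (round in 1:10) {
      changed <- FALSE
      for (ci in seq_along(cores)) {
        m_id <- coupled_mirnas[ci]
        hits <- gregexpr(cores[[ci]], regions, fixed = TRUE)
        for (gi in seq_len(ng)) {
          starts <- hits[[gi]]
          if (starts[1] == -1L) next
          g_id <- gene_ids[gi]
          partner <- unname(partner_of_gene[g_id])
          if (!is.na(partner) && partner == m_id) next
          iv <- site_iv[[g_id]]
          for (hs in as.integer(starts)) {
            he <- hs + 5L
            pos <- hs + 3L  # middle of the 6-mer
            if (!is.null(iv) && hs >= iv[1] && he <= iv[2]) {
              next  # inside a planted site; prevented at miRNA generation
            }
            if (!is.null(iv) && pos >= iv[1] && pos <= iv[2]) {
              pos <- if (hs < iv[1]) hs else he  # mutate outside the site
            }
            b <- substr(regions[gi], pos, pos)
            substr(regions[gi], pos, pos) <- mutate_cycle[[b]]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }

  # write final regions back into the genome
  for (i in seq_len(ng)) {
    seg <- if (strand[i] == "+") regions[i] else .rc_dna(regions[i])
    genome_chars[[chrom_of[i]]][(region_iv[i, 1] + 1L):region_iv[i, 2]] <-
      strsplit(seg, "")[[1]]
  }
  genome <- vapply(genome_chars, paste, character(1), collapse = "")
  names(genome) <- chrom_names

  ## --- miRNA loci --------------------------------------------------------
  n_inter <- round(0.5 * n_mir)
  n_intr <- round(0.3 * n_mir)
  n_cds <- round(0.1 * n_mir)
  n_utr <- n_mir - n_inter - n_intr - n_cds
  cats <- sample(c(rep("intergenic", n_inter), rep("intronic", n_intr),
                   rep("CDS", n_cds), rep("UTR", n_utr)))
  intron_genes <- which(has_intron)
  utr_genes <- which(has_utr)
  loci <- data.frame(id = truth$mirna_ids, chrom = NA_character_,
                     start = NA_integer_, end = NA_integer_,
                     strand = sample(c("+", "-"), n_mir, replace = TRUE),
                     stringsAsFactors = FALSE)
  host_i <- 0L; host_off <- 0L
  for (i in seq_len(n_mir)) {
    cat_i <- cats[i]
    if (cat_i == "intronic" && length(intron_genes) == 0) cat_i <- "intergenic"
    if (cat_i == "UTR" && length(utr_genes) == 0) cat_i <- "intergenic"
    if (cat_i == "intergenic" && length(host_gaps) == 0) cat_i <- "CDS"
    if (cat_i == "intergenic") {
      spacing <- sample(c(300L, 800L, 1500L), 1L)
      if (host_i == 0L || host_off + spacing + len > 2900L) {
        host_i <- host_i %% length(host_gaps) + 1L
        host_off <- 50L
      } else {
        host_off <- host_off + spacing
      }
      hg <- host_gaps[[host_i]]
      loci$chrom[i] <- hg$chrom
      loci$start[i] <- hg$start + host_off
    } else {
      gi <- switch(cat_i,
        intronic = sample(intron_genes, 1L),
        UTR = sample(utr_genes, 1L),
        CDS = sample.int(ng, 1L))
      iv <- switch(cat_i,
        intronic = c(min(cds1[gi, 2], cds2[gi, 2], na.rm = TRUE),
                     max(cds1[gi, 1], cds2[gi, 1], na.rm = TRUE)),
        UTR = utr3[gi, ],
        CDS = cds1[gi, ])
      lo <- iv[1]; hi <- iv[2] - len
      loci$chrom[i] <- chrom_names[chrom_of[gi]]
      loci$start[i] <- lo + sample.int(max(1L, hi - lo), 1L) - 1L
    }
    loci$end[i] <- loci$start[i] + len
  }

  ## --- annotation object -------------------------------------------------
  cds_rows <- do.call(rbind, lapply(seq_len(ng), function(i) {
    rows <- rbind(cds1[i, ], if (has_intron[i]) cds2[i, ])
    data.frame(gene_id = gene_ids[i], chrom = chrom_names[chrom_of[i]],
               start = rows[, 1], end = rows[, 2], strand = strand[i],
               stringsAsFactors = FALSE)
  }))
  utr_rows <- do.call(rbind, lapply(which(has_utr), function(i) {
    data.frame(gene_id = gene_ids[i], chrom = chrom_names[chrom_of[i]],
               start = utr3[i, 1], end = utr3[i, 2], strand = strand[i],
               stringsAsFactors = FALSE)
  }))
  genes_df <- data.frame(gene_id = gene_ids,
                         chrom = chrom_names[chrom_of],
                         start = g_start, end = g_end, strand = strand,
                         stringsAsFactors = FALSE)
  ann <- bee_annotation(genes = genes_df, cds = cds_rows, utr3 = utr_rows,
                        mirna_loci = loci)

  gene_meta <- data.frame(
    gene_id = gene_ids,
    length = cds_total + utr_here,
    has_utr = has_utr, has_intron = has_intron,
    stringsAsFactors = FALSE)

  truth$planted_sites <- planted
  list(genome = genome, mirnas = mirnas, annotation = ann,
       regions = regions, gene_meta = gene_meta, truth = truth)
}
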