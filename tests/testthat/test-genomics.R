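# Locus classification, 1-kb clustering, target-region extraction.

# two-gene toy annotation: gplus (+, two CDS exons with an intron, a UTR)
# and gminus (-, two CDS exons, no UTR), all coordinates 0-based half-open
toy_ann <- function() {
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = c("chr1", "chr1"),
    start = c(1000L, 5000L), end = c(2200L, 6000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  cds <- data.frame(
    gene_id = c("gplus", "gplus", "gminus", "gminus"),
    chrom = "chr1",
    start = c(1000L, 1600L, 5000L, 5700L),
    end = c(1400L, 2000L, 5300L, 6000L),
    strand = c("+", "+", "-", "-"), stringsAsFactors = FALSE)
  utr3 <- data.frame(
    gene_id = "gplus", chrom = "chr1", start = 2000L, end = 2200L,
    strand = "+", stringsAsFactors = FALSE)
  bee_annotation(genes, cds, utr3)
}

loci_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], chrom = r[[2]], start = as.integer(r[[3]]),
               end = as.integer(r[[4]]), strand = r[[5]],
               stringsAsFactors = FALSE)
  }))
}

test_that("locus classification follows the CDS > UTR > intronic precedence", {
  ann <- toy_ann()
  loci <- loci_df(
    list("m_inter", "chr1", 3000, 3022, "+"),   # between the genes
    list("m_intron", "chr1", 1450, 1472, "+"),  # wholly inside + intron
    list("m_utr", "chr1", 2050, 2072, "-"),     # inside the + gene's UTR
    # overlaps both CDS and intron of the - gene, locus on + strand:
    # precedence gives CDS, strand relation opposite
    list("m_cds_intron", "chr1", 5280, 5320, "+"),
    list("m_offchrom", "chrZ", 10, 32, "+"))
  cls <- classify_mirna_loci(loci, ann)
  expect_equal(cls$category,
               c("intergenic", "intronic", "UTR", "CDS", "intergenic"))
  expect_equal(cls$strand_relation,
               c("n/a", "same", "opposite", "opposite", "n/a"))
  expect_true(cls$warning[cls$id == "m_offchrom"])
  expect_false(any(cls$warning[cls$id != "m_offchrom"]))
  # permuting transcript/locus input order never changes the outcome
  perm <- sample(nrow(loci))
  cls2 <- classify_mirna_loci(loci[perm, ], ann)
  expect_equal(cls2[order(match(cls2$id, cls$id)), ],
               cls, ignore_attr = TRUE)
})

test_that("1-kb clustering chains by nearest-end gaps, transitively", {
  loci <- loci_df(
    list("a", "chr1", 0, 100, "+"),
    list("b", "chr1", 1000, 1100, "+"),    # gap 900 -> joins a
    list("c", "chr1", 2101, 2200, "+"),    # gap 1001 -> new cluster
    list("d", "chr2", 0, 50, "+"),
    list("e", "chr2", 850, 900, "+"),      # gap 800
    list("f", "chr2", 1700, 1750, "+"))    # gap 800 -> transitive with d
  cl <- cluster_mirna_loci(loci, window = 1000L)
  grp <- split(cl$id, cl$cluster)
  expect_true(any(vapply(grp, setequal, logical(1), y = c("a", "b"))))
  expect_true(any(vapply(grp, setequal, logical(1), y = "c")))
  expect_true(any(vapply(grp, setequal, logical(1), y = c("d", "e", "f"))))
  # brute-force pairwise chaining oracle: same partition
  expect_equal(length(grp), 3L)
  # invariant to input order; union of clusters = input loci
  perm <- c(4, 1, 6, 3, 5, 2)
  cl2 <- cluster_mirna_loci(loci[perm, ], window = 1000L)
  grp2 <- split(cl2$id, cl2$cluster)
  expect_setequal(unname(vapply(grp, function(g)
    paste(sort(g), collapse = ","), character(1))),
    unname(vapply(grp2, function(g)
      paste(sort(g), collapse = ","), character(1))))
  expect_setequal(unlist(grp), loci$id)
})

test_that("target regions: annotated UTR, 500-bp fallback, strand symmetry", {
  ann <- toy_ann()
  set.seed(9)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 7000, TRUE), collapse = "")
  genome <- c(chr1 = chr1)
  # UTR present: that exact 200-nt segment
  r1 <- extract_target_region("gplus", ann, genome)
  expect_false(r1$flagged)
  expect_identical(r1$seq, substr(chr1, 2001, 2200))
  # no UTR, - strand: reverse complement of the 500 bp 5'-ward of the CDS
  r2 <- extract_target_region("gminus", ann, genome)
  expect_identical(r2$seq,
                   beemirnet:::.rc_dna(substr(chr1, 4501, 5000)))
  expect_equal(nchar(r2$seq), 500L)
  # no UTR, + strand, truncation at the contig end
  ann2 <- bee_annotation(
    genes = data.frame(gene_id = "gend", chrom = "chr1", start = 6500L,
                       end = 6900L, strand = "+", stringsAsFactors = FALSE),
    cds = data.frame(gene_id = "gend", chrom = "chr1", start = 6500L,
                     end = 6900L, strand = "+", stringsAsFactors = FALSE))
  r3 <- extract_target_region("gend", ann2, genome)
  expect_identical(r3$seq, substr(chr1, 6901, 7000))  # truncated to 100
  # stop codon at the contig edge: empty region, flagged
  ann3 <- bee_annotation(
    genes = data.frame(gene_id = "gedge", chrom = "chr1", start = 6500L,
                       end = 7000L, strand = "+", stringsAsFactors = FALSE),
    cds = data.frame(gene_id = "gedge", chrom = "chr1", start = 6500L,
                     end = 7000L, strand = "+", stringsAsFactors = FALSE))
  r4 <- extract_target_region("gedge", ann3, genome)
  expect_identical(r4$seq, "")
  expect_true(r4$flagged)
})

test_that("extracted regions of generated data contain the planted sites", {
  seqs <- synth_sequences(small_sim(seed = 21L))
  tr <- seqs$truth
  regions <- extract_target_regions(seqs$annotation, seqs$genome)
  for (j in seq_len(nrow(tr$planted_sites))) {
    g <- tr$planted_sites$gene[j]
    m <- seqs$mirnas[[tr$planted_sites$mirna[j]]]
    seed_rc <- beemirnet:::.rc_dna(chartr("U", "T", substr(m, 2, 8)))
    expect_true(grepl(seed_rc, regions[[g]], fixed = TRUE), label = g)
  }
})

test_that("GFF3 writing and reading round-trips the annotation", {
  seqs <- synth_sequences(small_sim(seed = 31L))
  path <- tempfile(fileext = ".gff3")
  write_gff3(seqs$annotation, path)
  back <- read_gff3_annotation(path)
  for (tb in c("genes", "cds", "utr3")) {
    a <- seqs$annotation[[tb]][order(seqs$annotation[[tb]]$gene_id,
                                     seqs$annotation[[tb]]$start), ]
    b <- back[[tb]][order(back[[tb]]$gene_id, back[[tb]]$start), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b[, c("gene_id", "chrom", "start", "end", "strand")],
                 a[, c("gene_id", "chrom", "start", "end", "strand")])
  }
  # interval lengths preserved through the 1-based inclusive round trip
  expect_equal(back$utr3$end - back$utr3$start,
               seqs$annotation$utr3$end - seqs$annotation$utr3$start)
  unlink(path)
})
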