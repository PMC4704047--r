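# Coordinate arithmetic on miRNA loci and transcripts.  All intervals are
# 0-based half-open; overlap means at least one shared base.

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Classify miRNA loci against the gene annotation
#'
#' Assigns each locus one category — intergenic, intronic, UTR or CDS —
#' with precedence CDS > UTR > intronic when a locus overlaps several
#' feature types (the published locus table's categories are mutually
#' exclusive but state no tie rule), plus the strand relation to the host
#' gene (`same`/`opposite`; `n/a` for intergenic loci).  A locus on a
#' chromosome absent from the annotation is classified intergenic and
#' flagged in the `warning` column.
#'
#' @param loci data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open), e.g. `annotation$mirna_loci`.
#' @param ann a [bee_annotation()].
#' @return data.frame with columns `id`, `category`, `strand_relation`,
#'   `host_gene`, `warning`.
#' @export
classify_mirna_loci <- function(loci, ann) {
  stopifnot(inherits(ann, "bee_annotation"))
  genes <- ann$genes
  known_chroms <- unique(c(genes$chrom, ann$cds$chrom, ann$utr3$chrom))
  res <- data.frame(id = loci$id, category = "intergenic",
                    strand_relation = "n/a", host_gene = NA_character_,
                    warning = FALSE, stringsAsFactors = FALSE)
  prec <- c(CDS = 3L, UTR = 2L, intronic = 1L)
  for (i in seq_len(nrow(loci))) {
    if (!loci$chrom[i] %in% known_chroms) {
      res$warning[i] <- TRUE
      next
    }
    hit <- genes[genes$chrom == loci$chrom[i] &
                   .overlaps(genes$start, genes$end,
                             loci$start[i], loci$end[i]), , drop = FALSE]
    if (nrow(hit) == 0) next
    hit <- hit[order(hit$gene_id), , drop = FALSE]
    best_cat <- NA_character_; best_gene <- NA_character_
    for (j in seq_len(nrow(hit))) {
      gid <- hit$gene_id[j]
      cc <- ann$cds[ann$cds$gene_id == gid, , drop = FALSE]
      uu <- ann$utr3[ann$utr3$gene_id == gid, , drop = FALSE]
      cat_j <- if (nrow(cc) && any(.overlaps(cc$start, cc$end,
                                             loci$start[i], loci$end[i]))) {
        "CDS"
      } else if (nrow(uu) && any(.overlaps(uu$start, uu$end,
                                           loci$start[i], loci$end[i]))) {
        "UTR"
      } else {
        "intronic"
      }
      if (is.na(best_cat) || prec[[cat_j]] > prec[[best_cat]]) {
        best_cat <- cat_j; best_gene <- gid
      }
    }
    res$category[i] <- best_cat
    res$host_gene[i] <- best_gene
    host_strand <- genes$strand[genes$gene_id == best_gene]
    res$strand_relation[i] <-
      if (loci$strand[i] == host_strand) "same" else "opposite"
  }
  res
}

#' Single-linkage clustering of miRNA loci
#'
#' Chains loci on the same chromosome whenever the gap between nearest ends
#' is at most `window` bases (default 1 kb); clusters are maximal under
#' transitive chaining and singletons are reported as their own cluster.
#'
#' @param loci data.frame with `id`, `chrom`, `start`, `end`.
#' @param window maximum gap in bases.
#' @return data.frame with columns `id`, `cluster` (cluster label), plus a
#'   `"sizes"` attribute (table of cluster sizes).
#' @export
cluster_mirna_loci <- function(loci, window = 1000L) {
  orig_ids <- loci$id
  o <- order(loci$chrom, loci$start, loci$id)
  loci <- loci[o, , drop = FALSE]
  cluster <- integer(nrow(loci))
  cur <- 0L
  for (i in seq_len(nrow(loci))) {
    new_cluster <- i == 1L ||
      loci$chrom[i] != loci$chrom[i - 1L] ||
      (loci$start[i] - max(loci$end[seq_len(i - 1L)][
        cluster[seq_len(i - 1L)] == cur])) > window
    if (new_cluster) cur <- cur + 1L
    cluster[i] <- cur
  }
  out <- data.frame(id = loci$id, cluster = sprintf("cl%04d", cluster),
                    stringsAsFactors = FALSE)
  out <- out[match(orig_ids, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sizes") <- table(out$cluster)
  out
}

#' Extract the target region of a gene
#'
#' Returns the annotated 3'UTR sequence when present; otherwise the
#' `fallback` bases (default 500) downstream of the stop codon in transcript
#' orientation, reverse-complemented for minus-strand genes and truncated at
#' the contig end.  The sequence is returned 5' to 3'.
#'
#' @param gene_id gene to extract.
#' @param ann a [bee_annotation()].
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param fallback downstream window when no 3'UTR is annotated.
#' @return list with `seq` (character; possibly `""`) and `flagged`
#'   (`TRUE` when the region was truncated to zero length).
#' @export
extract_target_region <- function(gene_id, ann, genome, fallback = 500L) {
  stopifnot(inherits(ann, "bee_annotation"))
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  g <- ann$genes[ann$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) stop("extract_target_region: unknown gene ", gene_id,
                         call. = FALSE)
  if (!g$chrom %in% names(genome))
    stop("extract_target_region: genome lacks contig ", g$chrom,
         call. = FALSE)
  chrom_seq <- genome[[g$chrom]]
  clen <- nchar(chrom_seq)
  uu <- ann$utr3[ann$utr3$gene_id == gene_id, , drop = FALSE]
  if (nrow(uu) > 0) {
    # longest annotated 3'UTR wins
    uu <- uu[which.max(uu$end - uu$start), , drop = FALSE]
    iv <- c(uu$start, uu$end)
  } else {
    cc <- ann$cds[ann$cds$gene_id == gene_id, , drop = FALSE]
    if (nrow(cc) == 0) stop("extract_target_region: gene ", gene_id,
                            " has no CDS", call. = FALSE)
    if (g$strand == "+") {
      ce <- max(cc$end)  # 3' boundary of the stop codon
      iv <- c(ce, min(ce + fallback, clen))
    } else {
      cs <- min(cc$start)
      iv <- c(max(cs - fallback, 0L), cs)
    }
  }
  if (iv[2] <= iv[1]) return(list(seq = "", flagged = TRUE))
  seg <- substr(chrom_seq, iv[1] + 1L, iv[2])
  if (g$strand == "-") seg <- .rc_dna(seg)
  list(seq = seg, flagged = FALSE)
}

#' Extract target regions for all genes
#'
#' @param ann a [bee_annotation()].
#' @param genome named character vector of chromosome sequences.
#' @param fallback downstream window when no 3'UTR is annotated.
#' @return named character vector of region sequences (empty regions
#'   dropped, with a warning naming them).
#' @export
extract_target_regions <- function(ann, genome, fallback = 500L) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  ids <- ann$genes$gene_id
  out <- vapply(ids, function(g) {
    extract_target_region(g, ann, genome, fallback)$seq
  }, character(1))
  empty <- out == ""
  if (any(empty))
    warning("extract_target_regions: empty region for ",
            paste(ids[empty], collapse = ", "))
  out[!empty]
}
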