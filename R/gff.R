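# Annotation container and GFF3 I/O.
#
# Internal coordinates are 0-based half-open; GFF3 is 1-based inclusive.
# One transcript per gene is modelled (the longest annotated 3'UTR wins if
# an input GFF3 ever carries several).

#' Annotation container
#'
#' Holds gene, CDS, 3'UTR and miRNA-locus coordinate tables, all 0-based
#' half-open.  Every table has columns `chrom`, `start`, `end`, `strand`
#' plus `gene_id` (gene features) or `id` (miRNA loci).
#'
#' @param genes,cds,utr3,mirna_loci data.frames as described above; `utr3`
#'   and `mirna_loci` may be `NULL`/empty.
#' @return an object of class `bee_annotation`.
#' @export
bee_annotation <- function(genes, cds, utr3 = NULL, mirna_loci = NULL) {
  empty_feat <- data.frame(gene_id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), stringsAsFactors = FALSE)
  empty_loci <- data.frame(id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), stringsAsFactors = FALSE)
  utr3 <- utr3 %||% empty_feat
  if (nrow(utr3) == 0) utr3 <- empty_feat
  mirna_loci <- mirna_loci %||% empty_loci
  for (tb in list(genes, cds, utr3)) {
    stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                    names(tb)))
    if (nrow(tb) && any(tb$start >= tb$end))
      stop("bee_annotation: intervals must satisfy start < end",
           call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id))
    stop("bee_annotation: duplicate gene IDs", call. = FALSE)
  structure(list(genes = genes, cds = cds, utr3 = utr3,
                 mirna_loci = mirna_loci),
            class = "bee_annotation")
}

#' Write annotation as GFF3
#'
#' Emits gene, mRNA, CDS, three_prime_UTR and miRNA features with 1-based
#' inclusive coordinates.
#'
#' @param ann a [bee_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "bee_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  line <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tbeemirnet\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  }
  out <- character(0)
  g <- ann$genes
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    tid <- paste0(gid, ".t1")
    out <- c(out,
      line(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
           sprintf("ID=%s", gid)),
      line(g$chrom[i], "mRNA", g$start[i], g$end[i], g$strand[i],
           sprintf("ID=%s;Parent=%s", tid, gid)))
    cc <- ann$cds[ann$cds$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(cc)))
      out <- c(out, line(cc$chrom[j], "CDS", cc$start[j], cc$end[j],
                         cc$strand[j], sprintf("Parent=%s", tid)))
    uu <- ann$utr3[ann$utr3$gene_id == gid, , drop = FALSE]
    for (j in seq_len(nrow(uu)))
      out <- c(out, line(uu$chrom[j], "three_prime_UTR", uu$start[j],
                         uu$end[j], uu$strand[j], sprintf("Parent=%s", tid)))
  }
  ml <- ann$mirna_loci
  for (i in seq_len(nrow(ml)))
    out <- c(out, line(ml$chrom[i], "miRNA", ml$start[i], ml$end[i],
                       ml$strand[i], sprintf("ID=%s", ml$id[i])))
  writeLines(out, con)
  invisible(path)
}

#' Read a GFF3 annotation
#'
#' Imports gene, mRNA, CDS, three_prime_UTR and miRNA features via
#' rtracklayer and converts 1-based inclusive coordinates to the internal
#' 0-based half-open convention.  CDS and UTR features are attached to their
#' gene through the `Parent` chain (mRNA ID `<gene>.t1`).
#'
#' @param path a GFF3 file.
#' @return a [bee_annotation()].
#' @export
read_gff3_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  # 1-based inclusive [start, end]  ->  0-based half-open [start-1, end)
  df$start0 <- df$start - 1L
  parent_gene <- function(p) sub("\\.t[0-9]+$", "", p)
  first_parent <- function(x) {
    vapply(x, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  }
  take <- function(type, id_col) {
    rows <- df[df$type == type, , drop = FALSE]
    if (nrow(rows) == 0) {
      return(data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
    }
    gene_id <- if (id_col == "ID") {
      as.character(rows$ID)
    } else {
      parent_gene(first_parent(rows$Parent))
    }
    data.frame(gene_id = gene_id, chrom = rows$seqnames,
               start = rows$start0, end = rows$end, strand = rows$strand,
               stringsAsFactors = FALSE)
  }
  genes <- take("gene", "ID")
  cds <- take("CDS", "Parent")
  utr3 <- take("three_prime_UTR", "Parent")
  ml <- df[df$type == "miRNA", , drop = FALSE]
  loci <- data.frame(id = as.character(ml$ID), chrom = ml$seqnames,
                     start = ml$start0, end = ml$end,
                     strand = ml$strand, stringsAsFactors = FALSE)
  bee_annotation(genes = genes, cds = cds, utr3 = utr3, mirna_loci = loci)
}
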