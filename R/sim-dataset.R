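#' Generate and write a complete synthetic dataset
#'
#' Runs the whole generator ([synth_truth()], [synth_sequences()],
#' [synth_counts()], [plant_methylation()], [synth_term_map()]) and writes
#' the standard input files of the pipeline:
#' `genome.fa`, `annotation.gff3`, `mirnas.fa`, `mirna_counts.tsv`,
#' `mrna_counts.tsv`, `methylated.txt`, `gene_terms.tsv`,
#' `gene_lengths.tsv`, `design.tsv` and a `truth.json` sidecar with the
#' planted ground truth.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (`design`, `truth`,
#'   `seqs`, `counts`, `methylated`, `terms`, `paths`).
#' @export
synth_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- make_design(config)
  seqs <- synth_sequences(config)
  truth <- seqs$truth
  counts <- synth_counts(config, design, truth)
  methylated <- plant_methylation(config, truth, truth$gene_ids)
  truth$methylated_genes <- methylated
  terms <- synth_term_map(config, truth$gene_ids)

  p <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    mirnas = file.path(dir, "mirnas.fa"),
    mirna_counts = file.path(dir, "mirna_counts.tsv"),
    mrna_counts = file.path(dir, "mrna_counts.tsv"),
    methylated = file.path(dir, "methylated.txt"),
    gene_terms = file.path(dir, "gene_terms.tsv"),
    gene_lengths = file.path(dir, "gene_lengths.tsv"),
    design = file.path(dir, "design.tsv"),
    truth = file.path(dir, "truth.json")
  )
  genome_set <- Biostrings::DNAStringSet(seqs$genome)
  Biostrings::writeXStringSet(genome_set, p$genome, width = 80L)
  mir_set <- Biostrings::RNAStringSet(seqs$mirnas)
  Biostrings::writeXStringSet(mir_set, p$mirnas, width = 80L)
  write_gff3(seqs$annotation, p$annotation)
  write_count_matrix(counts$mirna, p$mirna_counts)
  write_count_matrix(counts$mrna, p$mrna_counts)
  writeLines(methylated, p$methylated)
  term_df <- data.frame(
    gene = unlist(terms, use.names = FALSE),
    term = rep(names(terms), lengths(terms)),
    stringsAsFactors = FALSE)
  write.table(term_df[, c("gene", "term")], p$gene_terms, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(seqs$gene_meta[, c("gene_id", "length")], p$gene_lengths,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(design, p$design, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_json <- list(
    coupled_pairs = truth$coupled_pairs,
    de_mirna = truth$de_mirna,
    de_mrna = truth$de_mrna,
    de_features = truth$de_features,
    planted_sites = truth$planted_sites,
    methylated_genes = truth$methylated_genes
  )
  jsonlite::write_json(truth_json, p$truth, dataframe = "columns",
                       pretty = TRUE)

  invisible(list(design = design, truth = truth, seqs = seqs,
                 counts = counts, methylated = methylated, terms = terms,
                 paths = p))
}
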