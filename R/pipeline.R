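# Configuration, input loading and end-to-end orchestration.

#' Pipeline configuration
#'
#' Collects every path and threshold of the full analysis.  Thresholds
#' default to the study's stated constants: DE FDR 1%, correlation FDR 5%,
#' enrichment FDR 5%, count filter (5 counts in 5 samples), 1-kb miRNA
#' locus clustering, 500-bp downstream fallback, and method free-energy
#' thresholds of -10/-20/-27 kcal/mol.
#'
#' @param input_dir directory holding the input files (the layout written
#'   by [synth_dataset()]).
#' @param out_dir directory for result tables.
#' @param master_seed master seed for all stochastic stages.
#' @param simulate when `TRUE`, [run_pipeline()] first generates the
#'   synthetic inputs into `input_dir` with `sim`.
#' @param sim the [sim_config()] used when `simulate = TRUE`.
#' @param de_fdr,corr_fdr,enrich_fdr,min_count,min_samples,cluster_window,downstream_fallback
#'   stage thresholds.
#' @param enrich_n_perm resampling draws for the enrichment null.
#' @param overlap_universe `"expressed"` (genes surviving the count filter,
#'   default) or `"all"` for the Fisher overlap test.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            master_seed = 1L,
                            simulate = TRUE,
                            sim = sim_config(master_seed = master_seed),
                            de_fdr = 0.01, corr_fdr = 0.05,
                            enrich_fdr = 0.05,
                            min_count = 5L, min_samples = 5L,
                            cluster_window = 1000L,
                            downstream_fallback = 500L,
                            enrich_n_perm = 10000L,
                            overlap_universe = c("expressed", "all")) {
  stopifnot(de_fdr > 0, de_fdr < 1, corr_fdr > 0, corr_fdr < 1,
            enrich_fdr > 0, enrich_fdr < 1,
            min_count >= 1, min_samples >= 1,
            cluster_window >= 0, downstream_fallback > 0)
  structure(list(
    input_dir = input_dir, out_dir = out_dir,
    master_seed = as.integer(master_seed),
    simulate = simulate, sim = sim,
    de_fdr = de_fdr, corr_fdr = corr_fdr, enrich_fdr = enrich_fdr,
    min_count = as.integer(min_count),
    min_samples = as.integer(min_samples),
    cluster_window = as.integer(cluster_window),
    downstream_fallback = as.integer(downstream_fallback),
    enrich_n_perm = as.integer(enrich_n_perm),
    overlap_universe = match.arg(overlap_universe)
  ), class = "pipeline_config")
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Load and validate the pipeline inputs
#'
#' Reads counts, sequences, annotation, the gene-to-term map, gene lengths
#' and the methylated-gene list from `config$input_dir`, verifies
#' cross-file ID consistency (count features must be known to the
#' annotation or miRNA FASTA) and reports unmatched IDs.
#'
#' @param config a [pipeline_config()].
#' @return a list bundle: `design`, `mirna_counts`, `mrna_counts`,
#'   `genome`, `annotation`, `mirnas`, `terms`, `gene_lengths`,
#'   `methylated`, `unmatched`.
#' @export
load_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  d <- config$input_dir
  need <- c("design.tsv", "mirna_counts.tsv", "mrna_counts.tsv",
            "genome.fa", "annotation.gff3", "mirnas.fa",
            "gene_terms.tsv", "gene_lengths.tsv", "methylated.txt")
  missing <- need[!file.exists(file.path(d, need))]
  if (length(missing))
    stop("load_inputs: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  design <- read.delim(file.path(d, "design.tsv"),
                       stringsAsFactors = FALSE)
  mirna_counts <- read_count_matrix(file.path(d, "mirna_counts.tsv"),
                                    design)
  mrna_counts <- read_count_matrix(file.path(d, "mrna_counts.tsv"),
                                   design)
  genome <- as.character(
    Biostrings::readDNAStringSet(file.path(d, "genome.fa")))
  mirnas <- as.character(
    Biostrings::readRNAStringSet(file.path(d, "mirnas.fa")))
  ann <- read_gff3_annotation(file.path(d, "annotation.gff3"))
  term_df <- read.delim(file.path(d, "gene_terms.tsv"),
                        stringsAsFactors = FALSE)
  terms <- split(term_df$gene, term_df$term)
  len_df <- read.delim(file.path(d, "gene_lengths.tsv"),
                       stringsAsFactors = FALSE)
  gene_lengths <- setNames(len_df$length, len_df$gene_id)
  methylated <- readLines(file.path(d, "methylated.txt"))
  methylated <- methylated[nzchar(methylated)]

  unmatched <- list(
    mirna = setdiff(rownames(mirna_counts$counts), names(mirnas)),
    mrna = setdiff(rownames(mrna_counts$counts), ann$genes$gene_id))
  n_un <- sum(lengths(unmatched))
  .stage_log("load", "%d miRNAs, %d genes, %d samples; %d unmatched IDs",
             nrow(mirna_counts$counts), nrow(mrna_counts$counts),
             nrow(design), n_un)
  if (n_un > 0)
    warning("load_inputs: ", n_un, " count feature(s) not found in the ",
            "annotation/FASTA inputs")
  list(design = design, mirna_counts = mirna_counts,
       mrna_counts = mrna_counts, genome = genome, annotation = ann,
       mirnas = mirnas, terms = terms, gene_lengths = gene_lengths,
       methylated = methylated, unmatched = unmatched)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis end to end
#'
#' simulate (optional) -> load -> filter -> normalize + PCA/cluster ->
#' differential expression + pattern partition -> miRNA locus
#' classification and clustering -> target prediction (three profiles) ->
#' 2-of-3 consensus -> correlation refinement and network statistics ->
#' enrichment (consensus targets, plus the per-method term intersection) ->
#' methylation-overlap test -> truth-panel concordance.  Every stage logs
#' input/output record counts; all result tables are TSVs under
#' `config$out_dir`; identical config + seed gives byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(config$simulate)) {
    .stage_log("simulate", "writing synthetic inputs to %s",
               config$input_dir)
    synth_dataset(config$sim, config$input_dir)
  }
  inp <- load_inputs(config)
  res <- list(inputs = inp, out_dir = config$out_dir)
  op <- function(f) file.path(config$out_dir, f)

  ## filter
  mir_f <- filter_low_counts(inp$mirna_counts, config$min_count,
                             config$min_samples)
  mrna_f <- filter_low_counts(inp$mrna_counts, config$min_count,
                              config$min_samples)
  .stage_log("filter", "miRNA %d -> %d; mRNA %d -> %d features",
             nrow(inp$mirna_counts$counts), nrow(mir_f$counts),
             nrow(inp$mrna_counts$counts), nrow(mrna_f$counts))
  res$mirna_filtered <- mir_f; res$mrna_filtered <- mrna_f

  ## normalize + QC
  mir_norm <- normalize_log_cpm(mir_f)
  mrna_norm <- normalize_log_cpm(mrna_f)
  res$mirna_norm <- mir_norm; res$mrna_norm <- mrna_norm
  for (side in c("mirna", "mrna")) {
    nrm <- if (side == "mirna") mir_norm else mrna_norm
    qc <- project_pca_and_cluster(nrm$logcpm)
    res[[paste0(side, "_qc")]] <- qc
    .write_tsv(data.frame(sample = rownames(qc$scores),
                          qc$scores[, 1:min(5, ncol(qc$scores))],
                          check.names = FALSE),
               op(sprintf("pca_%s.tsv", side)))
    .write_tsv(data.frame(sample = rownames(qc$dist), qc$dist,
                          check.names = FALSE),
               op(sprintf("dist_%s.tsv", side)))
  }
  .stage_log("qc", "PCA and clustering written")

  ## differential expression
  de_mir <- test_all_comparisons(mir_f, fdr = config$de_fdr)
  de_mrna <- test_all_comparisons(mrna_f, fdr = config$de_fdr)
  res$de_mirna <- de_mir; res$de_mrna <- de_mrna
  .write_tsv(de_mir, op("de_mirna.tsv"))
  .write_tsv(de_mrna, op("de_mrna.tsv"))
  pat_mir <- pattern_partition(de_mir)
  pat_mrna <- pattern_partition(de_mrna)
  res$pattern_mirna <- pat_mir; res$pattern_mrna <- pat_mrna
  .write_tsv(data.frame(pattern = names(pat_mir$counts),
                        n = pat_mir$counts), op("patterns_mirna.tsv"))
  .write_tsv(data.frame(pattern = names(pat_mrna$counts),
                        n = pat_mrna$counts), op("patterns_mrna.tsv"))
  .stage_log("de", "miRNA: %d/%d features DE in >=1 comparison",
             length(unique(de_mir$feature[de_mir$direction != "ns"])),
             nrow(mir_f$counts))
  .stage_log("de", "mRNA: %d/%d features DE in >=1 comparison",
             length(unique(de_mrna$feature[de_mrna$direction != "ns"])),
             nrow(mrna_f$counts))

  ## miRNA locus genomics
  cls <- classify_mirna_loci(inp$annotation$mirna_loci, inp$annotation)
  clus <- cluster_mirna_loci(inp$annotation$mirna_loci,
                             config$cluster_window)
  res$locus_classes <- cls; res$locus_clusters <- clus
  .write_tsv(cls, op("mirna_locus_classes.tsv"))
  .write_tsv(clus, op("mirna_locus_clusters.tsv"))
  .stage_log("genomics", "locus categories: %s",
             paste(names(table(cls$category)), table(cls$category),
                   sep = "=", collapse = ", "))

  ## target prediction
  regions <- extract_target_regions(inp$annotation, inp$genome,
                                    config$downstream_fallback)
  sites <- lapply(names(method_profiles()), function(pn) {
    s <- predict_targets(inp$mirnas, regions, pn)
    .stage_log("targets", "%s: %d (miRNA, gene) pairs", pn, nrow(s))
    s
  })
  names(sites) <- names(method_profiles())
  res$sites <- sites
  for (pn in names(sites)) .write_tsv(sites[[pn]],
                                      op(sprintf("sites_%s.tsv", pn)))
  cons <- consensus_pairs(sites)
  res$consensus <- cons
  .write_tsv(cons, op("consensus_pairs.tsv"))
  .stage_log("targets", "consensus (>=2 methods): %d pairs", nrow(cons))

  ## correlation refinement + network
  corr <- correlate_pairs(cons, mir_norm$logcpm, mrna_norm$logcpm)
  kept <- filter_and_sign(corr$tested, config$corr_fdr)
  net <- build_network_stats(kept, de = de_mrna)
  res$correlated <- corr; res$network <- net
  .write_tsv(kept, op("network_edges.tsv"))
  .write_tsv(net$mirna_nodes, op("network_mirna_nodes.tsv"))
  .write_tsv(net$gene_nodes, op("network_gene_nodes.tsv"))
  .write_tsv(data.frame(key = names(net$summary),
                        value = vapply(net$summary, function(v)
                          paste(format(v), collapse = ","), character(1))),
             op("network_summary.tsv"))
  .stage_log("network", "%d edges (%d positive / %d negative), %d miRNAs, %d genes",
             net$summary$n_edges, net$summary$n_positive,
             net$summary$n_negative, net$summary$n_mirnas,
             net$summary$n_genes)

  ## enrichment: approach 1 (consensus-correlated targets)
  universe <- rownames(mrna_f$counts)
  sel <- intersect(unique(kept$gene), universe)
  weights <- compute_length_weights(sel, universe, inp$gene_lengths)
  enr <- enrichment_test(inp$terms, sel, universe, weights,
                         n_perm = config$enrich_n_perm,
                         seed = derive_seed(config$master_seed, 10L))
  res$enrichment <- enr
  .write_tsv(enr, op("enrichment_consensus.tsv"))
  .stage_log("enrich", "consensus targets: %d terms tested, %d at q < %g",
             nrow(enr), sum(enr$q < config$enrich_fdr), config$enrich_fdr)

  ## enrichment: approach 2 (per-method term intersection)
  per_method_terms <- lapply(names(sites), function(pn) {
    pm_pairs <- sites[[pn]][, c("mirna", "gene")]
    pm_corr <- correlate_pairs(pm_pairs, mir_norm$logcpm, mrna_norm$logcpm)
    pm_kept <- filter_and_sign(pm_corr$tested, config$corr_fdr)
    pm_sel <- intersect(unique(pm_kept$gene), universe)
    pm_w <- compute_length_weights(pm_sel, universe, inp$gene_lengths)
    pm_enr <- enrichment_test(inp$terms, pm_sel, universe, pm_w,
                              n_perm = config$enrich_n_perm,
                              seed = derive_seed(config$master_seed, 11L))
    pm_enr$term[pm_enr$q < config$enrich_fdr]
  })
  names(per_method_terms) <- names(sites)
  inter <- withCallingHandlers(
    combine_by_go_intersection(per_method_terms),
    warning = function(w) invokeRestart("muffleWarning"))
  res$enrichment_intersection <- inter
  .write_tsv(inter, op("enrichment_method_intersection.tsv"))
  .stage_log("enrich", "per-method intersection: %d terms", nrow(inter))

  ## methylation overlap
  overlap_universe <- if (config$overlap_universe == "expressed") {
    universe
  } else {
    inp$annotation$genes$gene_id
  }
  ov_targets <- intersect(unique(cons$gene), overlap_universe)
  ov_meth <- intersect(inp$methylated, overlap_universe)
  ov <- fisher_overlap(ov_targets, ov_meth, overlap_universe)
  res$overlap <- ov
  .write_tsv(data.frame(
    key = c("a_target_meth", "b_target_only", "c_meth_only", "d_neither",
            "odds_ratio", "p_under", "p_two_sided"),
    value = c(ov$table[1, 1], ov$table[1, 2], ov$table[2, 1],
              ov$table[2, 2], ov$odds_ratio, ov$p_under, ov$p_two_sided)),
    op("methylation_overlap.tsv"))
  .stage_log("overlap", "odds ratio %.3g, one-sided p %.3g",
             ov$odds_ratio, ov$p_under)

  ## concordance panel against planted truth (when available)
  truth_path <- file.path(config$input_dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    de_both <- rbind(de_mir, de_mrna)
    seq_calls <- data.frame(id = de_both$feature,
                            comparison = de_both$comparison,
                            call = de_both$direction,
                            stringsAsFactors = FALSE)
    truth_calls <- seq_calls
    truth_calls$call <- "ns"
    for (cmp in names(truth$de_features)) {
      tf <- truth$de_features[[cmp]]
      if (length(tf$feature) == 0) next
      ix <- match(paste(tf$feature, cmp),
                  paste(truth_calls$id, truth_calls$comparison))
      ok <- !is.na(ix)
      truth_calls$call[ix[ok]] <- tf$expected[ok]
    }
    set.seed(derive_seed(config$master_seed, 12L))
    # panel biased toward features with a changed call, like a validation
    # panel of candidate features would be
    changed_ids <- unique(seq_calls$id[seq_calls$call != "ns"])
    other_ids <- setdiff(unique(seq_calls$id), changed_ids)
    panel <- c(sample(changed_ids, min(12L, length(changed_ids))),
               sample(other_ids, min(8L, length(other_ids))))
    in_panel <- seq_calls$id %in% panel
    conc <- pcr_concordance(seq_calls[in_panel, ],
                            truth_calls[in_panel, ])
    res$concordance <- conc
    .write_tsv(data.frame(
      subset = c("changed", "unchanged"),
      n = c(conc$changed$n, conc$unchanged$n),
      concordant = c(conc$changed$concordant, conc$unchanged$concordant),
      pct = c(conc$changed$pct, conc$unchanged$pct)),
      op("concordance_panel.tsv"))
    .stage_log("concordance", "changed %s%%, unchanged %s%%",
               format(conc$changed$pct), format(conc$unchanged$pct))
  }

  invisible(res)
}
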