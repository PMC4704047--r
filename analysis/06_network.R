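#!/usr/bin/env Rscript
# Pearson-correlation refinement of the consensus pairs (BH over all pairs,
# FDR 5%), sign classification, and bipartite network statistics.

source("analysis/00_config.R")
b <- load_bundle()
truth <- jsonlite::read_json(file.path(DATA_DIR, "truth.json"),
                             simplifyVector = TRUE)

cons <- read.delim(file.path(OUT_DIR, "consensus_pairs.tsv"),
                   stringsAsFactors = FALSE)
mir_n <- normalize_log_cpm(filter_low_counts(b$inputs$mirna_counts))
mrna_n <- normalize_log_cpm(filter_low_counts(b$inputs$mrna_counts))
de_mrna <- test_all_comparisons(filter_low_counts(b$inputs$mrna_counts),
                                fdr = b$cfg$de_fdr)

corr <- correlate_pairs(cons, mir_n$logcpm, mrna_n$logcpm)
kept <- filter_and_sign(corr$tested, b$cfg$corr_fdr)
net <- build_network_stats(kept, de = de_mrna)
write.table(kept, file.path(OUT_DIR, "network_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(net$mirna_nodes, file.path(OUT_DIR, "network_mirna_nodes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(net$gene_nodes, file.path(OUT_DIR, "network_gene_nodes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

s <- net$summary
planted <- paste(truth$coupled_pairs$mirna, truth$coupled_pairs$gene)
kept_keys <- paste(kept$mirna, kept$gene)
cat(sprintf("network: %d interactions (%d positive / %d negative), %d miRNAs, %d target genes\n",
            s$n_edges, s$n_positive, s$n_negative, s$n_mirnas, s$n_genes))
cat(sprintf("max-degree miRNA: %s with %d interactions\n",
            s$max_degree_mirna, s$max_degree_mirna_k))
cat(sprintf("planted couplings kept: %d/%d; non-planted kept edges: %d\n",
            sum(planted %in% kept_keys), length(planted),
            sum(!kept_keys %in% planted)))
cat(sprintf("fraction of target genes DE in >= 1 comparison: %.0f%%\n",
            100 * s$frac_targets_de))
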