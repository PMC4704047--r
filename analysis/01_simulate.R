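#!/usr/bin/env Rscript
# Generate the synthetic larval study: 3 castes x 5 replicates, 200 miRNAs,
# 3000 genes, planted 4-fold caste effects, 60 signed miRNA-target
# couplings (|r| = 0.95) with sites planted in 3'UTRs, and methylation
# labels with a planted odds ratio of 0.3 for target genes.

source("analysis/00_config.R")

ds <- synth_dataset(SIM, DATA_DIR)

cat("Wrote synthetic inputs to", DATA_DIR, "\n")
cat(sprintf(" - %d miRNAs, %d genes, %d samples\n",
            SIM$n_mirnas, SIM$n_genes, nrow(ds$design)))
cat(sprintf(" - %d planted couplings (%d negative), %d + %d planted DE features\n",
            nrow(ds$truth$coupled_pairs),
            sum(ds$truth$coupled_pairs$sign == -1),
            nrow(ds$truth$de_mirna), nrow(ds$truth$de_mrna)))
cat(sprintf(" - %d methylated genes (planted target odds ratio %.2g)\n",
            length(ds$methylated), SIM$methylation_target_or))
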