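#!/usr/bin/env Rscript
# Genomic classification of the miRNA loci (intergenic / intronic / UTR /
# CDS with strand relation to the host gene) and 1-kb single-linkage
# clustering.

source("analysis/00_config.R")
b <- load_bundle()
ann <- b$inputs$annotation

cls <- classify_mirna_loci(ann$mirna_loci, ann)
clus <- cluster_mirna_loci(ann$mirna_loci, b$cfg$cluster_window)
write.table(cls, file.path(OUT_DIR, "mirna_locus_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(clus, file.path(OUT_DIR, "mirna_locus_clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# locus-table style summary: counts per category with same/opposite strand
tab <- table(cls$category)
cat("locus categories:\n")
for (cat_i in names(tab)) {
  sub <- cls[cls$category == cat_i, ]
  if (cat_i == "intergenic") {
    cat(sprintf("  %-10s %d\n", cat_i, nrow(sub)))
  } else {
    cat(sprintf("  %-10s %d (%d same : %d opposite)\n", cat_i, nrow(sub),
                sum(sub$strand_relation == "same"),
                sum(sub$strand_relation == "opposite")))
  }
}
sizes <- attr(clus, "sizes")
cat(sprintf("clusters within %d bp: %d loci in %d multi-locus clusters\n",
            b$cfg$cluster_window, sum(sizes[sizes > 1]),
            sum(sizes > 1)))
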