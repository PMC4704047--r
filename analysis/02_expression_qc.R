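#!/usr/bin/env Rscript
# Count filtering (>= 5 counts in >= 5 samples), TMM log2-CPM
# normalization, and the PCA / Euclidean-distance clustering QC view in
# which each caste should group separately.

source("analysis/00_config.R")
b <- load_bundle()

for (side in c("mirna", "mrna")) {
  cm <- b$inputs[[paste0(side, "_counts")]]
  f <- filter_low_counts(cm, b$cfg$min_count, b$cfg$min_samples)
  nrm <- normalize_log_cpm(f)
  qc <- project_pca_and_cluster(nrm$logcpm)
  write.table(data.frame(sample = rownames(qc$scores),
                         qc$scores[, 1:5], check.names = FALSE),
              file.path(OUT_DIR, sprintf("pca_%s.tsv", side)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = rownames(qc$dist), qc$dist,
                         check.names = FALSE),
              file.path(OUT_DIR, sprintf("dist_%s.tsv", side)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # does the average-linkage tree split the castes cleanly at k = 3?
  k3 <- stats::cutree(qc$hclust, k = 3)
  caste <- f$design$caste[match(names(k3), f$design$sample)]
  pure <- all(vapply(split(caste, k3), function(x)
    length(unique(x)) == 1, logical(1)))
  cat(sprintf("%s: %d -> %d features after filtering; PC1 %.0f%% of variance; caste-pure 3-way clustering: %s\n",
              side, nrow(cm$counts), nrow(f$counts),
              100 * qc$explained_var[1] / sum(qc$explained_var),
              ifelse(pure, "yes", "no")))
}
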