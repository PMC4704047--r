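Package: beemirnet
Title: Caste-Specific miRNA-mRNA Integration in Honeybee Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative reanalysis pipeline linking caste-specific miRNA
    and mRNA expression in honeybee (Apis mellifera) larvae. Provides
    negative-binomial exact differential-expression testing with TMM
    normalization, seed-match and nearest-neighbour free-energy miRNA target
    prediction under three method profiles with a two-of-three consensus,
    Pearson-correlation refinement of the target network with FDR control,
    length-bias-corrected gene-set enrichment by weighted resampling, a
    Fisher-exact test of the overlap between miRNA targets and methylated
    genes, and genomic classification and clustering of miRNA loci. A
    synthetic-data generator with planted ground truth (negative-binomial
    counts with caste effects, planted target sites, signed miRNA-target
    couplings, and a planted methylation odds ratio) makes every stage
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
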