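# beemirnet

Integrative analysis of caste-specific miRNA and mRNA expression in
honeybee (*Apis mellifera*) larvae, rebuilt as a tested, reusable R
package.  Queens, workers and drones arise from one genome; during the
late larval stage their miRNA and transcript profiles diverge, and miRNAs
are thought to buffer (canalize) the committed developmental program.
The package implements the full chain that links the two expression
layers and contrasts miRNA regulation with gene-body DNA methylation:

1. **Differential expression** — count filtering (>= 5 counts in >= 5
   samples), TMM normalization, and an exact negative-binomial test per
   caste pair (variance $\mu + \phi\mu^2$, common dispersion by
   conditional maximum likelihood, conditional two-sided p, BH-adjusted,
   calls at FDR 1%), plus the three-way expression-pattern partition.
2. **Target prediction** — canonical seed matching (7mer-m8, 7mer-A1,
   8mer) and intermolecular nearest-neighbour duplex free energy by
   dynamic programming, under three method profiles bounded at -10, -20
   and -27 kcal/mol; pairs kept when predicted by >= 2 of the 3 methods.
3. **Correlation refinement** — Pearson correlation of each candidate
   pair's log2-CPM across the 15 samples, BH over all pairs, kept at
   FDR 5% and signed; bipartite network statistics (degrees, sign
   profiles, positive/negative tallies).
4. **Enrichment** — gene-set over-representation with gene-length
   selection-bias correction (monotone length weights, weighted
   resampling null), plus the per-method enriched-term intersection.
5. **Methylation overlap** — Fisher-exact 2x2 test of whether predicted
   targets are under-represented among methylated genes.
6. **miRNA locus genomics** — classification of miRNA loci (intergenic /
   intronic / UTR / CDS, strand relation to host gene) and 1-kb
   single-linkage clustering.

No external sequencing libraries are required: a first-class
synthetic-data generator produces every input — genome,
annotation, mature miRNAs, NB counts with planted 4-fold caste effects,
planted signed miRNA-target couplings (|r| = 0.95) with real sequence
sites in 3'UTRs, and methylation labels with a planted odds ratio — so
every stage is testable against known truth from one master seed.  It is
aimed at computational biologists who want the method chain itself:
auditable, seeded, and verified against independent oracles.

## Worked example

```r
library(beemirnet)

cfg <- pipeline_config(input_dir = "results/data", out_dir = "results",
                       master_seed = 1, sim = sim_config(master_seed = 1))
res <- run_pipeline(cfg)
```

The run logs each stage; with the default configuration (200 miRNAs,
3000 genes, 3 castes x 5 replicates) it prints, among others:

```
[filter] miRNA 200 -> 200; mRNA 3000 -> 2995 features
[de] mRNA: 183/2995 features DE in >=1 comparison
[targets] hybridization: 69 (miRNA, gene) pairs
[targets] consensus (>=2 methods): 1214 pairs
[network] 63 edges (43 positive / 20 negative), 63 miRNAs, 63 genes
[overlap] odds ratio 0.948, one-sided p 0.322
```

Read: of 3000 genes, 183 are called differentially expressed between at
least two castes at FDR 1% (150 were planted); the 2-of-3 consensus
nominates 1214 (miRNA, gene) pairs, and correlation refinement at FDR 5%
keeps 63 interactions — all 60 planted couplings (every sign correct)
plus 3 chance decoys — with the positive:negative split reflecting the
planted 70/30 sign mix.  The methylation test on this desk-scale network
(only 60 planted target genes) is underpowered, as expected; the powered
configuration is exercised by the acceptance script below.

Planted-truth recovery for any run:

```r
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
recovery_metrics(res, truth)
#> $de_sensitivity    0.943   $de_fdr  0
#> $coupling_sensitivity  1   $coupling_fdp  0.048
#> $coupling_sign_accuracy 1  $target_sensitivity 1
```

The numbered drivers under `analysis/` run the same stages as a narrative
workflow (`Rscript analysis/01_simulate.R`, then `02` ... `07`), each
printing what it found and writing its tables under `results/`.

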