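# Shared settings for the analysis drivers.  Run the scripts from the
# repository root, in order; each writes its tables under results/.

library(beemirnet)

ANALYSIS_SEED <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(OUT_DIR, showWarnings = FALSE, recursive = TRUE)

SIM <- sim_config(master_seed = ANALYSIS_SEED)

load_bundle <- function() {
  cfg <- pipeline_config(input_dir = DATA_DIR, out_dir = OUT_DIR,
                         master_seed = ANALYSIS_SEED, simulate = FALSE,
                         sim = SIM)
  list(cfg = cfg, inputs = load_inputs(cfg))
}
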