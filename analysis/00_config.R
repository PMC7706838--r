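# Shared settings for the numbered analysis scripts. Every script can be run
# from the repository root with, e.g.:  Rscript analysis/01_simulate.R
# Outputs accumulate under results/pipeline/.

library(erydecon)

MASTER_SEED <- 1L
OUT_DIR <- "results/pipeline"
CFG <- pipeline_config(seed = MASTER_SEED)   # study-default conditions
dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)

out_path <- function(...) file.path(OUT_DIR, ...)

# child seeds mirror run_pipeline()'s counter-based scheme so the staged
# scripts and the one-shot pipeline produce identical artifacts
child_seed <- function(stage) erydecon:::.child_seed(MASTER_SEED, stage)
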