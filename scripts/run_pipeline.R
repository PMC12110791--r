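#!/usr/bin/env Rscript
# Thin command-line wrapper over cnvpop::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --config conf.yaml
#   Rscript scripts/run_pipeline.R --out runs/demo --seed 7
#
# Exit codes: 0 ok, 2 configuration error, 3 data/stage error.

suppressPackageStartupMessages(library(cnvpop))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(config = NULL, out = NULL, seed = NULL)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) { message("unknown argument: ", args[i]); quit(status = 2) }
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}

cfg <- tryCatch({
  if (!is.null(opt$config)) {
    cfg <- read_pipeline_config(opt$config)
    if (!is.null(opt$out)) cfg$out_dir <- opt$out
    cfg
  } else if (!is.null(opt$out)) {
    seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
    pipeline_config(out_dir = opt$out, sim = sim_config(seed = seed))
  } else {
    stop("provide --config conf.yaml or --out <dir>")
  }
}, error = function(e) { message("configuration error: ", conditionMessage(e)); quit(status = 2) })

tryCatch({
  run_pipeline(cfg)
}, error = function(e) { message(conditionMessage(e)); quit(status = 3) })
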