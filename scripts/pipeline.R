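#!/usr/bin/env Rscript
# Thin shell wrapper over bondtrace::runPipeline().
#
# Usage:
#   Rscript scripts/pipeline.R --seed 1 --out run1 [--config cfg.yaml]
#                              [--paper-scale]

suppressPackageStartupMessages(library(bondtrace))

args <- commandArgs(trailingOnly = TRUE)
getArg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}

cfgPath <- getArg("--config", NA)
cfg <- if (!is.na(cfgPath)) cfgPath else {
  pipelineConfig(seed = as.integer(getArg("--seed", "1")),
                 outDir = getArg("--out", "bondtrace_run"),
                 paperScale = "--paper-scale" %in% args)
}
manifest <- runPipeline(cfg)
message("pipeline complete; manifest has ", length(manifest$hashes),
        " artifact hashes")
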