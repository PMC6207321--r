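#!/usr/bin/env Rscript

# Thin command-line wrapper over the floodr pipeline functions.
#
# Usage:
#   Rscript scripts/pipeline.R <simulate|gate|stats|flood|all>
#     [--config cfg.yaml] [--seed N] [--out DIR] [--log-level info|quiet]
#
# A YAML config (keys mirroring floodr::run_config()) drives every stage;
# command-line flags override the config.

suppressPackageStartupMessages({
  library(floodr)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1] %in%
      c("simulate", "gate", "stats", "flood", "all")) {
  stop("usage: pipeline.R <simulate|gate|stats|flood|all> [options]",
       call. = FALSE)
}
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = NULL),
  make_option("--log-level", type = "character", default = "info",
              dest = "log_level")
)), args = args[-1])

config <- if (!is.null(opts$config)) read_run_config(opts$config) else
  run_config()
if (!is.null(opts$seed)) config$seed <- opts$seed
if (!is.null(opts$out)) config$out_dir <- opts$out

log_info <- function(...) {
  if (!identical(opts$log_level, "quiet")) {
    message(format(Sys.time(), "%H:%M:%S "), ...)
  }
}

log_info("running '", cmd, "' (seed ", config$seed, ") -> ", config$out_dir)
switch(cmd,
  simulate = pipeline_simulate(config),
  gate = pipeline_gate(config),
  stats = pipeline_stats(config),
  flood = pipeline_flood(config),
  all = pipeline_all(config)
)
log_info("done")
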