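#!/usr/bin/env Rscript
# Thin command-line wrapper over ginilag::run_pipeline(). All analysis
# lives in the package; this script only parses flags.
#
# Usage:
#   Rscript scripts/run_pipeline.R --config run.yaml --out results/run
#   Rscript scripts/run_pipeline.R --seed 3 --out results/run   # simulate

suppressPackageStartupMessages({
  library(optparse)
  library(ginilag)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration (see read_run_config)"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "ginilag_run")
)))

cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else list()
if (is.null(cfg$seed)) cfg$seed <- opts$seed

res <- run_pipeline(cfg, outdir = opts$out)
cat("pipeline complete:", opts$out, "\n")
cat("samples:", res$manifest$n_samples,
    " models:", length(res$records),
    " network edges:", res$manifest$n_network_edges, "\n")
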