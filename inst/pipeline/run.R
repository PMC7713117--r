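#!/usr/bin/env Rscript
# Thin shell wrapper over erpcluster::run_pipeline(). Stages map onto the
# package functions; `all` runs the full simulate -> preprocess -> stats ->
# behaviour -> report chain.
#
#   Rscript run.R --config cfg.yaml [--stage all] [--seed 1]
#     [--n-permutations N] [--alpha A] [--out DIR] [--verbose]

suppressPackageStartupMessages(library(erpcluster))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i)) args[i + 1L] else default
}
has_flag <- function(flag) flag %in% args

config_path <- get_opt("--config")
stage <- get_opt("--stage", "all")
verbose <- has_flag("--verbose")

cfg <- if (!is.null(config_path)) {
  read_pipeline_config(config_path)
} else {
  pipeline_config()
}
if (!is.null(get_opt("--seed"))) cfg$seed <- as.integer(get_opt("--seed"))
if (!is.null(get_opt("--out"))) cfg$out_dir <- get_opt("--out")
if (!is.null(get_opt("--n-permutations"))) {
  cfg$stat$n_permutations <- as.integer(get_opt("--n-permutations"))
}
if (!is.null(get_opt("--alpha"))) cfg$stat$alpha <- as.numeric(get_opt("--alpha"))

cfg$contrasts <- switch(stage,
  "simulate" = character(),
  "behaviour" = character(),
  cfg$contrasts
)
if (verbose) message("running pipeline into ", cfg$out_dir)
res <- run_pipeline(cfg)
if (verbose) message("outputs: ", paste(res$manifest$outputs, collapse = ", "))
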