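#!/usr/bin/env Rscript

# Thin command-line wrapper over gvmux::run_pipeline().
#   Rscript scripts/run_gvmux.R <subcommand> [--config cfg.yaml]
#                               [--out out_dir] [--seed <int>]
# Subcommands: demo, simulate-scene, simulate-plate, build-matrix, unmix,
#              screen, seqdist.
# Exit codes: 0 success, 2 validation error, 3 computation degeneracy.

suppressPackageStartupMessages(library(gvmux))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  message("usage: run_gvmux.R <subcommand> [--config cfg.yaml] [--out dir] [--seed int]")
  quit(status = 2L)
}
subcommand <- args[1L]
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
cfg <- tryCatch({
  base <- get_arg("--config")
  cfg <- if (is.null(base)) default_run_config() else read_run_config(base)
  seed <- get_arg("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}, error = function(e) {
  message("configuration error: ", conditionMessage(e))
  quit(status = 2L)
})

status <- tryCatch({
  run_pipeline(cfg, subcommand, get_arg("--out", "gvmux_out"))
  0L
}, error = function(e) {
  msg <- conditionMessage(e)
  message("error: ", msg)
  if (grepl("invalid run configuration|'arg' should be one of", msg)) 2L else 3L
})
quit(status = status)
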