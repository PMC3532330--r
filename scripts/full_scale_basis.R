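#!/usr/bin/env Rscript
# Full-scale offline basis generation for the two packaged case studies,
# at their published study conditions:
#   switch:     {0..150}^2 (d = 22801), T = 1e7, 81 log-equidistant
#               training points on [0.005, 0.02]^2, eps_tol = 1e-12
#   oscillator: {0..300}^2 (d = 90601), T = 6, 30 log-equidistant
#               training values of k4 on [10, 100], eps_tol = 1e-12
# These are multi-hour offline runs (the reference implementations took
# 7.9 h and 16.5 h); run on demand, not part of the test suite:
#   Rscript scripts/full_scale_basis.R [switch|oscillator] [--out DIR]
# Trajectories are cached under <out>/cache so interrupted runs resume.

suppressPackageStartupMessages(library(cmerb))

args <- commandArgs(trailingOnly = TRUE)
which_model <- if (length(args) >= 1 && !startsWith(args[1], "--")) args[1] else "switch"
out <- "full_scale_results"
if ("--out" %in% args) out <- args[match("--out", args) + 1L]
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cache <- file.path(out, "cache")

run <- function(model, grid, theta_train, tag) {
  message("training ", tag, ": d = ", model$ss$d, ", ",
          nrow(theta_train), " training parameters")
  rb <- pod_greedy(operator = model$operator, P0 = model$P0, grid = grid,
                   theta_train = theta_train, fixed = model$params,
                   V_init = model$P0$P0, eps_tol = 1e-12, max_size = 200L,
                   cache_dir = cache, verbose = TRUE)
  save_artifact(rb, file.path(out, paste0(tag, "_basis.rds")))
  rep <- rb$report
  utils::write.csv(data.frame(N = rep$basis_sizes, eps_N = rep$eps),
                   file.path(out, paste0(tag, "_decay.csv")), row.names = FALSE)
  message(tag, ": basis of ", ncol(rb$V), " vectors (", rep$status,
          "), ", round(rep$elapsed / 3600, 2), " h")
  rb
}

if (which_model == "switch") {
  model <- build_switch()                       # {0..150}^2, T = 1e7
  grid <- time_grid(model$T_final, n = 100, spacing = "log", t1 = 1)
  theta_train <- make_training_set(model$varied, 9, spacing = "log")
  run(model, grid, theta_train, "switch")
} else if (which_model == "oscillator") {
  model <- build_oscillator()                   # {0..300}^2, T = 6
  grid <- time_grid(model$T_final, n = 100, spacing = "log", t1 = 1e-3)
  theta_train <- make_training_set(model$varied, 30, spacing = "log")
  run(model, grid, theta_train, "oscillator")
} else {
  stop("unknown model '", which_model, "' (use switch or oscillator)")
}
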