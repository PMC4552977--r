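#!/usr/bin/env Rscript

# Aggregates the per-replicate run tables into the two headline
# comparison tables:
#   results/scheme_comparison.csv  response to selection and inbreeding
#                                  rate per scheme (mean and SD across
#                                  replicates)
#   results/accuracy_by_step.csv   selection accuracy by scheme and step
#                                  (progeny-tested G vs marker-only M)
#
# Usage: Rscript analysis/03_summarize.R [config.yml]
# (run from the repository root, after analysis/02_run_schemes.R)

suppressPackageStartupMessages(library(rrgsim))

args <- commandArgs(trailingOnly = TRUE)
cfg_path <- if (length(args) >= 1L) args[1L] else "analysis/config.yml"
cfg <- load_config(if (file.exists(cfg_path)) cfg_path else NULL)

runs_dir <- file.path(cfg$run$out_dir, "runs")
rep_dirs <- list.dirs(runs_dir, recursive = FALSE)
if (length(rep_dirs) == 0L)
  stop("no run outputs found; run analysis/02_run_schemes.R first")

summaries <- do.call(rbind, lapply(rep_dirs, function(d) {
  s <- read.csv(file.path(d, "summary.csv"))
  s$replicate <- basename(d)
  s
}))

agg <- aggregate(
  cbind(cumulative_response_pct, annual_response_pct,
        dF_y_deli, dF_y_lame) ~ run + strategy + pattern + total_years,
  data = summaries,
  FUN = function(x) c(mean = mean(x), sd = sd(x)))
agg <- do.call(data.frame, agg)
agg <- agg[order(-agg$annual_response_pct.mean), ]
write.csv(agg, file.path(cfg$run$out_dir, "scheme_comparison.csv"),
          row.names = FALSE)

acc <- do.call(rbind, lapply(rep_dirs, function(d) {
  files <- list.files(d, pattern = "_accuracy\\.csv$", full.names = TRUE)
  do.call(rbind, lapply(files, function(f) {
    a <- read.csv(f)
    a$run <- sub("_accuracy\\.csv$", "", basename(f))
    a$replicate <- basename(d)
    a
  }))
}))
acc_tab <- aggregate(accuracy ~ run + step, data = acc,
                     FUN = function(x) c(mean = mean(x), sd = sd(x),
                                         n = length(x)))
acc_tab <- do.call(data.frame, acc_tab)
write.csv(acc_tab, file.path(cfg$run$out_dir, "accuracy_by_step.csv"),
          row.names = FALSE)

message("wrote ", file.path(cfg$run$out_dir, "scheme_comparison.csv"))
message("wrote ", file.path(cfg$run$out_dir, "accuracy_by_step.csv"))
print(acc_tab)
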