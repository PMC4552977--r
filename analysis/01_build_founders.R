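#!/usr/bin/env Rscript

# Builds the calibrated founder populations for every replicate:
# neutral burn-in, QTL architecture, two-population history, and the
# replicate-acceptance statistics. Saves one founders RDS per replicate
# plus a founder-statistics table.
#
# Usage: Rscript analysis/01_build_founders.R [config.yml]
# (run from the repository root; default config analysis/config.yml)

suppressPackageStartupMessages(library(rrgsim))

args <- commandArgs(trailingOnly = TRUE)
cfg_path <- if (length(args) >= 1L) args[1L] else "analysis/config.yml"
cfg <- load_config(if (file.exists(cfg_path)) cfg_path else NULL)

out_dir <- file.path(cfg$run$out_dir, "founders")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

map <- palm_map(cfg$genome$n_chr, cfg$genome$total_length,
                cfg$genome$n_loci)
params <- meiosis_params(cfg$genome$mutation_rate)

set.seed(cfg$run$seed)
rep_seeds <- sample.int(.Machine$integer.max, cfg$run$n_replicates)

stats_rows <- list()
for (r in seq_len(cfg$run$n_replicates)) {
  message(sprintf("replicate %d/%d (seed %d)", r, cfg$run$n_replicates,
                  rep_seeds[r]))
  set.seed(rep_seeds[r])
  base <- run_burnin(cfg$burnin$n_ind, cfg$burnin$n_gen, map, params)
  founders <- build_founders(
    base, map, params,
    n_qtl = cfg$architecture$n_qtl, p_pleio = cfg$architecture$p_pleio,
    rho = cfg$architecture$rho, base_var = cfg$architecture$base_var,
    maf_min = cfg$architecture$maf_min, h2 = cfg$architecture$h2,
    max_attempts = cfg$history$max_attempts)
  saveRDS(list(founders = founders, map = map, params = params,
               seed = rep_seeds[r]),
          file.path(out_dir, sprintf("rep%02d.rds", r)))
  stats_rows[[r]] <- data.frame(replicate = r, seed = rep_seeds[r],
                                accepted = founders$accepted,
                                attempts = founders$attempts,
                                t(unlist(founders$stats)))
}

stats <- do.call(rbind, stats_rows)
write.csv(stats, file.path(cfg$run$out_dir, "founder_stats.csv"),
          row.names = FALSE)
message("wrote ", file.path(cfg$run$out_dir, "founder_stats.csv"))
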