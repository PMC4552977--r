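#!/usr/bin/env Rscript

# Runs the four-cycle scheme comparison on each replicate's founder
# populations: pedigree-based reciprocal recurrent selection (RRS) and
# its genomic counterparts using parental genotypes only (RRGS_PAR) or
# parental genotypes plus 1700 genotyped hybrids (RRGS_HYB), the latter
# two with alternating (GMGM) and calibration-sparse (GMMM) patterns.
# Writes per-generation, accuracy and summary tables per replicate.
#
# Usage: Rscript analysis/02_run_schemes.R [config.yml]
# (run from the repository root, after analysis/01_build_founders.R)

suppressPackageStartupMessages(library(rrgsim))

args <- commandArgs(trailingOnly = TRUE)
cfg_path <- if (length(args) >= 1L) args[1L] else "analysis/config.yml"
cfg <- load_config(if (file.exists(cfg_path)) cfg_path else NULL)

founder_dir <- file.path(cfg$run$out_dir, "founders")
rds_files <- sort(list.files(founder_dir, pattern = "^rep[0-9]+\\.rds$",
                             full.names = TRUE))
if (length(rds_files) == 0L)
  stop("no founder replicates found; run analysis/01_build_founders.R first")

grid <- list(
  rrs       = function() scheme_config("RRS"),
  par_gmgm  = function() scheme_config("RRGS_PAR", pattern = "GMGM"),
  hyb_gmgm  = function() scheme_config("RRGS_HYB", pattern = "GMGM",
                                       n_genotyped_hybrids = 1700L),
  hyb_gmmm  = function() scheme_config("RRGS_HYB", pattern = "GMMM",
                                       n_genotyped_hybrids = 1700L))

for (f in rds_files) {
  rep_name <- sub("\\.rds$", "", basename(f))
  obj <- readRDS(f)
  run_dir <- file.path(cfg$run$out_dir, "runs", rep_name)
  runs <- list()
  for (nm in names(grid)) {
    message(sprintf("%s: %s", rep_name, nm))
    # one deterministic stream per (replicate, scheme)
    set.seed(obj$seed + match(nm, names(grid)))
    runs[[nm]] <- run_scheme(obj$founders, grid[[nm]](), obj$map,
                             obj$params, verbose = TRUE)
  }
  write_run_outputs(runs, run_dir, seed = obj$seed)
  message("wrote ", run_dir)
}
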