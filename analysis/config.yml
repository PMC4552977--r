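# Desk-scale configuration for the analysis drivers.
#
# The package defaults (study_config()) describe the full-scale study:
# 20,000 loci and a 2400-generation burn-in, which takes hours per
# replicate on one CPU. This file overrides only the neutral-diversity
# generation phase to a reduced scale that preserves the founder
# properties (differentiation, variances, heritabilities) while running
# in minutes. Delete the `genome`/`burnin` overrides to run full scale.

genome:
  n_loci: 6000

burnin:
  n_gen: 300

run:
  seed: 11
  n_replicates: 1
  out_dir: results
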