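# rrgsim

Forward-in-time stochastic simulation of a two-population hybrid
breeding program for a **multiplicative trait**: oil palm bunch
production, the product of bunch weight (BW) and bunch number (BN).

## The scientific problem

BW and BN are close to additive individually but negatively correlated
(pleiotropic QTL effects with correlation −0.9). Two long-isolated
breeding pools complement each other — one with high BW and low BN
("Deli"), one with the reverse ("La Mé") — so interpool hybrids
outperform both parents **without any dominance**: the heterosis is
purely multiplicative, `production = (μ_BW + g_BW) × (μ_BN + g_BN)`.

Such pools are improved by reciprocal recurrent selection (RRS):
parents of each pool are selected on the progeny-tested performance of
their hybrids, at ~20 years per cycle. Genomic selection can replace
some progeny tests with 6-year marker-only cycles. `rrgsim` simulates
four selection cycles and compares:

| Scheme | Evaluation | Typical pattern (years) |
|---|---|---|
| `RRS` | pedigree-based bivariate GCA model | `GGGG` (80) |
| `RRGS_PAR` | genomic kernels from parental genotypes (2500-SNP panel) | `GMGM` (52) |
| `RRGS_HYB` | origin-aware single-step model incl. genotyped hybrids | `GMMM` (38) |

where `G` is a progeny-tested calibration cycle (300 crosses × 45
offspring = 13,500 hybrid records) and `M` a marker-only cycle. Tracked
outcomes: response to selection in hybrid production, selection
accuracy, additive variances and genetic correlation, and pedigree
inbreeding.

## Core model

* **Genome**: 16 chromosomes, 17 Morgans, 20,000 loci at full scale;
  Poisson crossovers (Haldane), mutation 10⁻⁵/locus/gamete; compiled
  meiosis core.
* **Trait architecture**: `n_QTL` ∈ {100, 500, 1000} per trait, 60–90 %
  pleiotropic with bivariate-normal effects (ρ = −0.9), base additive
  variances 6 (BW) and 12 (BN), h² = 0.8.
* **Founders**: neutral burn-in → 100 generations of divergent
  selection → strong bottlenecks and mass selection → two
  pseudo-realistic RRS cycles; each replicate filtered against
  reference windows (F_ST ≈ 0.49, variances, h², correlations,
  inbreeding, LD shape).
* **Evaluation**: bivariate mixed models solved from the MME — pedigree
  GCA kernels (RRS), VanRaden genomic kernels (PAR), or a structured
  single-step H⁻¹ with allele-origin-aware G from hybrid gametotypes
  (HYB); dense or conjugate-gradient solvers; optional EM-REML.

See the vignette (`vignettes/heterosis-without-dominance.Rmd`) for the
full model description, numerical safeguards, and documented
cluster-scale expectations.

## Worked example

A complete miniature study (toy genome, compressed history, all scheme
machinery) runs in seconds:

```r
library(rrgsim)

fx  <- make_toy_fixture("tiny", seed = 42)
run <- run_scheme(fx$founders, fx$configs$hyb_gm, fx$map, fx$params)
run$summary
#> run_summary: +5.2% cumulative response over 38 years (+0.136%/yr)
#> dF_y (rel. to initial F): Deli 1.35%/yr, La Me 1.95%/yr
head(run$accuracy, 4)
#>   generation step  pop trait  n  accuracy
#> 1          0    G deli    bw 24 0.2301099
#> 2          0    G deli    bn 24 0.3868662
#> 3          0    G lame    bw 24 0.9718077
#> 4          0    G lame    bn 24 0.8748573
```

(At toy scale — 20 QTL, 24 candidates — accuracies are noisy; study
scale uses 120–300 candidates and full-size progeny tests.)

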