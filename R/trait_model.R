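#' Assign a bivariate pleiotropic QTL architecture
#'
#' Chooses QTL among segregating loci with minor allele frequency above
#' `maf_min` in the reference (base) population. A fraction `p_pleio` of
#' each trait's QTL are shared between bunch weight (BW) and bunch number
#' (BN); their substitution effects are drawn from a bivariate normal with
#' correlation `rho` and per-trait variance `base_var / n_qtl`, so the
#' base-population additive variance is governed by `base_var`. The
#' remaining QTL are trait-private with univariate normal effects of the
#' same per-trait variance. Each trait sees exactly `n_qtl` QTL, hence
#' `n_qtl * (2 - p_pleio)` distinct loci overall.
#'
#' @param base_pop A `palm_pop`: the reference population whose allele
#'   frequencies define eligibility and the base additive variances.
#' @param n_qtl Number of QTL per trait (the study grid uses 100, 500,
#'   1000).
#' @param p_pleio Fraction of pleiotropic QTL (grid: 0.60, 0.75, 0.90).
#' @param rho Correlation of pleiotropic effects (default -0.9, the
#'   antagonism between BW and BN).
#' @param base_var Base-population additive variances, `c(bw = 6, bn = 12)`.
#' @param maf_min Minimum minor allele frequency for QTL eligibility.
#' @param means Trait means on the observed scale, `c(bw = 15, bn = 15)`;
#'   kept high enough that bunch production (BW x BN) stays positive.
#' @return An object of class `qtl_arch`: list with `loci` (distinct QTL
#'   locus indices), `alpha` (matrix loci x 2, columns bw/bn, zero where a
#'   locus does not affect a trait), `pleio` (logical), `base_freq`
#'   (allele-1 frequencies at `loci` in `base_pop`), `base_var_realized`
#'   (realized base additive variances, sum of 2p(1-p)a^2), `offset`
#'   (constant mapping absolute genetic values to the observed scale) and
#'   the generating parameters.
#' @export
assign_qtl <- function(base_pop, n_qtl = 500L, p_pleio = 0.75, rho = -0.9,
                       base_var = c(bw = 6, bn = 12), maf_min = 0.1,
                       means = c(bw = 15, bn = 15)) {
  stopifnot(n_qtl >= 1, p_pleio >= 0, p_pleio <= 1, abs(rho) <= 1)
  p_all <- allele_freq(base_pop)
  eligible <- which(pmin(p_all, 1 - p_all) > maf_min)
  n_pleio <- round(p_pleio * n_qtl)
  n_priv <- n_qtl - n_pleio             # per trait
  n_distinct <- n_pleio + 2L * n_priv
  if (length(eligible) < n_distinct)
    stop(sprintf("only %d loci with MAF > %g; %d needed",
                 length(eligible), maf_min, n_distinct))
  loci <- sample(eligible, n_distinct)
  pleio <- c(rep(TRUE, n_pleio), rep(FALSE, 2L * n_priv))
  v <- base_var / n_qtl
  alpha <- matrix(0, n_distinct, 2L, dimnames = list(NULL, c("bw", "bn")))
  if (n_pleio > 0) {
    z <- matrix(rnorm(2L * n_pleio), n_pleio, 2L)
    # Cholesky of the 2x2 effect covariance
    a_bw <- sqrt(v["bw"]) * z[, 1L]
    a_bn <- sqrt(v["bn"]) * (rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L])
    alpha[seq_len(n_pleio), "bw"] <- a_bw
    alpha[seq_len(n_pleio), "bn"] <- a_bn
  }
  if (n_priv > 0) {
    alpha[n_pleio + seq_len(n_priv), "bw"] <- rnorm(n_priv, 0, sqrt(v["bw"]))
    alpha[n_pleio + n_priv + seq_len(n_priv), "bn"] <-
      rnorm(n_priv, 0, sqrt(v["bn"]))
  }
  pq <- p_all[loci]
  w <- 2 * pq * (1 - pq)
  base_var_real <- c(bw = sum(w * alpha[, "bw"]^2),
                     bn = sum(w * alpha[, "bn"]^2))
  # mean absolute genetic value in the base population: sum over loci of
  # 2 p alpha (expected dosage times effect)
  mean_g <- c(bw = sum(2 * pq * alpha[, "bw"]),
              bn = sum(2 * pq * alpha[, "bn"]))
  structure(list(loci = as.integer(loci), alpha = alpha, pleio = pleio,
                 base_freq = pq, base_var_realized = base_var_real,
                 offset = means - mean_g, means = means,
                 n_qtl = as.integer(n_qtl), p_pleio = p_pleio, rho = rho,
                 base_var = base_var),
            class = "qtl_arch")
}

#' @export
print.qtl_arch <- function(x, ...) {
  cat(sprintf(
    "qtl_arch: %d QTL/trait, %.0f%% pleiotropic (%d distinct loci), rho = %.2f\n",
    x$n_qtl, 100 * x$p_pleio, length(x$loci), x$rho))
  cat(sprintf("realized base additive variances: BW %.3f, BN %.3f\n",
              x$base_var_realized["bw"], x$base_var_realized["bn"]))
  invisible(x)
}

#' Trait parameters (heritability, means, residual variances)
#'
#' Residual variances are fixed once from the realized base-population
#' additive variances via `sigma_e^2 = sigma_a^2 (1 - h2) / h2` with base
#' heritability 0.8 per trait, and then held constant for the whole study;
#' the base population therefore has heritability exactly `h2` and the
#' initial breeding populations, whose additive variance has been eroded by
#' bottlenecks and selection, show the lower realized heritabilities typical
#' of the real populations. The residual correlation between traits is zero.
#'
#' @param arch A `qtl_arch` (source of the realized base variances), or
#'   `NULL` if `sigma_a` is given directly.
#' @param h2 Base-population narrow-sense heritability (in (0, 1]).
#' @param sigma_a Optional explicit additive variances `c(bw=, bn=)`.
#' @return Object of class `trait_params` with `h2`, `means`, `sigma_e`.
#' @export
trait_params <- function(arch = NULL, h2 = 0.8, sigma_a = NULL) {
  if (h2 <= 0 || h2 > 1) stop("h2 must be in (0, 1]")
  if (is.null(sigma_a)) {
    stopifnot(inherits(arch, "qtl_arch"))
    sigma_a <- arch$base_var_realized
  }
  means <- if (!is.null(arch)) arch$means else c(bw = 15, bn = 15)
  structure(list(h2 = h2, means = means,
                 sigma_e = sigma_a * (1 - h2) / h2),
            class = "trait_params")
}

#' Residual variance from additive variance and heritability
#'
#' Closed form `sigma_a^2 (1 - h2) / h2`.
#' @param sigma_a Additive variance(s).
#' @param h2 Heritability in (0, 1].
#' @export
residual_variance <- function(sigma_a, h2) {
  if (any(h2 <= 0) || any(h2 > 1)) stop("h2 must be in (0, 1]")
  sigma_a * (1 - h2) / h2
}

#' Absolute genetic values at the QTL
#'
#' Sum over QTL of dosage times substitution effect. Absolute (uncentered)
#' values are comparable across generations; deviations relative to any
#' reference population are obtained with [true_breeding_values()].
#'
#' @param dosage Integer dosage matrix (individuals x `arch$loci`), e.g.
#'   `pop_dosage(pop, arch$loci)`.
#' @param arch A `qtl_arch`.
#' @return Numeric matrix, individuals x 2 (bw, bn).
#' @export
genetic_values <- function(dosage, arch) {
  stopifnot(ncol(dosage) == length(arch$loci))
  dosage %*% arch$alpha
}

#' True breeding values relative to a reference population
#'
#' Standard biallelic decomposition: a genotype with dosage x contributes
#' (x - 2p) * alpha for each trait, where p is the allele-1 frequency in
#' the reference population; summed over QTL. When the frequencies are
#' those of the same population, the mean breeding value is zero.
#'
#' @inheritParams genetic_values
#' @param freqs Allele-1 frequencies at `arch$loci` in the reference
#'   population.
#' @export
true_breeding_values <- function(dosage, arch, freqs = arch$base_freq) {
  stopifnot(length(freqs) == length(arch$loci))
  if (any(freqs < 0) || any(freqs > 1)) stop("frequencies must lie in [0, 1]")
  sweep(dosage, 2L, 2 * freqs) %*% arch$alpha
}

#' Additive variance from allele frequencies
#'
#' Sum over the trait's QTL of 2p(1-p)alpha^2, the intrapopulation additive
#' variance under linkage equilibrium. Also returns per-QTL shares, used by
#' the replicate-acceptance rule that discards architectures where a single
#' QTL explains more than 20 percent of the total.
#'
#' @param freqs Allele-1 frequencies at `arch$loci` in the population.
#' @param arch A `qtl_arch`.
#' @param trait `"bw"` or `"bn"`.
#' @return Scalar variance with attribute `shares` (per-locus fraction of
#'   the total; zero-effect loci contribute zero).
#' @export
additive_variance <- function(freqs, arch, trait = c("bw", "bn")) {
  trait <- match.arg(trait)
  contrib <- 2 * freqs * (1 - freqs) * arch$alpha[, trait]^2
  v <- sum(contrib)
  structure(v, shares = if (v > 0) contrib / v else contrib)
}

#' Additive (co)variance matrix from allele frequencies
#'
#' 2x2 matrix with diagonal `additive_variance` terms and off-diagonal
#' sum of 2p(1-p) alpha_bw alpha_bn (pleiotropic loci only contribute).
#' @inheritParams additive_variance
#' @export
additive_covmat <- function(freqs, arch) {
  w <- 2 * freqs * (1 - freqs)
  m <- crossprod(arch$alpha, w * arch$alpha)
  dimnames(m) <- list(c("bw", "bn"), c("bw", "bn"))
  m
}

#' Phenotypes from breeding values
#'
#' Phenotype = trait mean + breeding value + independent normal residual
#' per trait, with the residual variances fixed in `trait_params`.
#'
#' @param tbv Numeric matrix individuals x 2 (bw, bn) of breeding values on
#'   the deviation scale (or absolute genetic values minus their reference
#'   mean).
#' @param tp A `trait_params`.
#' @return Matrix individuals x 2 of phenotypes on the observed scale.
#' @export
residual_and_phenotype <- function(tbv, tp) {
  n <- nrow(tbv)
  e <- cbind(rnorm(n, 0, sqrt(tp$sigma_e["bw"])),
             rnorm(n, 0, sqrt(tp$sigma_e["bn"])))
  ph <- sweep(tbv + e, 2L, tp$means, "+")
  colnames(ph) <- c("bw", "bn")
  ph
}

#' Observed-scale trait values of a population
#'
#' Absolute genetic values shifted by the architecture's offset so that the
#' base population has the configured trait means. Adding residual noise
#' with [residual_and_phenotype()] (on the centered values) gives
#' phenotypes; this helper returns the noise-free genotypic values.
#'
#' @param pop A `palm_pop`.
#' @param arch A `qtl_arch`.
#' @export
trait_values <- function(pop, arch) {
  g <- genetic_values(pop_dosage(pop, arch$loci), arch)
  sweep(g, 2L, arch$offset, "+")
}

#' Phenotypes of a population
#'
#' @inheritParams trait_values
#' @param tp A `trait_params`.
#' @return Matrix individuals x 2 (bw, bn) on the observed scale.
#' @export
pop_phenotypes <- function(pop, arch, tp) {
  tv <- trait_values(pop, arch)
  n <- nrow(tv)
  tv + cbind(rnorm(n, 0, sqrt(tp$sigma_e["bw"])),
             rnorm(n, 0, sqrt(tp$sigma_e["bn"])))
}
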