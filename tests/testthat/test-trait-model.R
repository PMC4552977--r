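synthetic_base <- function(n = 60L, L = 3000L, seed = 11) {
  set.seed(seed)
  h <- matrix(rbinom(2L * n * L, 1L, 0.5), 2L * n, L)
  palm_pop(h, id = seq_len(n), sire = rep(NA_integer_, n),
           dam = rep(NA_integer_, n), generation = 0L, label = "BASE")
}

test_that("QTL assignment respects counts, eligibility and pleiotropy structure", {
  base <- synthetic_base()
  set.seed(12)
  arch <- assign_qtl(base, n_qtl = 200L, p_pleio = 0.75, maf_min = 0.1)
  n_pleio <- round(0.75 * 200L)
  expect_equal(sum(arch$pleio), n_pleio)
  expect_equal(length(arch$loci), n_pleio + 2L * (200L - n_pleio))
  p <- allele_freq(base)[arch$loci]
  expect_true(all(pmin(p, 1 - p) > 0.1))
  # private QTL affect exactly one trait
  priv <- !arch$pleio
  expect_true(all((arch$alpha[priv, "bw"] == 0) !=
                    (arch$alpha[priv, "bn"] == 0)))
  expect_true(all(arch$alpha[arch$pleio, "bw"] != 0))
})

test_that("pleiotropic effects recover the negative correlation of -0.9", {
  base <- synthetic_base()
  set.seed(13)
  arch <- assign_qtl(base, n_qtl = 1000L, p_pleio = 0.75, rho = -0.9,
                     maf_min = 0.1)
  ab <- arch$alpha[arch$pleio, ]
  expect_lt(abs(cor(ab[, "bw"], ab[, "bn"]) - (-0.9)), 0.06)
})

test_that("per-QTL effect variance scales the base additive variance", {
  base <- synthetic_base()
  set.seed(14)
  arch <- assign_qtl(base, n_qtl = 1000L, p_pleio = 0.75,
                     base_var = c(bw = 6, bn = 12), maf_min = 0.1)
  expect_lt(abs(var(arch$alpha[arch$alpha[, "bw"] != 0, "bw"]) /
                  (6 / 1000) - 1), 0.15)
  expect_lt(abs(var(arch$alpha[arch$alpha[, "bn"] != 0, "bn"]) /
                  (12 / 1000) - 1), 0.15)
})

test_that("breeding values follow the (x - 2p) alpha decomposition", {
  arch <- structure(list(loci = 1:2,
                         alpha = matrix(c(1, -2, 0.5, 4), 2L, 2L,
                                        dimnames = list(NULL, c("bw", "bn"))),
                         base_freq = c(0.25, 0.5)),
                    class = "qtl_arch")
  dosage <- rbind(c(2L, 0L), c(1L, 1L))
  tbv <- true_breeding_values(dosage, arch, freqs = c(0.25, 0.5))
  # individual 1: (2 - 0.5) * 1 + (0 - 1) * (-2) = 3.5 for bw
  expect_equal(unname(tbv[1L, ]), c(1.5 * 1 + (-1) * (-2),
                                    1.5 * 0.5 + (-1) * 4))
  expect_equal(unname(tbv[2L, ]), c(0.5 * 1, 0.5 * 0.5))
})

test_that("additive variance equals the sum of 2pq alpha^2 with unit share total", {
  arch <- structure(list(loci = 1:3,
                         alpha = matrix(c(1, 2, 0, 1, 0, 3), 3L, 2L,
                                        dimnames = list(NULL, c("bw", "bn")))),
                    class = "qtl_arch")
  p <- c(0.5, 0.1, 0.3)
  v <- additive_variance(p, arch, "bw")
  expect_equal(as.numeric(v), 2 * 0.25 * 1 + 2 * 0.09 * 4)
  expect_equal(sum(attr(v, "shares")), 1)
  cm <- additive_covmat(p, arch)
  expect_equal(cm["bw", "bw"], as.numeric(v))
  expect_equal(cm["bw", "bn"], 2 * 0.5 * 0.5 * 1 * 1)  # only locus 1 shared
})

test_that("residual variances follow sigma_a (1 - h2) / h2", {
  expect_equal(residual_variance(4, 0.8), 1)
  expect_equal(residual_variance(c(bw = 2, bn = 8), 0.5), c(bw = 2, bn = 8))
  expect_error(residual_variance(1, 0), "h2")
  base <- synthetic_base(n = 40L, L = 500L, seed = 15)
  set.seed(16)
  arch <- assign_qtl(base, n_qtl = 50L, maf_min = 0.1)
  tp <- trait_params(arch, h2 = 0.8)
  expect_equal(unname(tp$sigma_e),
               unname(arch$base_var_realized * 0.2 / 0.8))
})

test_that("the observed-scale offset centers the base population at the trait means", {
  base <- synthetic_base(n = 50L, L = 800L, seed = 17)
  set.seed(18)
  arch <- assign_qtl(base, n_qtl = 60L, maf_min = 0.1,
                     means = c(bw = 15, bn = 15))
  tv <- trait_values(base, arch)
  expect_equal(unname(colMeans(tv)), c(15, 15), tolerance = 1e-10)
})

test_that("phenotypes add means and independent per-trait residual noise", {
  set.seed(19)
  tp <- structure(list(h2 = 0.8, means = c(bw = 15, bn = 15),
                       sigma_e = c(bw = 1, bn = 4)),
                  class = "trait_params")
  tbv <- matrix(0, 4000L, 2L)
  ph <- residual_and_phenotype(tbv, tp)
  expect_lt(abs(mean(ph[, "bw"]) - 15), 0.1)
  expect_lt(abs(var(ph[, "bw"]) - 1), 0.15)
  expect_lt(abs(var(ph[, "bn"]) - 4), 0.5)
  expect_lt(abs(cor(ph[, 1L], ph[, 2L])), 0.05)
})
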