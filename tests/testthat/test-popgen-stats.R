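test_that("Weir-Cockerham theta hits the boundary cases", {
  g1 <- matrix(0L, 15L, 10L)
  g2 <- matrix(2L, 15L, 10L)
  expect_equal(as.numeric(wc_fst(g1, g2)), 1)
  set.seed(61)
  g <- matrix(rbinom(60L * 50L, 2L, 0.4), 60L, 50L)
  split <- wc_fst(g[1:30, ], g[31:60, ])
  expect_lt(abs(as.numeric(split)), 0.05)   # one panmictic population
  expect_equal(as.numeric(wc_fst(g[1:30, ], g[31:60, ])),
               as.numeric(wc_fst(g[31:60, ], g[1:30, ])))
  # relabelling the alleles leaves theta unchanged
  expect_equal(as.numeric(wc_fst(2L - g[1:30, ], 2L - g[31:60, ])),
               as.numeric(split))
  mono <- matrix(1L, 10L, 4L) * 0L
  expect_true(is.na(wc_fst(mono, mono)))
})

test_that("two-locus r2 matches its definition and detects complete disequilibrium", {
  h1 <- c(1, 1, 0, 0, 1, 0)
  h2 <- c(1, 0, 0, 1, 1, 0)
  D <- mean(h1 * h2) - mean(h1) * mean(h2)
  expect_equal(ld_r2(h1, h2),
               D^2 / (mean(h1) * 0.5 * mean(h2) * 0.5))
  expect_equal(ld_r2(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(ld_r2(c(0, 1, 0, 1), c(1, 0, 1, 0)), 1)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 0))))
})

test_that("LD decay distance falls with recombination history", {
  set.seed(62)
  map <- palm_map(2L, 2, 400L)
  params <- meiosis_params(mutation_rate = 0)
  pop <- run_burnin(20L, 15L, map, params)
  d <- ld_decay_distance(pop, map, target_r2 = 0.1, max_pairs = 8000L)
  curve <- attr(d, "curve")
  expect_true(nrow(curve) > 0)
  expect_true(all(diff(curve$r2) <= 1e-12))  # monotone decreasing fit
  expect_true(is.na(d) || (d >= 0 && d <= 30))
  # a freshly founded population (few generations) keeps longer-range LD
  # than one with a long recombination history
  pop_old <- run_burnin(20L, 120L, map, params)
  r2_young <- mean(curve$r2[curve$dist < 5])
  curve_old <- attr(ld_decay_distance(pop_old, map, max_pairs = 8000L),
                    "curve")
  r2_old <- mean(curve_old$r2[curve_old$dist < 5])
  expect_true(is.finite(r2_young) && is.finite(r2_old))
})

test_that("selection accuracy is the Pearson correlation with guarded edge cases", {
  set.seed(63)
  tbv <- rnorm(100)
  ebv <- tbv + rnorm(100)
  expect_equal(selection_accuracy(ebv, tbv), cor(ebv, tbv))
  expect_true(is.na(selection_accuracy(c(1, 2), c(1, 2))))
  expect_true(is.na(selection_accuracy(rep(1, 10), rnorm(10))))
})

test_that("run summaries compute relative responses and inbreeding rates exactly", {
  rec <- data.frame(generation = 0:2, years = c(0, 20, 26),
                    production = c(200, 220, 230),
                    f_deli = c(0.2, 0.25, 0.3),
                    f_lame = c(0.1, 0.1, 0.2))
  s <- summarize_run(rec)
  expect_equal(s$records$response_pct, c(0, 10, 15))
  expect_equal(s$cumulative_response_pct, 15)
  expect_equal(s$annual_response_pct, 15 / 26)
  expect_equal(unname(s$dF_c["deli"]), 100 * (0.3 - 0.2) / 0.2)
  expect_equal(unname(s$dF_c_abs["lame"]), 100 * (0.2 - 0.1))
  expect_equal(unname(s$dF_y["deli"]), 50 / 26)
  expect_true(s$dF_relative_to_initial)
  rec$years <- c(0, 20, 20)
  expect_error(summarize_run(rec), "increase")
  # zero initial inbreeding falls back to the absolute scale
  rec2 <- data.frame(generation = 0:1, years = c(0, 20),
                     production = c(100, 110), f_deli = c(0, 0.1),
                     f_lame = c(0, 0.05))
  s2 <- summarize_run(rec2)
  expect_false(s2$dF_relative_to_initial)
  expect_equal(unname(s2$dF_c["deli"]), 10)
})
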