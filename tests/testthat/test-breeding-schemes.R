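test_that("scheme configurations encode the cycle calendar and study constraints", {
  cfg <- scheme_config("RRS")
  expect_equal(sum(ifelse(cfg$steps == "G", cfg$years_g, cfg$years_m)), 80)
  cfg2 <- scheme_config("RRGS_HYB", pattern = "GMGM",
                        n_genotyped_hybrids = 300L)
  expect_equal(sum(ifelse(cfg2$steps == "G", cfg2$years_g, cfg2$years_m)), 52)
  cfg3 <- scheme_config("RRGS_HYB", pattern = "GMMM", n_candidates = 300L,
                        n_genotyped_hybrids = 1700L)
  expect_equal(sum(ifelse(cfg3$steps == "G", cfg3$years_g, cfg3$years_m)), 38)
  expect_error(scheme_config("RRS", pattern = "GMGM"), "progeny-test only")
  expect_error(scheme_config("RRGS_HYB"), "genotyped hybrids")
  expect_error(scheme_config("RRGS_PAR", pattern = "MGGG"), "first cycle")
  expect_error(scheme_config("RRGS_PAR", n_candidates = 77L), "120 or 300")
})

test_that("progeny-test designs balance parent usage and avoid duplicate pairs", {
  set.seed(51)
  plan <- design_progeny_test(120L, 120L, 300L)
  expect_equal(nrow(plan), 300L)
  for (side in c("deli", "lame")) {
    usage <- tabulate(plan[[side]], 120L)
    expect_true(all(usage %in% 2:3))
    expect_equal(sum(usage == 3L), 60L)
    expect_equal(mean(usage), 2.5)
  }
  expect_equal(anyDuplicated(plan), 0L)
})

test_that("within-population matings realize 80 percent of the selfing half diallel evenly", {
  set.seed(52)
  plan <- make_within_pop_matings(20L, 0.8, 300L)
  expect_equal(nrow(plan), 168L)  # 0.8 * 20 * 21 / 2
  expect_true(all(plan$p1 <= plan$p2))
  part <- tabulate(plan$p1, 20L) + tabulate(plan$p2, 20L)  # selfs count twice
  expect_equal(sum(part), 336L)
  expect_lte(max(part) - min(part), 2L)
  expect_equal(sum(plan$n_offspring), 300L)
  expect_lte(max(plan$n_offspring) - min(plan$n_offspring), 1L)
  # fewer offspring than crosses: the realized crosses shrink accordingly
  set.seed(53)
  plan2 <- make_within_pop_matings(20L, 0.8, 120L)
  expect_equal(nrow(plan2), 120L)
  expect_equal(sum(plan2$n_offspring), 120L)
})

test_that("parents are selected on expected cross production against the opposite mean", {
  gca_d <- cbind(bw = c(2, 0, -2, 1), bn = c(0, 0, 0, 0.5))
  gca_l <- cbind(bw = c(0, 0), bn = c(1, -1))
  sel <- select_parents(gca_d, gca_l, means = c(bw = 15, bn = 15),
                        n_selected = 2L)
  # scores are (15 + gca_bw)(15 + gca_bn): candidates 1 and 4 lead
  expect_setequal(sel$deli, c(1L, 4L))
  sel2 <- select_parents(gca_d, gca_l, c(bw = 15, bn = 15), 1L,
                         eligible_deli = c(2L, 3L))
  expect_equal(sel2$deli, 2L)
  expect_error(select_parents(gca_d, gca_l, c(bw = 15, bn = 15), 3L,
                              eligible_deli = 1L), "fewer eligible")
})

test_that("marker panels respect the MAF threshold and exclude the QTL", {
  set.seed(54)
  n <- 40L
  freqs <- c(0.5, 0.02, 0.3, 0.5, 0.01, 0.45)
  dosage <- sapply(freqs, function(p) rbinom(n, 2L, p))
  panel <- select_snp_panel(dosage, n_panel = 2L, maf_min = 0.04,
                            exclude = 1L)
  expect_true(all(panel %in% c(3L, 4L, 6L)))
  expect_length(panel, 2L)
  expect_message(select_snp_panel(dosage, n_panel = 10L, maf_min = 0.04),
                 "using all")
})

test_that("expected hybrid production is the factorial mean of parental-mean products", {
  tv_d <- cbind(bw = c(10, 20), bn = c(30, 10))
  tv_l <- cbind(bw = c(10, 30), bn = c(10, 20))
  grid <- expand.grid(deli = 1:2, lame = 1:2)
  manual <- mean((tv_d[grid$deli, 1] + tv_l[grid$lame, 1]) / 2 *
                   (tv_d[grid$deli, 2] + tv_l[grid$lame, 2]) / 2)
  expect_equal(measure_hybrid_production(tv_d, tv_l), manual)
  pairs <- data.frame(deli = c(1L, 2L), lame = c(2L, 1L))
  manual2 <- mean((tv_d[pairs$deli, 1] + tv_l[pairs$lame, 1]) / 2 *
                    (tv_d[pairs$deli, 2] + tv_l[pairs$lame, 2]) / 2)
  expect_equal(measure_hybrid_production(tv_d, tv_l, pairs), manual2)
})

test_that("a simulated progeny test produces the full record set with even genotyping", {
  fx <- toy_fixture()
  f <- fx$founders
  set.seed(55)
  pt_d <- 1:12; pt_l <- 1:12
  plan <- design_progeny_test(12L, 12L, 30L)
  panel <- select_snp_panel(rbind(pop_dosage(f$deli), pop_dosage(f$lame)),
                            n_panel = 40L, maf_min = 0.02,
                            exclude = f$arch$loci)
  pt <- simulate_progeny_test(f$deli, f$lame, pt_d, pt_l, plan,
                              n_per_cross = 5L, f$arch, f$tp, fx$map,
                              fx$params, panel = panel, n_genotyped = 20L)
  expect_equal(nrow(pt$records), 150L)
  expect_true(all(pt$records$deli %in% pt_d))
  expect_equal(nrow(pt$g), 150L)
  expect_length(pt$genotyped$idx, 20L)
  per_cross <- tabulate(pt$cross[pt$genotyped$idx], 30L)
  expect_lte(max(per_cross) - min(per_cross), 1L)
  expect_equal(dim(pt$genotyped$deli_gam), c(20L, length(panel)))
  expect_true(all(pt$genotyped$deli_gam %in% 0:1))
  expect_true(all(pt$within_cross_var >= 0))
})

test_that("a four-cycle run tracks the calendar, accuracies and inbreeding", {
  fx <- toy_fixture()
  set.seed(56)
  run <- run_scheme(fx$founders, fx$configs$par_gm, fx$map, fx$params)
  expect_equal(run$records$generation, 0:4)
  expect_equal(run$records$years, c(0, 20, 26, 46, 52))
  expect_true(all(is.finite(run$records$production)))
  expect_true(all(run$records$f_deli >= 0 & run$records$f_deli <= 1))
  acc <- run$accuracy
  expect_setequal(unique(acc$step[acc$generation %in% c(0, 2)]), "G")
  expect_setequal(unique(acc$step[acc$generation %in% c(1, 3)]), "M")
  expect_equal(nrow(acc), 4L * 4L)   # 4 generations x 2 pops x 2 traits
  expect_equal(run$summary$total_years, 52)
  # the model pedigree is a subset of the inbreeding pedigree
  expect_true(all(run$ped$id %in% run$ped_full$id))
})

test_that("selection on true combining abilities raises expected production", {
  fx <- toy_fixture()
  f <- fx$founders
  g_d <- genetic_values(pop_dosage(f$deli, f$arch$loci), f$arch)
  g_l <- genetic_values(pop_dosage(f$lame, f$arch$loci), f$arch)
  tv_d <- sweep(g_d, 2L, f$arch$offset, "+")
  tv_l <- sweep(g_l, 2L, f$arch$offset, "+")
  set.seed(57)
  sel <- select_parents(sweep(g_d, 2L, colMeans(g_d)) / 2,
                        sweep(g_l, 2L, colMeans(g_l)) / 2,
                        means = colMeans((tv_d + tv_l) / 2),
                        n_selected = 6L)
  expect_gt(measure_hybrid_production(tv_d[sel$deli, ], tv_l[sel$lame, ]),
            measure_hybrid_production(tv_d, tv_l))
})
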