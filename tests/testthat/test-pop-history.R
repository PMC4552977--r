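test_that("mass selection keeps exactly the top fraction on the phenotype product", {
  set.seed(41)
  map <- palm_map(2L, 1, 100L)
  pop <- run_burnin(10L, 0L, map)
  pheno <- cbind(bw = c(5, 1, 3, 2, 4, 6, 7, 1.5, 2.5, 8),
                 bn = c(2, 9, 3, 4, 2, 1, 2, 8.0, 4.0, 2))
  sel <- mass_select(pop, 0.3, pheno = pheno)
  prod <- pheno[, 1L] * pheno[, 2L]
  expect_equal(sort(attr(sel, "index")),
               sort(order(-prod)[1:3]))
  expect_equal(n_ind(sel), 3L)
  expect_error(mass_select(pop, 0, pheno = pheno), "retain_frac")
})

test_that("pseudo progeny tests hit the target accuracy and preserve scale", {
  tbv <- rnorm(3000, 0, 2)
  expect_equal(pseudo_progeny_test(tbv, 1), tbv - mean(tbv))
  set.seed(42)
  ebv <- pseudo_progeny_test(tbv, 0.8)
  expect_lt(abs(cor(ebv, tbv) - 0.8), 0.03)
  expect_lt(abs(sd(ebv) / sd(tbv) - 1), 0.05)
  expect_message(pseudo_progeny_test(rep(1, 10), 0.8), "zero-variance")
})

test_that("history configuration rejects invalid fractions", {
  expect_error(history_config(deli_retain = 0), "retain")
  expect_error(history_config(prerrs_accuracy = c(2, 0.9)))
  expect_s3_class(history_config(), "history_config")
})

test_that("the divergence phase yields two populations of the requested size", {
  fx <- toy_fixture()
  set.seed(43)
  arch <- fx$founders$arch
  tp <- fx$founders$tp
  div <- divergence_phase(fx$base, arch, tp, fx$map, fx$params,
                          n_gen = 3L, size = 12L)
  expect_equal(n_ind(div$A), 12L)
  expect_equal(n_ind(div$B), 12L)
  expect_equal(div$A$label, "A")
  expect_error(divergence_phase(div$A, arch, tp, fx$map, fx$params,
                                n_gen = 1L, size = 12L), "too small")
})

test_that("a phenotype-era selection cycle produces the requested offspring with pedigree links", {
  fx <- toy_fixture()
  f <- fx$founders
  set.seed(44)
  cyc <- pre_rrs_cycle(f$deli, f$lame, f$arch, f$tp, fx$map, fx$params,
                       target_r = 0.8, n_offspring = 18L, n_selected = 5L,
                       id_start = 10000L)
  expect_equal(n_ind(cyc$deli), 18L)
  expect_equal(n_ind(cyc$lame), 18L)
  expect_equal(length(cyc$selected$deli), 5L)
  expect_true(all(cyc$deli$sire %in% f$deli$id[cyc$selected$deli]))
  expect_true(all(cyc$deli$dam %in% f$deli$id[cyc$selected$deli]))
  expect_true(all(cyc$deli$id >= 10000L))
  expect_true(all(cyc$lame$id > max(cyc$deli$id)))
})

test_that("pedigree truncation keeps the last generations and blanks their founders", {
  ped <- data.frame(id = 1:8,
                    sire = c(NA, NA, 1L, 1L, 3L, 3L, 5L, 5L),
                    dam = c(NA, NA, 2L, 2L, 4L, 4L, 6L, 6L),
                    generation = c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L),
                    label = "Deli")
  out <- rrgsim:::trim_pedigree(ped, deli_gens = 2L, lame_gens = 2L)
  expect_equal(sort(out$id), 5:8)
  expect_true(all(is.na(out$sire[out$id %in% 5:6])))
  expect_equal(out$sire[out$id %in% 7:8], c(5L, 5L))
})

test_that("calibration windows are centred on the per-cell reference means", {
  tg <- calibration_targets(500L, 0.75)
  win <- tg$windows
  fst <- win[win$stat == "fst", ]
  expect_equal((fst$lo + fst$hi) / 2, 0.47)
  expect_true(all(win$hi > win$lo))
  expect_equal(tg$max_qtl_share, 0.20)
  # floors guarantee a minimum half width
  expect_true(all(win$hi - win$lo >= 2 * 0.03 - 1e-12))
  # an off-grid cell falls back to the pooled mean
  tg2 <- calibration_targets(250L, 0.5)
  expect_equal(tg2$cell, "250 50")
  expect_true(nrow(tg2$windows) == nrow(win))
})

test_that("replicate acceptance passes inside the windows and reports each criterion", {
  tg <- calibration_targets(500L, 0.75)
  win <- tg$windows
  stats <- as.list(setNames((win$lo + win$hi) / 2, win$stat))
  stats$max_qtl_share <- 0.1
  stats$ld_deli <- 5; stats$ld_lame <- 2.5
  ok <- accept_replicate(stats, tg)
  expect_true(as.logical(ok))
  rep <- attr(ok, "report")
  expect_true(all(rep$pass))
  stats$fst <- 0.9
  stats$ld_lame <- 8
  bad <- accept_replicate(stats, tg)
  expect_false(as.logical(bad))
  repb <- attr(bad, "report")
  expect_false(repb$pass[repb$criterion == "fst"])
  expect_false(repb$pass[repb$criterion == "ld_shape_deli_gt_lame"])
})

test_that("founder construction yields two populations with a consistent pedigree", {
  fx <- toy_fixture()
  f <- fx$founders
  expect_s3_class(f, "founders")
  expect_equal(n_ind(f$deli), 24L)
  expect_equal(n_ind(f$lame), 24L)
  expect_silent(validate_pedigree(f$ped))
  expect_silent(validate_pedigree(f$ped_full))
  expect_true(all(f$ped$id %in% f$ped_full$id))
  expect_true(all(c(f$deli$id, f$lame$id) %in% f$ped$id))
  # deeper pedigree cannot show less identity by descent
  expect_gte(mean(pedigree_inbreeding(f$ped_full, f$deli$id)),
             mean(pedigree_inbreeding(f$ped, f$deli$id)))
  expect_true(is.finite(f$stats$fst))
  expect_lt(f$stats$corr_deli, 0)   # antagonistic traits stay negatively correlated
  expect_lt(f$stats$corr_lame, 0)
})
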