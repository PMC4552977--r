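test_that("the initial population has every locus at allele frequency one half", {
  set.seed(1)
  map <- palm_map(n_chr = 2L, total_length = 1, n_loci = 120L)
  pop <- run_burnin(10L, 0L, map)
  expect_equal(unname(allele_freq(pop)), rep(0.5, 120L))
  expect_equal(n_ind(pop), 10L)
})

test_that("heterozygosity decays by 1/(2N) per generation under Wright-Fisher mating", {
  set.seed(2)
  map <- palm_map(n_chr = 4L, total_length = 4, n_loci = 400L)
  params <- meiosis_params(mutation_rate = 0)
  N <- 20L; t <- 30L
  het <- replicate(3, {
    pop <- run_burnin(N, t, map, params, pairing = "wright_fisher")
    mean_heterozygosity(pop)
  })
  expected <- 0.5 * (1 - 1 / (2 * N))^t
  expect_lt(abs(mean(het) - expected), 0.06)
})

test_that("equal-contribution mating conserves diversity better than Wright-Fisher", {
  map <- palm_map(n_chr = 4L, total_length = 4, n_loci = 300L)
  params <- meiosis_params(mutation_rate = 0)
  het <- sapply(1:4, function(r) {
    set.seed(100 + r)
    h_eq <- mean_heterozygosity(run_burnin(20L, 40L, map, params,
                                           pairing = "equal"))
    set.seed(100 + r)
    h_wf <- mean_heterozygosity(run_burnin(20L, 40L, map, params,
                                           pairing = "wright_fisher"))
    c(eq = h_eq, wf = h_wf)
  })
  expect_gt(mean(het["eq", ]) - mean(het["wf", ]), 0)
})

test_that("crossover counts are Poisson with mean equal to the map length in Morgans", {
  set.seed(3)
  map <- palm_map(n_chr = 4L, total_length = 2, n_loci = 200L)
  pop <- run_burnin(4L, 0L, map)
  xo <- replicate(600, sum(attr(meiose(pop, map, meiosis_params(), 1L),
                               "crossovers")))
  expect_lt(abs(mean(xo) - 2), 0.3)
  expect_gt(var(xo) / mean(xo), 0.7)   # Poisson: variance equals mean
  expect_lt(var(xo) / mean(xo), 1.4)
})

test_that("without mutation a gamete only carries parental alleles", {
  set.seed(4)
  map <- palm_map(n_chr = 2L, total_length = 1, n_loci = 150L)
  pop <- run_burnin(6L, 2L, map, meiosis_params(mutation_rate = 0))
  for (k in 1:20) {
    i <- sample.int(6L, 1L)
    g <- meiose(pop, map, meiosis_params(mutation_rate = 0), i)
    h1 <- pop$haplo[2L * i - 1L, ]
    h2 <- pop$haplo[2L * i, ]
    expect_true(all(g == h1 | g == h2))
  }
})

test_that("mutation flips approximately mu * L alleles per gamete", {
  set.seed(5)
  L <- 500L
  map <- palm_map(n_chr = 2L, total_length = 1, n_loci = L)
  # a fully homozygous parent: any deviation in the gamete is a mutation
  h <- matrix(rep(rbinom(L, 1L, 0.5), each = 2L), nrow = 2L)
  pop <- palm_pop(h, id = 1L, sire = NA_integer_, dam = NA_integer_,
                  generation = 0L, label = "T")
  mu <- 0.02
  flips <- replicate(200, {
    g <- meiose(pop, map, meiosis_params(mutation_rate = mu), 1L)
    sum(g != pop$haplo[1L, ])
  })
  expect_gt(mean(flips), 8)    # expectation mu * L = 10
  expect_lt(mean(flips), 11.5)
})

test_that("recombination fractions follow Haldane's map function", {
  set.seed(6)
  L <- 50L
  map <- palm_map(n_chr = 1L, total_length = 0.5, n_loci = L)
  h <- rbind(rep(0L, L), rep(1L, L))
  pop <- palm_pop(h, id = 1L, sire = NA_integer_, dam = NA_integer_,
                  generation = 0L, label = "T")
  params <- meiosis_params(mutation_rate = 0)
  i <- 5L
  j <- which.min(abs(map$pos - (map$pos[i] + 0.2)))  # ~0.2 Morgan apart
  d <- abs(map$pos[j] - map$pos[i])
  rec <- replicate(1500, {
    g <- meiose(pop, map, params, 1L)
    g[i] != g[j]
  })
  expected <- 0.5 * (1 - exp(-2 * d))
  expect_lt(abs(mean(rec) - expected), 0.045)
})

test_that("equal-contribution pairing uses every parent exactly twice without selfing", {
  set.seed(7)
  for (n in c(4L, 12L, 30L)) {
    pairs <- equal_contribution_pairing(n)
    expect_equal(nrow(pairs), n)
    expect_equal(sort(tabulate(as.vector(pairs), n)), rep(2L, n))
    expect_true(all(pairs[, 1L] != pairs[, 2L]))
  }
})

test_that("offspring records its parents and generation in the pedigree fields", {
  set.seed(8)
  map <- palm_map(n_chr = 2L, total_length = 1, n_loci = 100L)
  pop <- run_burnin(8L, 1L, map)
  pairs <- cbind(c(1L, 3L), c(2L, 5L))
  off <- next_generation(pop, pairs, map, meiosis_params(), id_start = 50L)
  expect_equal(off$id, c(50L, 51L))
  expect_equal(off$sire, pop$id[c(1L, 3L)])
  expect_equal(off$dam, pop$id[c(2L, 5L)])
  expect_equal(off$generation, pop$generation + 1L)
  expect_equal(n_ind(off), 2L)
})

test_that("restricting gametes to a locus subset matches the full gamete", {
  map <- palm_map(n_chr = 2L, total_length = 1, n_loci = 100L)
  set.seed(9)
  pop <- run_burnin(6L, 2L, map)
  keep <- c(3L, 17L, 55L, 90L)
  set.seed(10)
  g_full <- gametes(pop, c(1L, 4L, 6L), map, meiosis_params())
  set.seed(10)
  g_keep <- gametes(pop, c(1L, 4L, 6L), map, meiosis_params(), keep = keep)
  expect_equal(g_keep, g_full[, keep, drop = FALSE])
})
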