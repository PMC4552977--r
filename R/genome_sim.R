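#' Simulate one meiosis
#'
#' Produces a gamete from one parent: a crossover mosaic of its two
#' haplotypes with a Poisson number of crossovers per chromosome (mean
#' equal to the chromosome length in Morgans, positions uniform, no
#' interference), followed by independent symmetric allele flips with the
#' configured mutation rate.
#'
#' @param pop A `palm_pop` holding the parent.
#' @param map The `palm_map` the haplotypes refer to.
#' @param params A `meiosis_params` object.
#' @param index Index of the parent within `pop`.
#' @return Integer 0/1 gamete of length `map$n_loci`, with attribute
#'   `crossovers`: the per-chromosome crossover counts.
#' @export
meiose <- function(pop, map, params = meiosis_params(), index = 1L) {
  if (ncol(pop$haplo) != map$n_loci)
    stop("haplotype length does not match the map")
  res <- cpp_gametes(pop$haplo, as.integer(index), map$chr, map$pos,
                     map$chr_len, params$mutation_rate, integer(0))
  g <- as.integer(res$gametes[1L, ])
  attr(g, "crossovers") <- as.integer(res$crossovers[1L, ])
  g
}

#' Batch gamete production
#'
#' Vectorized meiosis over many parents (the workhorse behind burn-in,
#' crosses and progeny tests). Optionally restricts the returned gametes to
#' a subset of loci to keep memory low when only QTL and marker-panel
#' columns are needed downstream.
#'
#' @inheritParams meiose
#' @param parents Integer vector of parent indices, one gamete per entry.
#' @param keep Optional locus indices to retain in the output.
#' @return Integer matrix, `length(parents)` rows by `length(keep)` (or
#'   `map$n_loci`) columns.
#' @export
gametes <- function(pop, parents, map, params = meiosis_params(),
                    keep = NULL) {
  if (ncol(pop$haplo) != map$n_loci)
    stop("haplotype length does not match the map")
  res <- cpp_gametes(pop$haplo, as.integer(parents), map$chr, map$pos,
                     map$chr_len, params$mutation_rate,
                     if (is.null(keep)) integer(0) else as.integer(keep))
  res$gametes
}

#' Equal-contribution random pairing
#'
#' Random mating plan in which every individual contributes exactly two
#' gametes to the next generation and selfing is excluded, as used during
#' the neutral burn-in.
#'
#' @param n Population size (even, at least 2), or a `palm_pop`.
#' @return Integer matrix with `n` rows and columns `sire`, `dam`; each
#'   index in `1:n` appears exactly twice over the two columns and no row
#'   pairs an individual with itself.
#' @export
equal_contribution_pairing <- function(n) {
  if (inherits(n, "palm_pop")) n <- n_ind(n)
  n <- as.integer(n)
  if (n < 2L || n %% 2L != 0L) stop("population size must be even and >= 2")
  for (attempt in 1:100) {
    slots <- sample(rep.int(seq_len(n), 2L))
    pairs <- matrix(slots, ncol = 2L)
    bad <- which(pairs[, 1L] == pairs[, 2L])
    tries <- 0L
    while (length(bad) > 0L && tries < 10L * n) {
      i <- bad[1L]
      j <- sample.int(n, 1L)
      if (j != i && pairs[j, 2L] != pairs[i, 1L] &&
          pairs[i, 2L] != pairs[j, 1L]) {
        tmp <- pairs[i, 2L]
        pairs[i, 2L] <- pairs[j, 2L]
        pairs[j, 2L] <- tmp
      }
      bad <- which(pairs[, 1L] == pairs[, 2L])
      tries <- tries + 1L
    }
    if (length(bad) == 0L) {
      colnames(pairs) <- c("sire", "dam")
      return(pairs)
    }
  }
  stop("could not build a selfing-free equal-contribution pairing")
}

#' Advance a population by one generation of random mating
#'
#' @param pop A `palm_pop`.
#' @param pairs Mating plan: matrix of parent indices with columns sire,
#'   dam; one offspring per row.
#' @param map,params See [meiose()].
#' @param generation Generation index of the offspring.
#' @param id_start First id to assign to offspring (`NA` to keep ids
#'   local, i.e. `1:n`).
#' @export
next_generation <- function(pop, pairs, map, params = meiosis_params(),
                            generation = pop$generation + 1L,
                            id_start = NA_integer_) {
  h <- cpp_next_generation(pop$haplo, as.integer(pairs[, 1L]),
                           as.integer(pairs[, 2L]), map$chr, map$pos,
                           map$chr_len, params$mutation_rate)
  n <- nrow(pairs)
  id <- if (is.na(id_start)) seq_len(n) else seq.int(id_start, length.out = n)
  palm_pop(h, id = id, sire = pop$id[pairs[, 1L]], dam = pop$id[pairs[, 2L]],
           generation = generation, label = pop$label)
}

#' Neutral burn-in to mutation-drift equilibrium
#'
#' Simulates a closed random-mating population over discrete generations,
#' starting from independent equifrequent alleles at every locus. With the
#' default equal-contribution mating each individual leaves exactly two
#' gametes; a plain Wright-Fisher alternative (parents drawn uniformly with
#' replacement across offspring) is available for drift calibration.
#'
#' @param n_ind Population size (even).
#' @param n_gen Number of generations.
#' @param map A `palm_map`.
#' @param params A `meiosis_params`.
#' @param pairing `"equal"` (equal contribution, no selfing) or
#'   `"wright_fisher"` (uniform parent sampling, no selfing).
#' @return The final-generation `palm_pop`, with attributes
#'   `freq_spectrum` (allele frequencies of the 1 allele at every locus)
#'   and `n_segregating`.
#' @export
run_burnin <- function(n_ind = 200L, n_gen = 2400L, map = palm_map(),
                       params = meiosis_params(),
                       pairing = c("equal", "wright_fisher")) {
  stopifnot(n_ind >= 2L, n_gen >= 0L)
  pairing <- match.arg(pairing)
  # exactly equifrequent alleles at every locus in generation 0
  h0 <- matrix(0L, nrow = 2L * n_ind, ncol = map$n_loci)
  for (j in seq_len(map$n_loci)) h0[sample.int(2L * n_ind, n_ind), j] <- 1L
  pop <- palm_pop(h0, label = "BASE")
  for (g in seq_len(n_gen)) {
    pairs <- if (pairing == "equal") {
      equal_contribution_pairing(n_ind)
    } else {
      t(vapply(seq_len(n_ind), function(i) sample.int(n_ind, 2L),
               integer(2L)))
    }
    pop <- next_generation(pop, pairs, map, params, generation = g)
  }
  p <- allele_freq(pop)
  attr(pop, "freq_spectrum") <- p
  attr(pop, "n_segregating") <- sum(p > 0 & p < 1)
  pop
}
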