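#' Diploid population container
#'
#' A population is a set of diploid individuals over a common genetic map.
#' Haplotypes are stored as an integer 0/1 matrix with two consecutive rows
#' per individual (rows 2i-1 and 2i belong to individual i).
#'
#' @param haplo Integer matrix of 0/1 alleles, `2 * n` rows by `n_loci`
#'   columns.
#' @param id Integer ids, one per individual (unique within a study).
#' @param sire,dam Integer ids of the parents (`NA` for founders).
#' @param generation Generation index (scalar).
#' @param label Population label, e.g. "BASE", "A", "B", "Deli", "LaMe",
#'   "Hybrid".
#' @return An object of class `palm_pop`.
#' @export
palm_pop <- function(haplo, id = seq_len(nrow(haplo) / 2L),
                     sire = rep(NA_integer_, length(id)),
                     dam = rep(NA_integer_, length(id)),
                     generation = 0L, label = "BASE") {
  stopifnot(is.matrix(haplo), nrow(haplo) %% 2L == 0L)
  n <- nrow(haplo) / 2L
  stopifnot(length(id) == n, length(sire) == n, length(dam) == n)
  if (!all(haplo %in% c(0L, 1L))) stop("alleles must be 0/1")
  structure(list(haplo = haplo, id = as.integer(id),
                 sire = as.integer(sire), dam = as.integer(dam),
                 generation = as.integer(generation), label = label),
            class = "palm_pop")
}

#' Number of individuals in a population
#' @param pop A `palm_pop`.
#' @export
n_ind <- function(pop) nrow(pop$haplo) / 2L

#' @export
print.palm_pop <- function(x, ...) {
  cat(sprintf("palm_pop '%s': %d individuals, %d loci, generation %d\n",
              x$label, n_ind(x), ncol(x$haplo), x$generation))
  invisible(x)
}

#' Allele-dosage matrix of a population
#'
#' @param pop A `palm_pop`.
#' @param loci Optional locus indices to restrict to.
#' @return Integer matrix, individuals by loci, entries in 0..2 (count of
#'   the 1 allele).
#' @export
pop_dosage <- function(pop, loci = NULL) {
  h <- pop$haplo
  if (!is.null(loci)) h <- h[, loci, drop = FALSE]
  n <- nrow(h) / 2L
  h[2L * seq_len(n) - 1L, , drop = FALSE] + h[2L * seq_len(n), , drop = FALSE]
}

#' Allele frequencies (of the 1 allele) in a population
#' @inheritParams pop_dosage
#' @export
allele_freq <- function(pop, loci = NULL) {
  h <- pop$haplo
  if (!is.null(loci)) h <- h[, loci, drop = FALSE]
  colMeans(h)
}

#' Subset a population by individual index
#' @param pop A `palm_pop`.
#' @param idx Individual indices to keep.
#' @export
pop_subset <- function(pop, idx) {
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  palm_pop(pop$haplo[rows, , drop = FALSE], pop$id[idx], pop$sire[idx],
           pop$dam[idx], pop$generation, pop$label)
}

#' Expected heterozygosity across loci
#'
#' Mean of 2p(1-p) over loci, the usual drift diagnostic.
#' @param pop A `palm_pop`.
#' @export
mean_heterozygosity <- function(pop) {
  p <- allele_freq(pop)
  mean(2 * p * (1 - p))
}
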