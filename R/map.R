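#' Genetic map with equally spaced loci
#'
#' Builds the genome representation used throughout the simulator: a set of
#' chromosomes with lengths in Morgans and ordered biallelic loci. The
#' default emulates an oil-palm-like genome of 16 chromosomes totalling
#' 17 M carrying 20000 equally spaced loci.
#'
#' @param n_chr Number of chromosomes.
#' @param total_length Total genome length in Morgans. Ignored when
#'   `chr_len` is supplied.
#' @param n_loci Total number of loci, spread over chromosomes in
#'   proportion to their length.
#' @param chr_len Optional vector of per-chromosome lengths in Morgans.
#' @return An object of class `palm_map`: a list with `chr` (chromosome
#'   index per locus), `pos` (position in Morgans within the chromosome),
#'   `chr_len`, `n_chr` and `n_loci`. Loci are ordered by chromosome and
#'   position, strictly increasing within a chromosome.
#' @examples
#' map <- palm_map(n_chr = 2, total_length = 1, n_loci = 10)
#' @export
palm_map <- function(n_chr = 16, total_length = 17, n_loci = 20000,
                     chr_len = NULL) {
  if (is.null(chr_len)) {
    stopifnot(n_chr >= 1, total_length > 0)
    chr_len <- rep(total_length / n_chr, n_chr)
  } else {
    n_chr <- length(chr_len)
    stopifnot(all(chr_len > 0))
  }
  stopifnot(n_loci >= n_chr)
  # proportional allocation of loci to chromosomes
  alloc <- diff(round(cumsum(chr_len) / sum(chr_len) * n_loci))
  alloc <- c(round(chr_len[1] / sum(chr_len) * n_loci), alloc)
  alloc[alloc < 1] <- 1
  while (sum(alloc) != n_loci) { # fix rounding drift on the largest chromosome
    i <- which.max(chr_len)
    alloc[i] <- alloc[i] + sign(n_loci - sum(alloc))
  }
  chr <- rep(seq_len(n_chr), alloc)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    s <- chr_len[c] / alloc[c]
    (seq_len(alloc[c]) - 0.5) * s
  }), use.names = FALSE)
  m <- structure(list(chr = as.integer(chr), pos = pos, chr_len = chr_len,
                      n_chr = n_chr, n_loci = as.integer(n_loci)),
                 class = "palm_map")
  validate_palm_map(m)
  m
}

validate_palm_map <- function(m) {
  stopifnot(length(m$chr) == m$n_loci, length(m$pos) == m$n_loci)
  for (c in seq_len(m$n_chr)) {
    p <- m$pos[m$chr == c]
    if (length(p) == 0) next
    if (any(diff(p) <= 0)) stop("locus positions must strictly increase within a chromosome")
    if (any(p < 0) || any(p > m$chr_len[c])) stop("locus outside its chromosome")
  }
  invisible(m)
}

#' @export
print.palm_map <- function(x, ...) {
  cat(sprintf("palm_map: %d chromosomes, %.3g M total, %d loci\n",
              x$n_chr, sum(x$chr_len), x$n_loci))
  invisible(x)
}

#' Meiosis parameters
#'
#' @param mutation_rate Probability of a symmetric allele flip per locus and
#'   per meiosis (default 1e-5). Crossovers follow a Poisson count per
#'   chromosome with mean equal to its length in Morgans (no interference).
#' @return An object of class `meiosis_params`.
#' @export
meiosis_params <- function(mutation_rate = 1e-5) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  structure(list(mutation_rate = mutation_rate), class = "meiosis_params")
}
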