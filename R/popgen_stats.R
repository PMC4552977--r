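#' Weir-Cockerham Fst between two populations
#'
#' Multi-locus ratio-of-averages theta: per-locus variance components a
#' (among populations), b (among individuals within populations) and c
#' (within individuals) are summed over loci before taking the ratio.
#'
#' @param geno1,geno2 Dosage matrices (individuals x loci, 0/1/2) on a
#'   shared locus set.
#' @return Scalar theta (`NA` when no locus is polymorphic), with
#'   attribute `n_loci_used`.
#' @export
wc_fst <- function(geno1, geno2) {
  stopifnot(ncol(geno1) == ncol(geno2), nrow(geno1) > 0, nrow(geno2) > 0)
  r <- 2
  n1 <- nrow(geno1); n2 <- nrow(geno2)
  p1 <- colMeans(geno1) / 2; p2 <- colMeans(geno2) / 2
  h1 <- colMeans(geno1 == 1L); h2 <- colMeans(geno2 == 1L)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  if (!any(poly)) return(structure(NA_real_, n_loci_used = 0L))
  theta <- sum(a[poly]) / sum((a + b + cc)[poly])
  structure(theta, n_loci_used = sum(poly))
}

#' Two-locus squared correlation of alleles (r2)
#'
#' @param h1,h2 0/1 haplotype vectors over the same gametes.
#' @return r2 = D^2 / (p1 q1 p2 q2), `NA` if either locus is monomorphic.
#' @export
ld_r2 <- function(h1, h2) {
  p1 <- mean(h1); p2 <- mean(h2)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  D <- mean(h1 * h2) - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

#' Distance at which linkage disequilibrium decays to a target r2
#'
#' Builds an r2-versus-distance curve from locus pairs within
#' `max_dist_cm`, averages it in distance bins, enforces a monotone
#' decreasing fit (isotonic regression) and returns the interpolated
#' distance where the curve crosses `target_r2`.
#'
#' @param pop A `palm_pop` (phased haplotypes).
#' @param map The `palm_map`.
#' @param target_r2 Target level (default 0.1).
#' @param max_dist_cm Maximum pair distance considered, in centimorgans.
#' @param bin_cm Bin width in centimorgans.
#' @param max_pairs Cap on the number of sampled pairs.
#' @return Distance in centimorgans (`NA` if the curve never crosses),
#'   with attribute `curve`: data frame of bin midpoints and mean r2.
#' @export
ld_decay_distance <- function(pop, map, target_r2 = 0.1, max_dist_cm = 30,
                              bin_cm = 1, max_pairs = 50000L) {
  p <- allele_freq(pop)
  poly <- which(p > 0 & p < 1)
  if (length(poly) < 2L)
    return(structure(NA_real_, curve = data.frame(dist = numeric(0),
                                                  r2 = numeric(0))))
  h <- pop$haplo
  cum_start <- c(0, cumsum(map$chr_len))[map$chr] # genome-wide coordinate
  coord_cm <- (cum_start + map$pos) * 100
  chr <- map$chr
  # sample pairs: random anchor locus, random partner within the window
  n_target <- max_pairs
  anchors <- sample(poly, n_target, replace = TRUE)
  d <- numeric(n_target); r2 <- numeric(n_target)
  got <- 0L
  for (i in anchors) {
    win <- poly[chr[poly] == chr[i] & poly != i &
                abs(coord_cm[poly] - coord_cm[i]) <= max_dist_cm]
    if (length(win) == 0L) next
    j <- win[sample.int(length(win), 1L)]
    got <- got + 1L
    d[got] <- abs(coord_cm[j] - coord_cm[i])
    r2[got] <- ld_r2(h[, i], h[, j])
  }
  if (got == 0L)
    return(structure(NA_real_, curve = data.frame(dist = numeric(0),
                                                  r2 = numeric(0))))
  d <- d[seq_len(got)]; r2 <- r2[seq_len(got)]
  ok <- !is.na(r2)
  d <- d[ok]; r2 <- r2[ok]
  bins <- pmin(floor(d / bin_cm), ceiling(max_dist_cm / bin_cm) - 1L)
  mid <- (sort(unique(bins)) + 0.5) * bin_cm
  mr2 <- tapply(r2, bins, mean)
  # monotone decreasing fit against distance
  iso <- stats::isoreg(mid, -as.numeric(mr2))
  curve <- data.frame(dist = mid, r2 = -iso$yf)
  below <- which(curve$r2 <= target_r2)
  if (length(below) == 0L || below[1L] == 1L) {
    out <- if (length(below) > 0L) curve$dist[1L] else NA_real_
    return(structure(out, curve = curve))
  }
  k <- below[1L]
  x0 <- curve$dist[k - 1L]; x1 <- curve$dist[k]
  y0 <- curve$r2[k - 1L]; y1 <- curve$r2[k]
  xc <- if (y0 == y1) x1 else x0 + (y0 - target_r2) / (y0 - y1) * (x1 - x0)
  structure(xc, curve = curve)
}

#' Selection accuracy
#'
#' Pearson correlation between estimated and true breeding values over a
#' candidate set.
#'
#' @param ebv,tbv Numeric vectors.
#' @return Correlation, or `NA` with fewer than 3 individuals or a
#'   zero-variance input.
#' @export
selection_accuracy <- function(ebv, tbv) {
  stopifnot(length(ebv) == length(tbv))
  if (length(ebv) < 3L) return(NA_real_)
  if (sd(ebv) == 0 || sd(tbv) == 0) return(NA_real_)
  cor(ebv, tbv)
}

#' Summarize a four-cycle run
#'
#' Turns per-generation records into the study's outcome measures:
#' cumulative selection response (percent of generation-0 hybrid
#' production), annual response (cumulative divided by total years), and
#' the cumulative and annual increase in inbreeding per parental
#' population, both relative to generation-0 inbreeding (the default
#' reading) and on the absolute scale.
#'
#' @param records Data frame with one row per generation and columns
#'   `generation`, `years` (cumulative years elapsed), `production`
#'   (expected hybrid bunch production), `f_deli`, `f_lame` (mean pedigree
#'   inbreeding).
#' @return Object of class `run_summary`: the records plus `response_pct`
#'   per generation and scalars `cumulative_response_pct`,
#'   `annual_response_pct`, `total_years`, `dF_c` and `dF_y` (relative,
#'   per population) and `dF_c_abs`, `dF_y_abs`.
#' @export
summarize_run <- function(records) {
  stopifnot(all(c("generation", "years", "production", "f_deli", "f_lame")
                %in% names(records)))
  records <- records[order(records$generation), , drop = FALSE]
  if (any(diff(records$years) <= 0)) stop("years must strictly increase")
  v0 <- records$production[1L]
  records$response_pct <- 100 * (records$production - v0) / v0
  total_years <- records$years[nrow(records)] - records$years[1L]
  cum <- records$response_pct[nrow(records)]
  f0 <- c(deli = records$f_deli[1L], lame = records$f_lame[1L])
  f4 <- c(deli = records$f_deli[nrow(records)],
          lame = records$f_lame[nrow(records)])
  dF_c_abs <- 100 * (f4 - f0)
  if (any(f0 == 0)) {
    dF_c <- dF_c_abs
    rel_flag <- FALSE
  } else {
    dF_c <- 100 * (f4 - f0) / f0
    rel_flag <- TRUE
  }
  structure(list(records = records,
                 cumulative_response_pct = cum,
                 annual_response_pct = cum / total_years,
                 total_years = total_years,
                 dF_c = dF_c, dF_y = dF_c / total_years,
                 dF_c_abs = dF_c_abs, dF_y_abs = dF_c_abs / total_years,
                 dF_relative_to_initial = rel_flag),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "run_summary: %+.1f%% cumulative response over %g years (%+.3f%%/yr)\n",
    x$cumulative_response_pct, x$total_years, x$annual_response_pct))
  cat(sprintf("dF_y (rel. to initial F): Deli %.2f%%/yr, La Me %.2f%%/yr\n",
              x$dF_y["deli"], x$dF_y["lame"]))
  invisible(x)
}
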