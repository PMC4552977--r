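#' History configuration for the two breeding populations
#'
#' Encodes the stylized demographic history that turns the equilibrium
#' base population into the Deli-like and La Me-like founder populations:
#' 100 generations of divergent natural selection (bunch weight in A,
#' bunch number in B, 100 individuals each), a 4-founder bottleneck with
#' three generations of 25 then six mass-selected generations
#' (50/50/60/75/100/150, best 70 percent retained) on the Deli side, a
#' 19-founder bottleneck with two mass-selected generations (75/150, best
#' 30 percent) on the La Me side, and two cycles of phenotype-era
#' reciprocal recurrent selection (progeny-test accuracies 0.8 then 0.9,
#' top 20 selected, 80 percent half diallel) ending with 300 individuals
#' per population. Pedigree is retained for the last four generations in
#' Deli and the last two in La Me.
#'
#' @param divergence_gens,divergence_size Divergence phase length and per
#'   population size.
#' @param deli_founders,deli_random_sizes,deli_mass_sizes,deli_retain
#'   Deli bottleneck schedule and mass-selection retained fraction.
#' @param lame_founders,lame_mass_sizes,lame_retain La Me schedule.
#' @param prerrs_accuracy,prerrs_sizes,prerrs_n_selected,prerrs_diallel_fraction
#'   The two phenotype-era RRS cycles.
#' @param deli_ped_gens,lame_ped_gens Number of most recent generations
#'   whose pedigree is retained (oldest retained generation becomes the
#'   founder set of the recorded pedigree).
#' @export
history_config <- function(divergence_gens = 100L, divergence_size = 100L,
                           deli_founders = 4L,
                           deli_random_sizes = c(25L, 25L, 25L),
                           deli_mass_sizes = c(50L, 50L, 60L, 75L, 100L, 150L),
                           deli_retain = 0.70,
                           lame_founders = 19L,
                           lame_mass_sizes = c(75L, 150L),
                           lame_retain = 0.30,
                           prerrs_accuracy = c(0.8, 0.9),
                           prerrs_sizes = c(120L, 300L),
                           prerrs_n_selected = 20L,
                           prerrs_diallel_fraction = 0.8,
                           deli_ped_gens = 4L, lame_ped_gens = 2L) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[grepl("sizes|founders|gens", names(cfg))]) > 0),
            deli_retain > 0, deli_retain <= 1,
            lame_retain > 0, lame_retain <= 1,
            all(abs(prerrs_accuracy) <= 1))
  structure(cfg, class = "history_config")
}

# sample n_off matings among n parents, optionally weighted, no selfing
sample_matings <- function(n_off, n, weights = NULL, no_selfing = TRUE) {
  if (n < 2L) stop("need at least two parents")
  if (!is.null(weights)) {
    if (all(weights <= 0)) weights <- NULL else weights <- pmax(weights, 0)
  }
  t(vapply(seq_len(n_off), function(i) {
    s <- sample.int(n, 1L, prob = weights)
    repeat {
      d <- sample.int(n, 1L, prob = weights)
      if (!no_selfing || d != s) break
    }
    c(s, d)
  }, integer(2L)))
}

#' Divergent natural-selection phase
#'
#' Splits the base population into two populations that evolve
#' independently for `n_gen` generations under fitness-proportional parent
#' sampling: the probability of being drawn as a parent is proportional to
#' the (non-negative part of the) phenotype for the population's focal
#' trait, bunch weight in A and bunch number in B. Falls back to uniform
#' sampling when all phenotypes are non-positive.
#'
#' @param base_pop The equilibrium `palm_pop` (size >= twice
#'   `size`... at least 2 x 100 by default).
#' @param arch,tp QTL architecture and trait parameters.
#' @param map,params Genome map and meiosis parameters.
#' @param n_gen,size Phase length and per-population size.
#' @return List with `A` and `B` (`palm_pop`s).
#' @export
divergence_phase <- function(base_pop, arch, tp, map,
                             params = meiosis_params(),
                             n_gen = 100L, size = 100L) {
  n <- n_ind(base_pop)
  if (n < 2L * size) stop("base population too small to split")
  idx <- sample.int(n, 2L * size)
  pops <- list(A = pop_subset(base_pop, idx[seq_len(size)]),
               B = pop_subset(base_pop, idx[size + seq_len(size)]))
  pops$A$label <- "A"; pops$B$label <- "B"
  focal <- c(A = "bw", B = "bn")
  for (nm in names(pops)) {
    pop <- pops[[nm]]
    tcol <- match(focal[[nm]], c("bw", "bn"))
    for (g in seq_len(n_gen)) {
      ph <- pop_phenotypes(pop, arch, tp)[, tcol]
      w <- pmax(ph, 0)
      if (all(w == 0)) {
        message("all phenotypes non-positive; uniform parent sampling")
        w <- NULL
      }
      pairs <- sample_matings(size, n_ind(pop), weights = w)
      pop <- next_generation(pop, pairs, map, params)
    }
    pop$label <- nm
    pops[[nm]] <- pop
  }
  pops
}

#' Mass selection on bunch production
#'
#' Bunch production of each individual is the product of its bunch-number
#' and bunch-weight phenotypes; the top `retain_frac` fraction is kept
#' (ties broken at random under the session seed).
#'
#' @param pop A `palm_pop`.
#' @param retain_frac Fraction retained, in (0, 1].
#' @param pheno Optional phenotype matrix (individuals x 2, bw/bn); drawn
#'   from `arch`/`tp` when omitted.
#' @param arch,tp Needed when `pheno` is missing.
#' @return The selected `palm_pop` (attribute `index`: positions kept).
#' @export
mass_select <- function(pop, retain_frac, pheno = NULL, arch = NULL,
                        tp = NULL) {
  if (retain_frac <= 0 || retain_frac > 1) stop("retain_frac must be in (0,1]")
  n <- n_ind(pop)
  if (n == 0L) stop("empty population")
  if (is.null(pheno)) pheno <- pop_phenotypes(pop, arch, tp)
  production <- pheno[, 1L] * pheno[, 2L]
  k <- ceiling(retain_frac * n)
  keep <- order(-production, runif(n))[seq_len(k)]
  out <- pop_subset(pop, keep)
  attr(out, "index") <- keep
  out
}

#' Pseudo progeny-test estimated breeding values
#'
#' Emulates the accuracy of a phenotype-era progeny test: the returned
#' estimates correlate with the true breeding values at `target_r` and
#' have the same variance. Used for the two historical RRS cycles where
#' accuracies of 0.8 then 0.9 are assumed.
#'
#' @param tbv Numeric vector (one trait) of true breeding values.
#' @param target_r Target correlation, |r| <= 1.
#' @return Numeric vector of pseudo-EBV on the same (deviation) scale.
#' @export
pseudo_progeny_test <- function(tbv, target_r) {
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  n <- length(tbv)
  s <- sd(tbv)
  if (is.na(s) || s == 0) {
    message("zero-variance breeding values: pseudo-EBV are pure noise")
    return(rnorm(n))
  }
  z <- (tbv - mean(tbv)) / s
  (target_r * z + sqrt(1 - target_r^2) * rnorm(n)) * s
}

#' One phenotype-era reciprocal recurrent selection cycle
#'
#' Pseudo progeny tests both populations at accuracy `target_r`, selects
#' the top `n_selected` per population on expected cross production
#' against the opposite population's mean, and mates them in an 80
#' percent half diallel with selfing to produce `n_offspring` individuals
#' per population.
#'
#' @param deli,lame `palm_pop`s.
#' @param arch,tp,map,params Simulation context.
#' @param target_r Pseudo progeny-test accuracy.
#' @param n_offspring Offspring per population.
#' @param n_selected,diallel_fraction Selection and mating-design control.
#' @param id_start First offspring id.
#' @return List with the two offspring populations, the selected indices
#'   and the pedigree rows of the offspring.
#' @export
pre_rrs_cycle <- function(deli, lame, arch, tp, map,
                          params = meiosis_params(), target_r,
                          n_offspring, n_selected = 20L,
                          diallel_fraction = 0.8, id_start = 1L) {
  stopifnot(n_ind(deli) > 0L, n_ind(lame) > 0L)
  tv_d <- trait_values(deli, arch)
  tv_l <- trait_values(lame, arch)
  ebv_d <- apply(tv_d, 2L, function(x) pseudo_progeny_test(x - mean(x), target_r))
  ebv_l <- apply(tv_l, 2L, function(x) pseudo_progeny_test(x - mean(x), target_r))
  means <- (colMeans(tv_d) + colMeans(tv_l)) / 2
  sel <- select_parents(ebv_d / 2, ebv_l / 2, means, n_selected)
  out <- list(selected = sel)
  for (nm in c("deli", "lame")) {
    pop <- if (nm == "deli") deli else lame
    idx <- sel[[nm]]
    plan <- make_within_pop_matings(length(idx), diallel_fraction, n_offspring)
    off <- make_cross_offspring(pop, idx[plan$p1], idx[plan$p2],
                                plan$n_offspring, map, params,
                                id_start = id_start)
    id_start <- max(off$id) + 1L
    out[[nm]] <- off
  }
  out
}

# produce offspring for a within-population cross plan; parents given as
# positions in pop, one row per cross with its offspring count
make_cross_offspring <- function(pop, p1, p2, n_off, map, params,
                                 id_start = 1L, label = pop$label,
                                 generation = pop$generation + 1L) {
  sire <- rep(p1, n_off)
  dam <- rep(p2, n_off)
  h1 <- gametes(pop, sire, map, params)
  h2 <- gametes(pop, dam, map, params)
  n <- length(sire)
  h <- matrix(0L, 2L * n, ncol(h1))
  h[2L * seq_len(n) - 1L, ] <- h1
  h[2L * seq_len(n), ] <- h2
  palm_pop(h, id = seq.int(id_start, length.out = n),
           sire = pop$id[sire], dam = pop$id[dam],
           generation = generation, label = label)
}

pop_ped_rows <- function(pop) {
  data.frame(id = pop$id, sire = pop$sire, dam = pop$dam,
             generation = pop$generation, label = pop$label)
}

#' Build calibrated founder populations
#'
#' Runs the complete history (QTL assignment, divergence, bottlenecks,
#' mass selection, two phenotype-era RRS cycles) from a shared equilibrium
#' base population, then applies the replicate acceptance filter on the
#' resulting genetic parameters. The QTL architecture is redrawn on every
#' attempt, as the calibration is a property of the (architecture,
#' history) pair. If no attempt passes all windows the attempt with the
#' fewest violations is returned, flagged as not accepted.
#'
#' @param base_pop Equilibrium `palm_pop` from [run_burnin()].
#' @param map,params Genome context.
#' @param n_qtl,p_pleio,rho,base_var,maf_min Passed to [assign_qtl()].
#' @param h2 Base heritability for [trait_params()].
#' @param hist A `history_config`.
#' @param targets Acceptance windows from [calibration_targets()] (`NULL`
#'   disables filtering).
#' @param max_attempts Maximum number of history attempts.
#' @param ld_max_pairs Pair budget for the LD summaries (0 skips them).
#' @return Object of class `founders`: `deli`, `lame` (generation-0
#'   populations of 300), `ped` (the truncated pedigree available to the
#'   evaluation models), `ped_full` (the complete branch pedigree back to
#'   the bottleneck founders, used for inbreeding), `arch`, `tp`,
#'   `stats`, `accepted`, `attempts`.
#' @export
build_founders <- function(base_pop, map, params = meiosis_params(),
                           n_qtl = 500L, p_pleio = 0.75, rho = -0.9,
                           base_var = c(bw = 6, bn = 12), maf_min = 0.1,
                           h2 = 0.8, hist = history_config(),
                           targets = calibration_targets(n_qtl, p_pleio),
                           max_attempts = 5L, ld_max_pairs = 20000L) {
  best <- NULL
  for (attempt in seq_len(max_attempts)) {
    arch <- assign_qtl(base_pop, n_qtl, p_pleio, rho, base_var, maf_min)
    tp <- trait_params(arch, h2 = h2)
    div <- divergence_phase(base_pop, arch, tp, map, params,
                            hist$divergence_gens, hist$divergence_size)
    res <- run_history_branches(div, arch, tp, map, params, hist)
    stats <- founder_stats(res$deli, res$lame, res$ped_full, arch, tp, map,
                           ld_max_pairs = ld_max_pairs)
    acc <- if (is.null(targets)) {
      structure(TRUE, report = data.frame())
    } else {
      accept_replicate(stats, targets)
    }
    cand <- list(deli = res$deli, lame = res$lame, ped = res$ped,
                 ped_full = res$ped_full,
                 arch = arch, tp = tp, stats = stats,
                 accepted = as.logical(acc),
                 report = attr(acc, "report"), attempts = attempt)
    n_fail <- if (is.null(targets)) 0L else sum(!attr(acc, "report")$pass)
    if (is.null(best) || n_fail < attr(best, "n_fail")) {
      best <- cand
      attr(best, "n_fail") <- n_fail
    }
    if (cand$accepted) break
  }
  structure(best, class = "founders")
}

# the bottleneck + mass-selection + pre-RRS part of the history
run_history_branches <- function(div, arch, tp, map, params, hist) {
  id <- 1L
  ped <- list()
  grow <- function(pop) {
    ped[[length(ped) + 1L]] <<- pop_ped_rows(pop)
    pop
  }
  assign_ids <- function(pop) {
    n <- n_ind(pop)
    pop$id <- seq.int(id, length.out = n)
    id <<- id + n
    pop
  }
  branch <- function(base, n_founders, random_sizes, mass_sizes, retain,
                     label) {
    pop <- pop_subset(base, sample.int(n_ind(base), n_founders))
    pop$label <- label
    pop$sire <- pop$dam <- rep(NA_integer_, n_founders)
    pop <- assign_ids(pop)
    pop <- grow(pop)
    for (sz in random_sizes) {
      pairs <- sample_matings(sz, n_ind(pop))
      pop <- grow(assign_ids(next_generation(pop, pairs, map, params)))
    }
    for (sz in mass_sizes) {
      sel <- mass_select(pop, retain, arch = arch, tp = tp)
      pairs <- sample_matings(sz, n_ind(sel))
      pop <- grow(assign_ids(next_generation(sel, pairs, map, params)))
    }
    pop
  }
  deli <- branch(div$A, hist$deli_founders, hist$deli_random_sizes,
                 hist$deli_mass_sizes, hist$deli_retain, "Deli")
  lame <- branch(div$B, hist$lame_founders, integer(0),
                 hist$lame_mass_sizes, hist$lame_retain, "LaMe")
  for (k in seq_along(hist$prerrs_accuracy)) {
    cyc <- pre_rrs_cycle(deli, lame, arch, tp, map, params,
                         target_r = hist$prerrs_accuracy[k],
                         n_offspring = hist$prerrs_sizes[k],
                         n_selected = hist$prerrs_n_selected,
                         diallel_fraction = hist$prerrs_diallel_fraction,
                         id_start = id)
    deli <- grow(cyc$deli)
    lame <- grow(cyc$lame)
    id <- max(deli$id, lame$id) + 1L
  }
  ped_full <- do.call(rbind, ped)
  ped <- trim_pedigree(ped_full, deli_gens = hist$deli_ped_gens,
                       lame_gens = hist$lame_ped_gens)
  list(deli = deli, lame = lame, ped = ped, ped_full = ped_full)
}

# keep only the last n generations of each branch; the oldest retained
# generation becomes pedigree founders (parents set unknown)
trim_pedigree <- function(ped, deli_gens = 4L, lame_gens = 2L) {
  keep <- logical(nrow(ped))
  for (br in list(c("Deli", deli_gens), c("LaMe", lame_gens))) {
    lab <- br[1L]; ng <- as.integer(br[2L])
    rows <- ped$label == lab
    if (!any(rows)) next
    gens <- sort(unique(ped$generation[rows]), decreasing = TRUE)
    kept_gens <- gens[seq_len(min(ng, length(gens)))]
    keep <- keep | (rows & ped$generation %in% kept_gens)
    oldest <- min(kept_gens)
    founder_rows <- rows & ped$generation == oldest
    ped$sire[founder_rows] <- NA_integer_
    ped$dam[founder_rows] <- NA_integer_
  }
  out <- ped[keep, , drop = FALSE]
  out[order(out$generation, out$id), , drop = FALSE]
}

#' Genetic parameters of the founder populations
#'
#' Computes the quantities used by the replicate-acceptance calibration:
#' Weir-Cockerham Fst, LD-decay distances, per-population realized
#' heritabilities and additive variances, genetic correlations (from true
#' genetic values), mean pedigree inbreeding and the maximum single-QTL
#' share of additive variance.
#'
#' @param deli,lame Generation-0 `palm_pop`s.
#' @param ped Pedigree used for inbreeding; pass the complete branch
#'   pedigree so coancestry since the bottleneck founders is counted.
#' @param arch,tp Architecture and trait parameters.
#' @param map Genome map.
#' @param ld_max_pairs Pair budget for LD curves (0 skips LD).
#' @return Named list of statistics.
#' @export
founder_stats <- function(deli, lame, ped, arch, tp, map,
                          ld_max_pairs = 20000L) {
  marker_loci <- setdiff(seq_len(map$n_loci), arch$loci)
  fst <- wc_fst(pop_dosage(deli, marker_loci), pop_dosage(lame, marker_loci))
  g_d <- genetic_values(pop_dosage(deli, arch$loci), arch)
  g_l <- genetic_values(pop_dosage(lame, arch$loci), arch)
  stats <- list(fst = as.numeric(fst))
  for (nm in c("deli", "lame")) {
    pop <- if (nm == "deli") deli else lame
    g <- if (nm == "deli") g_d else g_l
    p <- allele_freq(pop, arch$loci)
    for (tr in c("bw", "bn")) {
      av <- additive_variance(p, arch, tr)
      stats[[paste0("var_", nm, "_", tr)]] <- as.numeric(av)
      stats[[paste0("h2_", nm, "_", tr)]] <-
        as.numeric(av) / (as.numeric(av) + tp$sigma_e[tr])
      stats[[paste0("max_share_", nm, "_", tr)]] <- max(attr(av, "shares"))
    }
    stats[[paste0("corr_", nm)]] <- cor(g[, 1L], g[, 2L])
    Fv <- pedigree_inbreeding(ped, pop$id)
    stats[[paste0("f_", nm)]] <- mean(Fv)
  }
  stats$max_qtl_share <- max(stats$max_share_deli_bw, stats$max_share_deli_bn,
                             stats$max_share_lame_bw, stats$max_share_lame_bn)
  if (ld_max_pairs > 0L) {
    stats$ld_deli <- as.numeric(ld_decay_distance(deli, map,
                                                  max_pairs = ld_max_pairs))
    stats$ld_lame <- as.numeric(ld_decay_distance(lame, map,
                                                  max_pairs = ld_max_pairs))
  } else {
    stats$ld_deli <- stats$ld_lame <- NA_real_
  }
  stats
}

#' Acceptance windows for founder calibration
#'
#' Windows default to the per-cell replicate means plus/minus
#' `n_sd` standard deviations (with a floor) for the matching cell of the
#' study's QTL-architecture grid, covering Fst, genetic correlations,
#' additive variances, heritabilities and inbreeding; the LD criterion is
#' the shape rule (short-range LD higher in Deli than in La Me) and the
#' single-QTL share cap is 0.20.
#'
#' @param n_qtl,p_pleio Grid cell (100/500/1000 x 0.60/0.75/0.90); other
#'   values fall back to the pooled grid mean.
#' @param n_sd Half-width in SD units (default 2).
#' @param floors Named minimum half-widths.
#' @param max_qtl_share Cap on the single-QTL variance share.
#' @return Object of class `calibration_targets`: data frame of windows
#'   plus the share cap and LD shape flag.
#' @export
calibration_targets <- function(n_qtl = 500L, p_pleio = 0.75, n_sd = 2,
                                floors = c(fst = 0.03, corr = 0.10,
                                           var = 0.50, h2 = 0.10,
                                           f = 0.03),
                                max_qtl_share = 0.20) {
  tab <- founder_reference_table()
  key <- paste(n_qtl, round(100 * p_pleio))
  cell <- tab[tab$cell == key, , drop = FALSE]
  if (nrow(cell) == 0L) {
    cell <- aggregate(cbind(mean, sd) ~ stat, data = tab, FUN = mean)
    cell$cell <- "pooled"
  }
  grp <- sub("_.*", "", cell$stat)
  fl <- floors[ifelse(grp %in% names(floors), grp, "var")]
  half <- pmax(n_sd * cell$sd, fl)
  win <- data.frame(stat = cell$stat, lo = cell$mean - half,
                    hi = cell$mean + half)
  structure(list(windows = win, max_qtl_share = max_qtl_share,
                 ld_shape = TRUE, cell = key),
            class = "calibration_targets")
}

# Replicate means and SDs of the founder genetic parameters per
# architecture cell (cells keyed "n_qtl p_pleio_percent").
founder_reference_table <- function() {
  cells <- c("100 60", "100 75", "100 90", "500 60", "500 75", "500 90",
             "1000 60", "1000 75", "1000 90")
  m <- rbind(
    fst           = c(0.49, 0.48, 0.47, 0.47, 0.47, 0.48, 0.49, 0.48, 0.47),
    corr_deli     = c(-0.69, -0.75, -0.90, -0.64, -0.79, -0.83, -0.64, -0.75, -0.84),
    corr_lame     = c(-0.73, -0.73, -0.86, -0.68, -0.73, -0.86, -0.66, -0.71, -0.81),
    var_deli_bn   = c(1.55, 1.86, 1.78, 1.94, 1.99, 2.03, 1.94, 1.99, 1.97),
    var_deli_bw   = c(0.76, 0.98, 0.87, 0.91, 0.94, 1.00, 0.96, 0.99, 0.93),
    var_lame_bn   = c(2.00, 1.82, 2.12, 2.27, 2.27, 2.27, 2.20, 2.11, 2.36),
    var_lame_bw   = c(1.16, 1.04, 1.06, 1.21, 1.11, 1.15, 1.14, 1.08, 1.16),
    h2_lame_bn    = c(0.63, 0.64, 0.64, 0.67, 0.67, 0.66, 0.66, 0.66, 0.68),
    h2_lame_bw    = c(0.65, 0.65, 0.63, 0.68, 0.67, 0.67, 0.67, 0.67, 0.69),
    h2_deli_bn    = c(0.57, 0.63, 0.60, 0.63, 0.63, 0.64, 0.64, 0.65, 0.64),
    h2_deli_bw    = c(0.54, 0.63, 0.58, 0.61, 0.63, 0.64, 0.63, 0.65, 0.64),
    f_deli        = c(0.26, 0.26, 0.25, 0.26, 0.26, 0.25, 0.26, 0.25, 0.26),
    f_lame        = c(0.14, 0.13, 0.13, 0.13, 0.14, 0.13, 0.14, 0.14, 0.13))
  s <- rbind(
    fst           = c(0.01, 0.03, 0.02, 0.03, 0.01, 0.02, 0.02, 0.01, 0.03),
    corr_deli     = c(0.07, 0.07, 0.02, 0.05, 0.05, 0.03, 0.08, 0.07, 0.04),
    corr_lame     = c(0.04, 0.10, 0.03, 0.03, 0.03, 0.04, 0.01, 0.05, 0.03),
    var_deli_bn   = c(0.22, 0.63, 0.24, 0.13, 0.14, 0.42, 0.10, 0.13, 0.18),
    var_deli_bw   = c(0.15, 0.38, 0.15, 0.16, 0.08, 0.21, 0.05, 0.06, 0.05),
    var_lame_bn   = c(0.37, 0.28, 0.50, 0.14, 0.09, 0.30, 0.06, 0.19, 0.15),
    var_lame_bw   = c(0.20, 0.22, 0.20, 0.03, 0.07, 0.13, 0.08, 0.10, 0.06),
    h2_lame_bn    = c(0.06, 0.04, 0.07, 0.02, 0.01, 0.02, 0.01, 0.02, 0.01),
    h2_lame_bw    = c(0.02, 0.04, 0.03, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    h2_deli_bn    = c(0.03, 0.07, 0.04, 0.01, 0.01, 0.03, 0.02, 0.02, 0.02),
    h2_deli_bw    = c(0.04, 0.06, 0.05, 0.03, 0.02, 0.04, 0.02, 0.02, 0.01),
    f_deli        = c(0.00, 0.00, 0.01, 0.01, 0.01, 0.00, 0.00, 0.01, 0.01),
    f_lame        = c(0.01, 0.01, 0.00, 0.01, 0.01, 0.00, 0.00, 0.01, 0.01))
  long <- expand.grid(stat = rownames(m), cell = cells,
                      stringsAsFactors = FALSE)
  long$mean <- as.vector(m)
  long$sd <- as.vector(s)
  long
}

#' Accept or reject a founder replicate
#'
#' @param stats Output of [founder_stats()].
#' @param targets A `calibration_targets`.
#' @return Logical scalar with attribute `report`: per-criterion data
#'   frame (criterion, value, lo, hi, pass).
#' @export
accept_replicate <- function(stats, targets) {
  win <- targets$windows
  rep_rows <- list()
  for (k in seq_len(nrow(win))) {
    v <- stats[[win$stat[k]]]
    if (is.null(v)) next
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(criterion = win$stat[k], value = v, lo = win$lo[k],
                 hi = win$hi[k],
                 pass = !is.na(v) && v >= win$lo[k] && v <= win$hi[k])
  }
  rep_rows[[length(rep_rows) + 1L]] <-
    data.frame(criterion = "max_qtl_share", value = stats$max_qtl_share,
               lo = 0, hi = targets$max_qtl_share,
               pass = stats$max_qtl_share <= targets$max_qtl_share)
  if (isTRUE(targets$ld_shape) && !is.na(stats$ld_deli) &&
      !is.na(stats$ld_lame)) {
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(criterion = "ld_shape_deli_gt_lame",
                 value = stats$ld_deli - stats$ld_lame, lo = 0, hi = Inf,
                 pass = stats$ld_deli > stats$ld_lame)
  }
  report <- do.call(rbind, rep_rows)
  structure(all(report$pass), report = report)
}

#' @export
print.founders <- function(x, ...) {
  cat(sprintf("founders: Deli n=%d, La Me n=%d, %s after %d attempt(s)\n",
              n_ind(x$deli), n_ind(x$lame),
              if (x$accepted) "accepted" else "NOT accepted", x$attempts))
  cat(sprintf("Fst %.3f | F Deli %.3f, La Me %.3f | corr Deli %.2f, La Me %.2f\n",
              x$stats$fst, x$stats$f_deli, x$stats$f_lame,
              x$stats$corr_deli, x$stats$corr_lame))
  invisible(x)
}
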