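#' Configuration of a four-cycle breeding scheme
#'
#' Defines one strategy-by-design cell of the comparison between
#' phenotypic reciprocal recurrent selection (`RRS`) and its two genomic
#' counterparts: `RRGS_PAR`, which calibrates a genomic model on the
#' progeny-tested parents only, and `RRGS_HYB`, which adds genotyped
#' hybrids through a single-step combined relationship matrix. The
#' `pattern` string gives, per cycle, whether candidates are
#' progeny-tested (`G`, 20 years per cycle) or selected on marker data
#' alone with the last calibration (`M`, 6 years). `RRS` is constrained
#' to `GGGG` with 120 candidates and no genotyped hybrids.
#'
#' @param strategy `"RRS"`, `"RRGS_PAR"` or `"RRGS_HYB"`.
#' @param pattern Cycle pattern, e.g. `"GGGG"`, `"GMGM"`, `"GMMM"`; must
#'   start with `G`.
#' @param n_candidates Candidates per population and generation (120 or
#'   300 in the study).
#' @param n_genotyped_hybrids Genotyped hybrids per calibration for
#'   `RRGS_HYB` (study grid: 300, 1000, 1700; 0 otherwise).
#' @param n_pt_crosses,n_per_cross Progeny-test factorial size (300
#'   incomplete-factorial crosses of 45 individuals = 13,500 records).
#' @param n_pt_parents Parents per population entering the progeny test
#'   (120; a random subset when there are more candidates).
#' @param n_selected Parents selected per population (20).
#' @param diallel_fraction Fraction of the half diallel with selfing that
#'   is realized within each population (0.8).
#' @param n_panel,panel_maf SNP panel size and minimum MAF (2500, 0.04).
#' @param years_g,years_m Cycle lengths in years (20 and 6).
#' @param n_cycles Number of selection cycles (4).
#' @param .allow_custom Skip the study-grid checks (sizes must still be
#'   positive).
#' @return Object of class `scheme_config`.
#' @export
scheme_config <- function(strategy = c("RRS", "RRGS_PAR", "RRGS_HYB"),
                          pattern = "GGGG", n_candidates = 120L,
                          n_genotyped_hybrids = 0L,
                          n_pt_crosses = 300L, n_per_cross = 45L,
                          n_pt_parents = 120L, n_selected = 20L,
                          diallel_fraction = 0.8,
                          n_panel = 2500L, panel_maf = 0.04,
                          years_g = 20, years_m = 6, n_cycles = 4L,
                          .allow_custom = FALSE) {
  strategy <- match.arg(strategy)
  steps <- strsplit(pattern, "")[[1L]]
  if (length(steps) != n_cycles || !all(steps %in% c("G", "M")))
    stop("pattern must be ", n_cycles, " characters of G/M")
  if (steps[1L] != "G")
    stop("the first cycle must be a calibration cycle (G)")
  stopifnot(n_candidates > 0, n_pt_crosses > 0, n_per_cross > 0,
            n_pt_parents > 1, n_selected > 1,
            diallel_fraction > 0, diallel_fraction <= 1,
            n_panel > 0, panel_maf >= 0, panel_maf < 0.5,
            n_genotyped_hybrids >= 0)
  if (!.allow_custom) {
    if (strategy == "RRS" &&
        (pattern != strrep("G", n_cycles) || n_candidates != 120L ||
         n_genotyped_hybrids != 0L))
      stop("RRS is progeny-test only: pattern GGGG, 120 candidates, ",
           "no genotyped hybrids")
    if (strategy == "RRGS_HYB" && n_genotyped_hybrids == 0L)
      stop("RRGS_HYB needs genotyped hybrids")
    if (strategy != "RRGS_HYB" && n_genotyped_hybrids != 0L)
      stop("genotyped hybrids are only used by RRGS_HYB")
    if (!n_candidates %in% c(120L, 300L))
      stop("the study uses 120 or 300 candidates")
  }
  if (n_genotyped_hybrids > n_pt_crosses * n_per_cross)
    stop("cannot genotype more hybrids than are produced")
  structure(list(strategy = strategy, pattern = pattern, steps = steps,
                 n_candidates = as.integer(n_candidates),
                 n_genotyped_hybrids = as.integer(n_genotyped_hybrids),
                 n_pt_crosses = as.integer(n_pt_crosses),
                 n_per_cross = as.integer(n_per_cross),
                 n_pt_parents = as.integer(n_pt_parents),
                 n_selected = as.integer(n_selected),
                 diallel_fraction = diallel_fraction,
                 n_panel = as.integer(n_panel), panel_maf = panel_maf,
                 years_g = years_g, years_m = years_m,
                 n_cycles = as.integer(n_cycles)),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  yrs <- sum(ifelse(x$steps == "G", x$years_g, x$years_m))
  cat(sprintf("scheme_config: %s %s (%g years), %d candidates, %d genotyped hybrids\n",
              x$strategy, x$pattern, yrs, x$n_candidates,
              x$n_genotyped_hybrids))
  invisible(x)
}

#' Balanced incomplete-factorial progeny-test design
#'
#' Allocates `n_crosses` Deli x La Me crosses so that within each
#' population every parent appears in either `floor` or `ceiling` of
#' `n_crosses / n_parents` crosses (2 or 3 when 300 crosses are spread
#' over 120 parents), with no duplicated parent pair when avoidable.
#'
#' @param n_deli,n_lame Number of parents per population.
#' @param n_crosses Number of crosses.
#' @return Data frame with columns `deli` and `lame` (parent indices).
#' @export
design_progeny_test <- function(n_deli, n_lame, n_crosses) {
  slots <- function(n) {
    base <- n_crosses %/% n
    extra <- n_crosses %% n
    cnt <- rep(base, n)
    if (extra > 0L) cnt[sample.int(n, extra)] <- base + 1L
    sample(rep.int(seq_len(n), cnt))
  }
  d <- slots(n_deli)
  l <- slots(n_lame)
  for (k in seq_len(100L)) {
    dup <- which(duplicated(cbind(d, l)))
    if (length(dup) == 0L) break
    swap <- sample.int(n_crosses, length(dup))
    tmp <- l[dup]; l[dup] <- l[swap]; l[swap] <- tmp
  }
  if (anyDuplicated(cbind(d, l)))
    message("progeny-test design retains duplicated parent pairs")
  data.frame(deli = d, lame = l)
}

#' Within-population mating plan (partial half diallel with selfing)
#'
#' Draws `fraction` of the `n (n + 1) / 2` half-diallel-with-selfing
#' crosses among the selected parents, keeping parent participation as
#' even as possible (a selfing counts as two participations), and spreads
#' `n_offspring` over the chosen crosses so that per-cross sizes differ
#' by at most one.
#'
#' @param n Number of selected parents.
#' @param fraction Fraction of the half diallel realized.
#' @param n_offspring Total offspring.
#' @return Data frame with columns `p1`, `p2` (parent indices, `p1 <=
#'   p2`) and `n_offspring`; crosses allotted zero offspring are dropped.
#' @export
make_within_pop_matings <- function(n, fraction, n_offspring) {
  stopifnot(n >= 2L, fraction > 0, fraction <= 1, n_offspring >= 1L)
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  total <- nrow(pairs)
  n_cross <- max(1L, round(fraction * total))
  part <- integer(n)
  cap <- ceiling(2 * n_cross / n)
  chosen <- logical(total)
  n_found <- 0L
  while (n_found < n_cross) {
    for (k in seq_len(total)) {
      if (chosen[k]) next
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      add <- if (i == j) c(i = 2L) else c(i = 1L, j = 1L)
      if (part[i] + (if (i == j) 2L else 1L) > cap) next
      if (i != j && part[j] + 1L > cap) next
      chosen[k] <- TRUE
      part[i] <- part[i] + if (i == j) 2L else 1L
      if (i != j) part[j] <- part[j] + 1L
      n_found <- n_found + 1L
      if (n_found == n_cross) break
    }
    cap <- cap + 1L   # relax if the greedy pass could not fill the plan
  }
  sel <- pairs[chosen, , drop = FALSE]
  m <- nrow(sel)
  base <- n_offspring %/% m
  extra <- n_offspring %% m
  n_off <- rep(base, m)
  if (extra > 0L) {
    add <- sample.int(m, extra)
    n_off[add] <- n_off[add] + 1L
  }
  out <- data.frame(p1 = pmin(sel[, 1L], sel[, 2L]),
                    p2 = pmax(sel[, 1L], sel[, 2L]),
                    n_offspring = n_off)
  out[out$n_offspring > 0L, , drop = FALSE]
}

#' Select parents on predicted hybrid production
#'
#' Ranks each candidate by the expected bunch production of its cross
#' with the opposite population's mean general combining ability
#' ([predict_cross_value()]) and keeps the top `n_selected` per
#' population, breaking ties at random.
#'
#' @param gca_deli,gca_lame Matrices candidates x 2 (bw, bn) of estimated
#'   GCA.
#' @param means Per-trait hybrid means `c(bw=, bn=)` added before taking
#'   the product.
#' @param n_selected Parents kept per population.
#' @param eligible_deli,eligible_lame Optional index vectors restricting
#'   the candidates that may be selected (e.g. the progeny-tested subset).
#' @return List with `deli` and `lame` (selected candidate indices).
#' @export
select_parents <- function(gca_deli, gca_lame, means, n_selected,
                           eligible_deli = NULL, eligible_lame = NULL) {
  pick <- function(gca, opp_mean, eligible) {
    if (is.null(eligible)) eligible <- seq_len(nrow(gca))
    if (length(eligible) < n_selected)
      stop("fewer eligible candidates than parents to select")
    score <- predict_cross_value(gca[eligible, , drop = FALSE],
                                 matrix(opp_mean, length(eligible), 2L,
                                        byrow = TRUE),
                                 means)
    eligible[order(-score, runif(length(eligible)))[seq_len(n_selected)]]
  }
  list(deli = pick(gca_deli, colMeans(gca_lame), eligible_deli),
       lame = pick(gca_lame, colMeans(gca_deli), eligible_lame))
}

#' Sample a SNP marker panel
#'
#' Draws `n_panel` loci among those with minor allele frequency above
#' `maf_min` in the supplied genotypes, excluding the QTL; if fewer are
#' eligible, all of them are used.
#'
#' @param dosage Dosage matrix (individuals x all loci) of the genotyped
#'   set, typically both candidate populations combined.
#' @param n_panel Panel size (2500 in the study).
#' @param maf_min Minimum minor allele frequency (0.04).
#' @param exclude Locus indices never eligible (the QTL).
#' @return Sorted integer vector of locus indices.
#' @export
select_snp_panel <- function(dosage, n_panel = 2500L, maf_min = 0.04,
                             exclude = integer(0)) {
  p <- colMeans(dosage) / 2
  eligible <- setdiff(which(pmin(p, 1 - p) > maf_min), exclude)
  if (length(eligible) == 0L) stop("no locus passes the MAF threshold")
  if (length(eligible) < n_panel) {
    message(sprintf("only %d eligible loci for a panel of %d; using all",
                    length(eligible), n_panel))
    return(sort(eligible))
  }
  sort(sample(eligible, n_panel))
}

#' Expected hybrid bunch production of a population pair
#'
#' For each Deli x La Me pair the expected hybrid value per trait is the
#' parental mean; bunch production is the product of the two traits. With
#' `pairs = NULL` the mean over the complete factorial of the supplied
#' candidates is returned, which is the deterministic value the study
#' tracks across generations.
#'
#' @param tv_deli,tv_lame Matrices candidates x 2 (bw, bn) of true
#'   genotypic values on the observed scale ([trait_values()]).
#' @param pairs Optional data frame with `deli` and `lame` indices; the
#'   mean is then taken over those pairs only.
#' @return Mean expected production (scalar).
#' @export
measure_hybrid_production <- function(tv_deli, tv_lame, pairs = NULL) {
  stopifnot(ncol(tv_deli) == 2L, ncol(tv_lame) == 2L)
  if (is.null(pairs)) {
    bw <- outer(tv_deli[, 1L], tv_lame[, 1L], function(a, b) (a + b) / 2)
    bn <- outer(tv_deli[, 2L], tv_lame[, 2L], function(a, b) (a + b) / 2)
    return(mean(bw * bn))
  }
  bw <- (tv_deli[pairs$deli, 1L] + tv_lame[pairs$lame, 1L]) / 2
  bn <- (tv_deli[pairs$deli, 2L] + tv_lame[pairs$lame, 2L]) / 2
  mean(bw * bn)
}

#' Simulate a hybrid progeny test
#'
#' Produces the hybrid individuals of an incomplete factorial between the
#' progeny-tested parents of the two populations, with phenotypes for
#' both traits. To bound memory, hybrid genotypes are retained only at
#' the QTL and the marker panel; each hybrid's two gametes are kept
#' separately so its allelic origins are known.
#'
#' @param deli,lame Candidate `palm_pop`s.
#' @param pt_deli,pt_lame Positions of the progeny-tested parents.
#' @param plan Design from [design_progeny_test()] (indices into
#'   `pt_deli` / `pt_lame`).
#' @param n_per_cross Hybrids per cross.
#' @param arch,tp Trait architecture and parameters.
#' @param map,params Genome context.
#' @param panel Marker panel (locus indices) or `NULL`.
#' @param n_genotyped Number of hybrids to genotype, spread as evenly as
#'   possible over crosses.
#' @return List: `records` (data frame `deli`, `lame` candidate
#'   positions, `y_bw`, `y_bn`), `g` (hybrids x 2 genetic values on the
#'   observed scale), `within_cross_var` (per-trait mean within-cross
#'   genetic variance), `genotyped` (`idx`, plus `deli_gam` / `lame_gam`
#'   0/1 matrices at `panel`), `sire_pos` / `dam_pos` (candidate
#'   positions per hybrid), `cross` (cross index per hybrid).
#' @export
simulate_progeny_test <- function(deli, lame, pt_deli, pt_lame, plan,
                                  n_per_cross, arch, tp, map,
                                  params = meiosis_params(),
                                  panel = NULL, n_genotyped = 0L) {
  n_cross <- nrow(plan)
  keep <- sort(unique(c(arch$loci, panel)))
  qtl_cols <- match(arch$loci, keep)
  panel_cols <- if (is.null(panel)) integer(0) else match(panel, keep)
  sire_pos <- rep(pt_deli[plan$deli], each = n_per_cross)
  dam_pos <- rep(pt_lame[plan$lame], each = n_per_cross)
  cross <- rep(seq_len(n_cross), each = n_per_cross)
  gd <- gametes(deli, sire_pos, map, params, keep = keep)
  gl <- gametes(lame, dam_pos, map, params, keep = keep)
  g <- genetic_values(gd[, qtl_cols, drop = FALSE] +
                        gl[, qtl_cols, drop = FALSE], arch)
  g_obs <- sweep(g, 2L, arch$offset, "+")
  n <- nrow(g_obs)
  y <- g_obs + cbind(rnorm(n, 0, sqrt(tp$sigma_e["bw"])),
                     rnorm(n, 0, sqrt(tp$sigma_e["bn"])))
  wcv <- c(bw = mean(tapply(g_obs[, 1L], cross, var)),
           bn = mean(tapply(g_obs[, 2L], cross, var)))
  genotyped <- NULL
  if (n_genotyped > 0L) {
    base <- n_genotyped %/% n_cross
    extra <- n_genotyped %% n_cross
    per <- rep(base, n_cross)
    if (extra > 0L) per[sample.int(n_cross, extra)] <- base + 1L
    per <- pmin(per, n_per_cross)
    idx <- unlist(lapply(seq_len(n_cross), function(k) {
      if (per[k] == 0L) return(integer(0))
      (k - 1L) * n_per_cross + sample.int(n_per_cross, per[k])
    }))
    genotyped <- list(idx = idx,
                      deli_gam = gd[idx, panel_cols, drop = FALSE],
                      lame_gam = gl[idx, panel_cols, drop = FALSE])
  }
  list(records = data.frame(deli = sire_pos, lame = dam_pos,
                            y_bw = y[, 1L], y_bn = y[, 2L]),
       g = g_obs, within_cross_var = wcv, genotyped = genotyped,
       sire_pos = sire_pos, dam_pos = dam_pos, cross = cross)
}

#' Run one four-cycle breeding scheme
#'
#' Executes the configured strategy from the calibrated founder
#' populations: in `G` cycles candidates are progeny-tested on 13,500
#' hybrid records, the strategy's evaluation model is (re)calibrated and
#' 20 parents per population are selected on predicted hybrid production;
#' in `M` cycles new candidates are genotyped and predicted with the last
#' calibration before selection. Selected parents are mated in the 80
#' percent half diallel with selfing to produce the next candidate
#' generation. Per generation the run records expected hybrid production
#' over the complete candidate factorial (true genotypic values),
#' selection accuracies, additive variances and correlations, and mean
#' pedigree inbreeding.
#'
#' @param founders A `founders` object ([build_founders()]).
#' @param config A `scheme_config`.
#' @param map,params Genome context.
#' @param verbose Print one line per cycle.
#' @return Object of class `scheme_run`: `records` (per-generation data
#'   frame), `summary` ([summarize_run()]), `accuracy` (long data frame),
#'   `config`.
#' @export
run_scheme <- function(founders, config, map, params = meiosis_params(),
                       verbose = FALSE) {
  stopifnot(inherits(founders, "founders"), inherits(config, "scheme_config"))
  arch <- founders$arch; tp <- founders$tp
  deli <- founders$deli; lame <- founders$lame
  ped <- founders$ped[, c("id", "sire", "dam")]
  # inbreeding is tracked on the complete branch pedigree; the truncated
  # pedigree is what the evaluation models are allowed to use
  ped_full <- founders$ped_full[, c("id", "sire", "dam")]
  next_id <- max(ped$id, ped_full$id) + 1L
  calib <- NULL
  years <- 0
  gen_rows <- list()
  acc_rows <- list()
  record_generation <- function(g) {
    tv_d <- trait_values(deli, arch)
    tv_l <- trait_values(lame, arch)
    vd <- additive_covmat(allele_freq(deli, arch$loci), arch)
    vl <- additive_covmat(allele_freq(lame, arch$loci), arch)
    gen_rows[[length(gen_rows) + 1L]] <<- data.frame(
      generation = g, years = years,
      production = measure_hybrid_production(tv_d, tv_l),
      f_deli = mean(pedigree_inbreeding(ped_full, deli$id)),
      f_lame = mean(pedigree_inbreeding(ped_full, lame$id)),
      var_deli_bw = vd["bw", "bw"], var_deli_bn = vd["bn", "bn"],
      var_lame_bw = vl["bw", "bw"], var_lame_bn = vl["bn", "bn"],
      corr_deli = safe_corr(vd), corr_lame = safe_corr(vl))
  }
  record_accuracy <- function(g, step, pop_name, idx, est, truth) {
    for (t in 1:2)
      acc_rows[[length(acc_rows) + 1L]] <<- data.frame(
        generation = g, step = step, pop = pop_name,
        trait = c("bw", "bn")[t], n = length(idx),
        accuracy = selection_accuracy(est[, t], truth[idx, t]))
  }
  for (g in seq_len(config$n_cycles) - 1L) {
    step <- config$steps[g + 1L]
    record_generation(g)
    g_d <- genetic_values(pop_dosage(deli, arch$loci), arch)
    g_l <- genetic_values(pop_dosage(lame, arch$loci), arch)
    if (step == "G") {
      ev <- calibrate_cycle(deli, lame, ped, arch, tp, map, params, config,
                            next_id)
      calib <- ev$calib
      ped <- ev$ped
      next_id <- ev$next_id
      record_accuracy(g, "G", "deli", ev$eval_deli, ev$gca_deli, g_d)
      record_accuracy(g, "G", "lame", ev$eval_lame, ev$gca_lame, g_l)
      sel <- select_parents(ev$gca_deli, ev$gca_lame, calib$mu,
                            config$n_selected)
      sel <- list(deli = ev$eval_deli[sel$deli], lame = ev$eval_lame[sel$lame])
      years <- years + config$years_g
    } else {
      pr <- predict_new_candidates(calib, deli, lame, ped, arch, config)
      calib <- pr$calib
      record_accuracy(g, "M", "deli", seq_len(n_ind(deli)), pr$gca_deli, g_d)
      record_accuracy(g, "M", "lame", seq_len(n_ind(lame)), pr$gca_lame, g_l)
      sel <- select_parents(pr$gca_deli, pr$gca_lame, calib$mu,
                            config$n_selected)
      years <- years + config$years_m
    }
    for (nm in c("deli", "lame")) {
      pop <- if (nm == "deli") deli else lame
      plan <- make_within_pop_matings(length(sel[[nm]]),
                                      config$diallel_fraction,
                                      config$n_candidates)
      off <- make_cross_offspring(pop, sel[[nm]][plan$p1],
                                  sel[[nm]][plan$p2], plan$n_offspring,
                                  map, params, id_start = next_id)
      next_id <- max(off$id) + 1L
      new_rows <- data.frame(id = off$id, sire = off$sire, dam = off$dam)
      ped <- rbind(ped, new_rows)
      ped_full <- rbind(ped_full, new_rows)
      if (nm == "deli") deli <- off else lame <- off
    }
    if (verbose)
      message(sprintf("cycle %d (%s) done: %g years elapsed", g + 1L, step,
                      years))
  }
  record_generation(config$n_cycles)
  records <- do.call(rbind, gen_rows)
  structure(list(records = records, summary = summarize_run(records),
                 accuracy = do.call(rbind, acc_rows), config = config,
                 deli = deli, lame = lame, ped = ped,
                 ped_full = ped_full),
            class = "scheme_run")
}

#' @export
print.scheme_run <- function(x, ...) {
  cat(sprintf("scheme_run: %s %s\n", x$config$strategy, x$config$pattern))
  print(x$summary)
  invisible(x)
}

# keep a realized additive covariance matrix usable as a model variance:
# variances are floored at a small fraction of the residual scale and the
# matrix is nudged to positive definite, so populations whose variance for
# one trait has (nearly) fixed still yield solvable mixed-model equations
regularize_covmat <- function(S, ref_scale, frac = 1e-4) {
  floor_v <- frac * max(ref_scale, 1e-12)
  for (t in 1:2) S[t, t] <- max(S[t, t], floor_v)
  r <- S[1L, 2L] / sqrt(S[1L, 1L] * S[2L, 2L])
  if (!is.finite(r)) r <- 0
  r <- max(min(r, 0.999), -0.999)
  S[1L, 2L] <- S[2L, 1L] <- r * sqrt(S[1L, 1L] * S[2L, 2L])
  S
}

# a centered genomic relationship matrix is singular by construction
# (the all-ones vector lies in its null space); blending a small identity
# share in keeps the GCA kernel invertible without changing the ranking
blend_kernel <- function(K, weight = 0.01) {
  (1 - weight) * K + diag(weight * mean(diag(K)), nrow(K))
}

# correlation from a 2x2 covariance matrix, NA when a variance is zero
safe_corr <- function(S) {
  if (S[1L, 1L] <= 0 || S[2L, 2L] <= 0) return(NA_real_)
  S[1L, 2L] / sqrt(S[1L, 1L] * S[2L, 2L])
}

# One calibration (G) cycle: progeny test + model fit for the strategy.
# Returns the candidate GCA estimates (rows = evaluated candidates), the
# evaluated candidate positions, the updated pedigree/id counter and the
# stored calibration for later marker-only cycles.
calibrate_cycle <- function(deli, lame, ped, arch, tp, map, params, config,
                            next_id) {
  n_d <- n_ind(deli); n_l <- n_ind(lame)
  pt_d <- sort(sample.int(n_d, min(config$n_pt_parents, n_d)))
  pt_l <- sort(sample.int(n_l, min(config$n_pt_parents, n_l)))
  plan <- design_progeny_test(length(pt_d), length(pt_l),
                              config$n_pt_crosses)
  genomic <- config$strategy != "RRS"
  panel <- NULL
  if (genomic) {
    panel <- select_snp_panel(rbind(pop_dosage(deli), pop_dosage(lame)),
                              config$n_panel, config$panel_maf,
                              exclude = arch$loci)
  }
  pt <- simulate_progeny_test(deli, lame, pt_d, pt_l, plan,
                              config$n_per_cross, arch, tp, map, params,
                              panel = panel,
                              n_genotyped = config$n_genotyped_hybrids)
  covD <- regularize_covmat(additive_covmat(allele_freq(deli, arch$loci),
                                            arch), mean(tp$sigma_e))
  covL <- regularize_covmat(additive_covmat(allele_freq(lame, arch$loci),
                                            arch), mean(tp$sigma_e))
  if (config$strategy == "RRS") {
    K_d <- 0.5 * pedigree_A_subset(ped, deli$id)
    K_l <- 0.5 * pedigree_A_subset(ped, lame$id)
    vc <- varcomps(list(deli = 0.5 * covD, lame = 0.5 * covL),
                   resid = tp$sigma_e + pt$within_cross_var)
    fit <- solve_gca_bivariate(pt$records, K_d, K_l, vc)
    calib <- list(strategy = "RRS", mu = fit$mu, vc = vc)
    return(list(gca_deli = fit$gca$deli[pt_d, , drop = FALSE],
                gca_lame = fit$gca$lame[pt_l, , drop = FALSE],
                eval_deli = pt_d, eval_lame = pt_l, calib = calib,
                ped = ped, next_id = next_id))
  }
  dos_d <- pop_dosage(deli, panel)
  dos_l <- pop_dosage(lame, panel)
  if (config$strategy == "RRGS_PAR") {
    vc <- varcomps(list(deli = 0.25 * covD, lame = 0.25 * covL),
                   resid = tp$sigma_e + pt$within_cross_var)
    fit <- solve_gca_bivariate(pt$records, blend_kernel(vanraden_G(dos_d)),
                               blend_kernel(vanraden_G(dos_l)), vc)
    calib <- list(strategy = "RRGS_PAR", mu = fit$mu, vc = vc,
                  panel = panel, records = pt$records,
                  dosage_deli = dos_d, dosage_lame = dos_l)
    return(list(gca_deli = fit$gca$deli, gca_lame = fit$gca$lame,
                eval_deli = seq_len(n_d), eval_lame = seq_len(n_l),
                calib = calib, ped = ped, next_id = next_id))
  }
  # RRGS_HYB: single-step model over the full pedigree with an
  # origin-aware G on candidates plus genotyped hybrids
  n_hyb <- nrow(pt$records)
  hyb_ids <- seq.int(next_id, length.out = n_hyb)
  ped <- rbind(ped, data.frame(id = hyb_ids,
                               sire = deli$id[pt$sire_pos],
                               dam = lame$id[pt$dam_pos]))
  next_id <- next_id + n_hyb
  gt <- pt$genotyped
  calib <- list(strategy = "RRGS_HYB", panel = panel,
                deli_ids = deli$id, lame_ids = lame$id,
                dosage_deli = dos_d, dosage_lame = dos_l,
                hyb_ids = hyb_ids[gt$idx],
                hyb_deli_gam = gt$deli_gam, hyb_lame_gam = gt$lame_gam,
                records = data.frame(id = hyb_ids,
                                     y_bw = pt$records$y_bw,
                                     y_bn = pt$records$y_bn),
                vc = varcomps(list(a = (covD + covL) / 2),
                              resid = tp$sigma_e))
  fit <- fit_single_step(calib, ped)
  calib$mu <- fit$mu
  pos_d <- match(deli$id, fit$order)
  pos_l <- match(lame$id, fit$order)
  list(gca_deli = 0.5 * fit$a[pos_d, , drop = FALSE],
       gca_lame = 0.5 * fit$a[pos_l, , drop = FALSE],
       eval_deli = seq_len(n_d), eval_lame = seq_len(n_l),
       calib = calib, ped = ped, next_id = next_id)
}

# Fit the single-step model for the current calibration state; ped must
# contain every id referenced by the calibration and the candidates.
fit_single_step <- function(calib, ped) {
  gen_ids <- c(calib$deli_ids, calib$lame_ids, calib$hyb_ids)
  G <- origin_aware_G(calib$dosage_deli, calib$dosage_lame,
                      calib$hyb_deli_gam, calib$hyb_lame_gam)
  A22 <- pedigree_A_subset(ped, gen_ids)
  pos <- match(gen_ids, ped$id)
  if (anyNA(pos)) stop("genotyped ids missing from pedigree")
  Hinv <- h_inverse(a_inverse(ped), A22, G, pos)
  rec <- data.frame(ind = match(calib$records$id, ped$id),
                    y_bw = calib$records$y_bw, y_bn = calib$records$y_bn)
  fit <- solve_ssgblup_bivariate(rec, Hinv, calib$vc)
  list(mu = fit$mu, a = fit$a, order = ped$id)
}

# Marker-only (M) cycle prediction for the new candidate generations,
# extending the stored calibration with the new genotypes.
predict_new_candidates <- function(calib, deli, lame, ped, arch, config) {
  if (is.null(calib)) stop("no calibration available for a marker cycle")
  dos_d <- pop_dosage(deli, calib$panel)
  dos_l <- pop_dosage(lame, calib$panel)
  if (calib$strategy == "RRGS_PAR") {
    n0_d <- nrow(calib$dosage_deli); n0_l <- nrow(calib$dosage_lame)
    K_d <- blend_kernel(vanraden_G(rbind(calib$dosage_deli, dos_d)))
    K_l <- blend_kernel(vanraden_G(rbind(calib$dosage_lame, dos_l)))
    fit <- solve_gca_bivariate(calib$records, K_d, K_l, calib$vc)
    calib$dosage_deli <- rbind(calib$dosage_deli, dos_d)
    calib$dosage_lame <- rbind(calib$dosage_lame, dos_l)
    return(list(gca_deli = fit$gca$deli[n0_d + seq_len(n_ind(deli)), ,
                                        drop = FALSE],
                gca_lame = fit$gca$lame[n0_l + seq_len(n_ind(lame)), ,
                                        drop = FALSE],
                calib = calib))
  }
  if (calib$strategy != "RRGS_HYB")
    stop("strategy ", calib$strategy, " has no marker-only cycles")
  calib$deli_ids <- c(calib$deli_ids, deli$id)
  calib$lame_ids <- c(calib$lame_ids, lame$id)
  calib$dosage_deli <- rbind(calib$dosage_deli, dos_d)
  calib$dosage_lame <- rbind(calib$dosage_lame, dos_l)
  fit <- fit_single_step(calib, ped)
  pos_d <- match(deli$id, fit$order)
  pos_l <- match(lame$id, fit$order)
  list(gca_deli = 0.5 * fit$a[pos_d, , drop = FALSE],
       gca_lame = 0.5 * fit$a[pos_l, , drop = FALSE],
       calib = calib)
}
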