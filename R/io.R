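#' Default study configuration
#'
#' Nested list of every parameter of the simulation study with its
#' default value: genome and burn-in, QTL-architecture grid cell, history
#' schedule, scheme design and run control. [load_config()] merges a YAML
#' file over these defaults.
#'
#' @return Named nested list.
#' @export
study_config <- function() {
  list(
    genome = list(n_chr = 16L, total_length = 17, n_loci = 20000L,
                  mutation_rate = 1e-5),
    burnin = list(n_ind = 200L, n_gen = 2400L),
    architecture = list(n_qtl = 500L, p_pleio = 0.75, rho = -0.9,
                        base_var = c(bw = 6, bn = 12), maf_min = 0.1,
                        h2 = 0.8, means = c(bw = 15, bn = 15)),
    history = list(max_attempts = 5L),
    scheme = list(strategy = "RRS", pattern = "GGGG",
                  n_candidates = 120L, n_genotyped_hybrids = 0L),
    run = list(seed = 1L, n_replicates = 1L, out_dir = "results")
  )
}

#' Load a study configuration from YAML
#'
#' Reads a YAML file and merges it recursively over [study_config()], so
#' a file only needs to state what differs from the defaults. Unknown
#' top-level sections are rejected to catch typos.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Configuration list as from [study_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- study_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad) > 0L)
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  for (nm in names(user)) {
    if (!is.list(user[[nm]]))
      stop("section '", nm, "' must be a mapping")
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
  }
  with(cfg$architecture, {
    if (p_pleio < 0 || p_pleio > 1) stop("p_pleio must be in [0, 1]")
    if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  })
  if (cfg$genome$n_loci < 1L || cfg$genome$n_chr < 1L)
    stop("genome sizes must be positive")
  cfg
}

#' Write the tables and manifest of one or more scheme runs
#'
#' Writes, under `dir`: one per-generation records CSV per run, one
#' accuracy CSV per run, a combined summary CSV across runs, and a JSON
#' manifest recording the seed and each run's configuration.
#'
#' @param runs Named list of `scheme_run` objects.
#' @param dir Output directory (created if needed).
#' @param seed The seed the runs were produced under (recorded in the
#'   manifest).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(runs, dir, seed = NA_integer_) {
  stopifnot(length(runs) > 0L, !is.null(names(runs)), all(names(runs) != ""))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  summary_rows <- list()
  manifest <- list(seed = seed, runs = list())
  for (nm in names(runs)) {
    run <- runs[[nm]]
    stopifnot(inherits(run, "scheme_run"))
    p1 <- file.path(dir, paste0(nm, "_generations.csv"))
    utils::write.csv(run$records, p1, row.names = FALSE)
    p2 <- file.path(dir, paste0(nm, "_accuracy.csv"))
    utils::write.csv(run$accuracy, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
    s <- run$summary
    summary_rows[[nm]] <- data.frame(
      run = nm, strategy = run$config$strategy,
      pattern = run$config$pattern,
      n_candidates = run$config$n_candidates,
      n_genotyped_hybrids = run$config$n_genotyped_hybrids,
      total_years = s$total_years,
      cumulative_response_pct = s$cumulative_response_pct,
      annual_response_pct = s$annual_response_pct,
      dF_y_deli = s$dF_y["deli"], dF_y_lame = s$dF_y["lame"])
    manifest$runs[[nm]] <- list(
      strategy = run$config$strategy, pattern = run$config$pattern,
      n_candidates = run$config$n_candidates,
      n_genotyped_hybrids = run$config$n_genotyped_hybrids,
      files = basename(c(p1, p2)))
  }
  p3 <- file.path(dir, "summary.csv")
  utils::write.csv(do.call(rbind, summary_rows), p3, row.names = FALSE)
  p4 <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p4, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, p3, p4))
}

#' Export a population's phased genotypes as VCF
#'
#' One row per locus; positions are the map positions in base pairs
#' (1 Morgan mapped to 1 Mb, 1-based), chromosomes named `chr1..chrK`,
#' alleles coded REF=A, ALT=T, genotypes phased (`h1|h2`).
#'
#' @param pop A `palm_pop`.
#' @param map The `palm_map`.
#' @param file Output path (plain text `.vcf`).
#' @return Invisibly, `file`.
#' @export
export_genotypes <- function(pop, map, file) {
  n <- n_ind(pop)
  stopifnot(ncol(pop$haplo) == map$n_loci)
  ids <- paste0("ind", pop$id)
  header <- c("##fileformat=VCFv4.2",
              "##source=rrgsim",
              paste0("##contig=<ID=chr", seq_len(map$n_chr), ",length=",
                     ceiling(map$chr_len * 1e6) + 1L, ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  h1 <- pop$haplo[2L * seq_len(n) - 1L, , drop = FALSE]
  h2 <- pop$haplo[2L * seq_len(n), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = map$n_loci)
  body <- paste(paste0("chr", map$chr),
                as.integer(round(map$pos * 1e6)) + 1L,
                paste0("locus", seq_len(map$n_loci)),
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), file)
  invisible(file)
}

#' Export a matrix as plain text
#'
#' `dense` writes a tab-separated table with row and column names;
#' `triplet` writes `i j value` rows for the non-zero entries (upper
#' triangle only when the matrix is symmetric).
#'
#' @param M Numeric matrix (dense or `Matrix` sparse).
#' @param file Output path.
#' @param format `"dense"` or `"triplet"`.
#' @return Invisibly, `file`.
#' @export
export_matrix <- function(M, file, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(as.matrix(M), file, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    T3 <- as(as(as(M, "dMatrix"), "generalMatrix"), "TsparseMatrix")
    sym <- isSymmetric(as.matrix(M))
    i <- T3@i + 1L; j <- T3@j + 1L; x <- T3@x
    if (sym) {
      keep <- i <= j
      i <- i[keep]; j <- j[keep]; x <- x[keep]
    }
    utils::write.table(data.frame(i = i, j = j, value = x), file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' Build a toy end-to-end fixture
#'
#' Generates, at a deliberately small scale, everything the full study
#' needs: a short genome, a quick burn-in, a compressed population
#' history and matching scheme configurations. Used by the examples and
#' the test suite to exercise the complete pipeline in seconds. The
#' replicate-acceptance filter is disabled (its windows describe the
#' full-scale study).
#'
#' @param scale `"tiny"` (2 chromosomes, 200 loci, the fastest) or
#'   `"small"` (4 chromosomes, 1000 loci).
#' @param seed Seed applied before generation.
#' @return List: `map`, `params`, `base` (burn-in population),
#'   `founders`, and `configs` (named `scheme_config`s for `rrs`, `par`
#'   and `hyb` at the toy scale).
#' @export
make_toy_fixture <- function(scale = c("tiny", "small"), seed = 1L) {
  scale <- match.arg(scale)
  set.seed(seed)
  if (scale == "tiny") {
    map <- palm_map(n_chr = 2L, total_length = 1, n_loci = 200L)
    burn <- c(n_ind = 30L, n_gen = 50L)
    n_qtl <- 20L
    hist <- history_config(
      divergence_gens = 5L, divergence_size = 15L,
      deli_founders = 4L, deli_random_sizes = c(10L),
      deli_mass_sizes = c(12L, 16L), deli_retain = 0.7,
      lame_founders = 6L, lame_mass_sizes = c(12L, 16L),
      lame_retain = 0.5,
      prerrs_sizes = c(16L, 24L), prerrs_n_selected = 6L,
      deli_ped_gens = 3L, lame_ped_gens = 2L)
    cand <- 24L; pt_par <- 12L; crosses <- 30L; per_cross <- 5L
    n_sel <- 6L; panel <- 60L
  } else {
    map <- palm_map(n_chr = 4L, total_length = 4, n_loci = 1000L)
    burn <- c(n_ind = 50L, n_gen = 150L)
    n_qtl <- 50L
    hist <- history_config(
      divergence_gens = 10L, divergence_size = 25L,
      deli_founders = 4L, deli_random_sizes = c(15L, 15L),
      deli_mass_sizes = c(20L, 25L, 30L), deli_retain = 0.7,
      lame_founders = 10L, lame_mass_sizes = c(25L, 30L),
      lame_retain = 0.4,
      prerrs_sizes = c(30L, 40L), prerrs_n_selected = 8L,
      deli_ped_gens = 3L, lame_ped_gens = 2L)
    cand <- 40L; pt_par <- 20L; crosses <- 50L; per_cross <- 6L
    n_sel <- 8L; panel <- 200L
  }
  params <- meiosis_params()
  base <- run_burnin(burn["n_ind"], burn["n_gen"], map, params)
  founders <- build_founders(base, map, params, n_qtl = n_qtl,
                             p_pleio = 0.75, maf_min = 0.05,
                             hist = hist, targets = NULL,
                             max_attempts = 1L, ld_max_pairs = 0L)
  mk <- function(strategy, n_geno = 0L, pattern = "GGGG")
    scheme_config(strategy, pattern = pattern, n_candidates = cand,
                  n_genotyped_hybrids = n_geno, n_pt_crosses = crosses,
                  n_per_cross = per_cross, n_pt_parents = pt_par,
                  n_selected = n_sel, n_panel = panel, panel_maf = 0.02,
                  .allow_custom = TRUE)
  list(map = map, params = params, base = base, founders = founders,
       configs = list(rrs = mk("RRS"),
                      par = mk("RRGS_PAR"),
                      par_gm = mk("RRGS_PAR", pattern = "GMGM"),
                      hyb = mk("RRGS_HYB", n_geno = 40L),
                      hyb_gm = mk("RRGS_HYB", n_geno = 40L,
                                  pattern = "GMMM")))
}
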