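#' Validate and normalize a pedigree table
#'
#' A pedigree is a data frame with integer columns `id`, `sire`, `dam`
#' (`NA` for unknown parents), ordered so that parents precede offspring.
#'
#' @param ped Pedigree data frame.
#' @return The pedigree with an extra attribute `pos`: named lookup from id
#'   to row.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  pos <- seq_len(nrow(ped))
  names(pos) <- as.character(ped$id)
  sp <- unname(pos[as.character(ped$sire)])
  dp <- unname(pos[as.character(ped$dam)])
  if (any(!is.na(ped$sire) & is.na(sp)) || any(!is.na(ped$dam) & is.na(dp)))
    stop("parent id missing from pedigree")
  if (any(sp >= pos, na.rm = TRUE) || any(dp >= pos, na.rm = TRUE))
    stop("pedigree not sorted parents-first (or cyclic)")
  attr(ped, "sire_pos") <- sp
  attr(ped, "dam_pos") <- dp
  ped
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`), parents before
#'   offspring; `NA` parents are unrelated, non-inbred founders.
#' @return Dense symmetric matrix with dimnames = ids and attribute `F`
#'   (inbreeding coefficients, `diag(A) - 1`).
#' @export
pedigree_A <- function(ped) {
  ped <- validate_pedigree(ped)
  sp <- attr(ped, "sire_pos")
  dp <- attr(ped, "dam_pos")
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sp[i]; d <- dp[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (!is.na(s)) A[s, j] else 0
      row_d <- if (!is.na(d)) A[d, j] else 0
      A[i, j] <- A[j, i] <- 0.5 * (row_s + row_d)
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$id, ped$id)
  attr(A, "F") <- setNames(diag(A) - 1, ped$id)
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' Tabular-method F restricted to the ancestor closure of `ids`, so large
#' pedigrees with many terminal individuals stay cheap.
#'
#' @param ped Pedigree data frame.
#' @param ids Ids whose inbreeding is wanted (default: all).
#' @return Named numeric vector of F over `ids`.
#' @export
pedigree_inbreeding <- function(ped, ids = ped$id) {
  keep <- ancestor_closure(ped, ids)
  sub <- ped[ped$id %in% keep, , drop = FALSE]
  A <- pedigree_A(sub)
  attr(A, "F")[as.character(ids)]
}

ancestor_closure <- function(ped, ids) {
  pos <- setNames(seq_len(nrow(ped)), as.character(ped$id))
  keep <- unique(ids)
  frontier <- keep
  while (length(frontier) > 0) {
    rows <- pos[as.character(frontier)]
    parents <- unique(c(ped$sire[rows], ped$dam[rows]))
    parents <- parents[!is.na(parents)]
    frontier <- setdiff(parents, keep)
    keep <- c(keep, frontier)
  }
  keep
}

# Mendelian-sampling variances d_i and parent positions, shared by the
# A-inverse and the indirect A-submatrix computation.
ped_decomposition <- function(ped) {
  ped <- validate_pedigree(ped)
  sp <- attr(ped, "sire_pos")
  dp <- attr(ped, "dam_pos")
  parents <- unique(c(sp, dp))
  parents <- parents[!is.na(parents)]
  Fv <- rep(0, nrow(ped))
  if (length(parents) > 0) {
    pid <- ped$id[parents]
    Fv[parents] <- pedigree_inbreeding(ped, pid)
  }
  Fs <- ifelse(is.na(sp), NA, Fv[sp])
  Fd <- ifelse(is.na(dp), NA, Fv[dp])
  d <- ifelse(is.na(sp) & is.na(dp), 1,
       ifelse(!is.na(sp) & !is.na(dp), 0.5 - 0.25 * (Fs + Fd),
              0.75 - 0.25 * ifelse(is.na(sp), Fd, Fs)))
  list(ped = ped, sire_pos = sp, dam_pos = dp, d = d, F_parents = Fv)
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding: only parental inbreeding
#' coefficients are needed, and they are obtained on the ancestor closure
#' of the parent set, so pedigrees with tens of thousands of terminal
#' individuals (hybrids) remain cheap.
#'
#' @param ped Pedigree data frame (`id`, `sire`, `dam`), parents first.
#' @return Sparse symmetric `Matrix::dgCMatrix` with dimnames = ids.
#' @export
a_inverse <- function(ped) {
  dec <- ped_decomposition(ped)
  n <- nrow(dec$ped)
  sp <- dec$sire_pos; dp <- dec$dam_pos
  di <- 1 / dec$d
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, di)
  hs <- !is.na(sp); hd <- !is.na(dp)
  add(idx[hs], sp[hs], -0.5 * di[hs]); add(sp[hs], idx[hs], -0.5 * di[hs])
  add(idx[hd], dp[hd], -0.5 * di[hd]); add(dp[hd], idx[hd], -0.5 * di[hd])
  add(sp[hs], sp[hs], 0.25 * di[hs])
  add(dp[hd], dp[hd], 0.25 * di[hd])
  b <- hs & hd
  add(sp[b], dp[b], 0.25 * di[b]); add(dp[b], sp[b], 0.25 * di[b])
  M <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n),
                            dimnames = list(dec$ped$id, dec$ped$id))
  Matrix::drop0(M)
}

#' Relationship submatrix by the indirect (triangular) method
#'
#' Computes `A[ids, ids]` without forming the full dense A, via the
#' decomposition A = (I-P)^-1 D (I-P)^-T: one sparse triangular solve per
#' requested column block followed by a crossproduct.
#'
#' @param ped Pedigree data frame.
#' @param ids Ids of the wanted block.
#' @return Dense matrix `length(ids)` square, dimnames = ids.
#' @export
pedigree_A_subset <- function(ped, ids) {
  dec <- ped_decomposition(ped)
  n <- nrow(dec$ped)
  sp <- dec$sire_pos; dp <- dec$dam_pos
  hs <- !is.na(sp); hd <- !is.na(dp)
  idx <- seq_len(n)
  P <- Matrix::sparseMatrix(i = c(idx[hs], idx[hd]), j = c(sp[hs], dp[hd]),
                            x = rep(0.5, sum(hs) + sum(hd)), dims = c(n, n))
  IP <- Matrix::Diagonal(n) - P
  pos <- match(as.character(ids), as.character(dec$ped$id))
  if (anyNA(pos)) stop("ids missing from pedigree")
  S <- Matrix::sparseMatrix(i = pos, j = seq_along(pos),
                            x = rep(1, length(pos)),
                            dims = c(n, length(pos)))
  W <- as.matrix(Matrix::solve(Matrix::t(IP), S))   # W = (I-P)^-T S
  A22 <- crossprod(W, dec$d * W)
  dimnames(A22) <- list(ids, ids)
  A22
}

#' VanRaden genomic relationship matrix
#'
#' Centered cross-product of dosages scaled by `2 * sum(p (1 - p))`, using
#' observed allele frequencies by default, then normalized so that the
#' mean diagonal equals one.
#'
#' @param dosage Integer matrix individuals x loci, entries 0/1/2.
#' @param freqs Optional allele-1 frequencies; default observed
#'   (`colMeans(dosage) / 2`).
#' @return Dense symmetric matrix with attribute `scale` (the
#'   pre-normalization mean diagonal).
#' @export
vanraden_G <- function(dosage, freqs = NULL) {
  if (any(!dosage %in% 0:2)) stop("dosages must be 0, 1 or 2")
  if (is.null(freqs)) freqs <- colMeans(dosage) / 2
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("no polymorphic loci: G scale is zero")
  Z <- sweep(dosage, 2L, 2 * freqs)
  G0 <- tcrossprod(Z) / denom
  md <- mean(diag(G0))
  if (md <= 0) stop("degenerate genotype panel: zero mean diagonal")
  G <- G0 / md
  rownames(G) <- colnames(G) <- rownames(dosage)
  attr(G, "scale") <- md
  G
}

#' Origin-aware multiallelic genomic relationship matrix
#'
#' For hybrids between two populations, every biallelic marker is recoded
#' as a four-allele marker (0 and 1 alleles by population of origin). Each
#' parental individual carries two copies of own-origin classes; each
#' hybrid carries one allele of each origin with the origin known from the
#' simulation (its gametotype). The class-dosage matrix is centered at
#' twice the observed class frequencies, cross-multiplied, scaled by
#' `sum(p (1 - p))` over classes, and normalized to a unit mean diagonal.
#'
#' @param deli_dosage,lame_dosage Parental dosage matrices (individuals x
#'   loci, 0/1/2) for the two populations.
#' @param hyb_deli_gam,hyb_lame_gam Hybrid gametotypes: 0/1 matrices
#'   (hybrids x loci) of the allele received from the Deli-side and the
#'   La Me-side parent. Pass `NULL` for both when there are no hybrids.
#' @return Dense symmetric matrix, rows ordered Deli parents, La Me
#'   parents, hybrids.
#' @export
origin_aware_G <- function(deli_dosage, lame_dosage,
                           hyb_deli_gam = NULL, hyb_lame_gam = NULL) {
  L <- ncol(deli_dosage)
  stopifnot(ncol(lame_dosage) == L)
  nh <- 0L
  if (!is.null(hyb_deli_gam)) {
    stopifnot(ncol(hyb_deli_gam) == L, ncol(hyb_lame_gam) == L,
              nrow(hyb_deli_gam) == nrow(hyb_lame_gam))
    if (any(!hyb_deli_gam %in% 0:1) || any(!hyb_lame_gam %in% 0:1))
      stop("gametotype alleles must be 0/1")
    nh <- nrow(hyb_deli_gam)
  }
  nd <- nrow(deli_dosage); nl <- nrow(lame_dosage)
  n <- nd + nl + nh
  zd <- matrix(0, nl, L); zl <- matrix(0, nd, L)
  # class order: 1_Deli, 0_Deli, 1_LaMe, 0_LaMe
  M <- cbind(rbind(deli_dosage, zd,
                   if (nh) hyb_deli_gam),
             rbind(2 - deli_dosage, zd,
                   if (nh) 1 - hyb_deli_gam),
             rbind(zl, lame_dosage,
                   if (nh) hyb_lame_gam),
             rbind(zl, 2 - lame_dosage,
                   if (nh) 1 - hyb_lame_gam))
  p <- colMeans(M) / 2
  denom <- sum(p * (1 - p))
  if (denom <= 0) stop("no polymorphic allele classes: G scale is zero")
  Z <- sweep(M, 2L, 2 * p)
  G0 <- tcrossprod(Z) / denom
  md <- mean(diag(G0))
  G <- G0 / md
  ids <- c(rownames(deli_dosage), rownames(lame_dosage),
           if (nh) rownames(hyb_deli_gam))
  if (!is.null(ids) && length(ids) == n) rownames(G) <- colnames(G) <- ids
  attr(G, "scale") <- md
  G
}

#' Single-step combined relationship matrix inverse
#'
#' H^-1 = A_all^-1 + [0 0; 0 G^-1 - A22^-1] on the genotyped block, after
#' blending G with A22 (`G* = (1 - blend) G + blend A22`) to guarantee
#' invertibility. Stored in structured form (sparse pedigree inverse plus
#' a dense correction on the genotyped block) so that matrix-vector
#' products stay cheap for large pedigrees.
#'
#' @param A_all_inv Sparse inverse of the full pedigree relationship
#'   matrix (from [a_inverse()]), covering all individuals.
#' @param A22 Dense pedigree relationship block of the genotyped
#'   individuals (from [pedigree_A_subset()]).
#' @param G Genomic relationship matrix of the genotyped individuals, in
#'   the same order as `A22`.
#' @param genotyped_index Positions of the genotyped individuals within
#'   the full pedigree order.
#' @param blend Blending weight on A22 (default 0.01; 0 disables
#'   blending).
#' @return Object of class `h_inverse`.
#' @export
h_inverse <- function(A_all_inv, A22, G, genotyped_index, blend = 0.01) {
  k <- length(genotyped_index)
  stopifnot(nrow(A22) == k, nrow(G) == k)
  Gb <- (1 - blend) * G + blend * A22
  Ginv <- tryCatch(chol2inv(chol(Gb)), error = function(e) {
    if (blend <= 0)
      stop("G is singular; enable blending (blend > 0)")
    stop("blended G is singular: ", conditionMessage(e))
  })
  A22inv <- chol2inv(chol(A22))
  structure(list(Ainv = A_all_inv, corr = Ginv - A22inv,
                 idx = as.integer(genotyped_index), n = nrow(A_all_inv)),
            class = "h_inverse")
}

#' Multiply an `h_inverse` by a vector or matrix
#' @param h An `h_inverse`.
#' @param x Numeric vector or matrix with `h$n` rows.
#' @export
hinv_mult <- function(h, x) {
  x <- as.matrix(x)
  y <- as.matrix(h$Ainv %*% x)
  y[h$idx, ] <- y[h$idx, , drop = FALSE] + h$corr %*% x[h$idx, , drop = FALSE]
  y
}

#' Diagonal of an `h_inverse`
#' @param h An `h_inverse`.
#' @export
hinv_diag <- function(h) {
  d <- Matrix::diag(h$Ainv)
  d[h$idx] <- d[h$idx] + diag(h$corr)
  d
}

#' @export
as.matrix.h_inverse <- function(x, ...) {
  M <- as.matrix(x$Ainv)
  M[x$idx, x$idx] <- M[x$idx, x$idx] + x$corr
  M
}
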