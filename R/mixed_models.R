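#' Variance components for the bivariate models
#'
#' @param terms Named list of 2x2 additive (co)variance matrices (rows and
#'   columns bw, bn), one per random term (e.g. `deli`, `lame`, or a single
#'   `a` for the single-relationship model).
#' @param resid Residual variances `c(bw=, bn=)`; the residual covariance
#'   is fixed at zero.
#' @return Object of class `varcomps`.
#' @export
varcomps <- function(terms, resid) {
  stopifnot(is.list(terms), length(resid) == 2L)
  for (S in terms) {
    stopifnot(is.matrix(S), nrow(S) == 2L, ncol(S) == 2L)
    if (max(abs(S - t(S))) > 1e-8) stop("covariance matrix not symmetric")
    if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
      stop("covariance matrix not positive semi-definite")
  }
  if (any(resid <= 0)) stop("residual variances must be positive")
  structure(list(terms = terms, resid = setNames(as.numeric(resid),
                                                 c("bw", "bn"))),
            class = "varcomps")
}

# robust inverse of a 2x2 (co)variance matrix: eigenvalues are floored at
# a small fraction of the largest so a collapsed trait variance (e.g. all
# of one trait's QTL fixed) degrades gracefully instead of failing
spd_inv <- function(S, eps_frac = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  floor_ev <- max(e$values, eps_frac) * eps_frac
  v <- pmax(e$values, floor_ev)
  e$vectors %*% (t(e$vectors) / v)
}

kernel_inv <- function(K, jitter = 1e-10) {
  K <- as.matrix(K)
  tryCatch(chol2inv(chol(K)), error = function(e)
    chol2inv(chol(K + diag(jitter * mean(diag(K)) + 1e-12, nrow(K)))))
}

#' Bivariate two-kernel GCA mixed model (RRS / RRGS_PAR)
#'
#' Fits, by direct solution of the mixed-model equations, the bivariate
#' model in which each hybrid record is the sum of a per-trait overall
#' mean, the general combining ability (GCA) of its Deli parent, the GCA
#' of its La Me parent and an independent residual. The GCA vectors of
#' each population follow a bivariate normal with the population's 2x2
#' additive covariance (on the GCA scale) Kronecker the supplied kernel
#' (0.5 A for pedigree-based RRS, the genomic G for RRGS_PAR).
#'
#' @param records Data frame with columns `deli`, `lame` (indices into the
#'   respective kernels) and `y_bw`, `y_bn` (hybrid phenotypes).
#' @param K_deli,K_lame Kernel matrices over the candidates of each
#'   population.
#' @param vc A `varcomps` with terms `deli` and `lame`.
#' @return Object of class `blup_fit`: `mu` (per-trait means), `gca`
#'   (list of matrices candidates x 2 per population), and solver
#'   diagnostics (`rel_residual`).
#' @export
solve_gca_bivariate <- function(records, K_deli, K_lame, vc) {
  stopifnot(inherits(vc, "varcomps"),
            all(c("deli", "lame") %in% names(vc$terms)))
  nD <- nrow(K_deli); nL <- nrow(K_lame)
  d <- as.integer(records$deli); l <- as.integer(records$lame)
  stopifnot(max(d) <= nD, max(l) <= nL, min(d) >= 1L, min(l) >= 1L)
  y <- cbind(records$y_bw, records$y_bn)
  nr <- nrow(y)
  re <- vc$resid
  zeroD <- max(abs(vc$terms$deli)) == 0
  zeroL <- max(abs(vc$terms$lame)) == 0
  if (zeroD && zeroL) {
    mu <- colMeans(y)
    return(structure(list(mu = setNames(mu, c("bw", "bn")),
                          gca = list(deli = matrix(0, nD, 2,
                                       dimnames = list(rownames(K_deli),
                                                       c("bw", "bn"))),
                                     lame = matrix(0, nL, 2,
                                       dimnames = list(rownames(K_lame),
                                                       c("bw", "bn")))),
                          vc = vc, rel_residual = 0),
                     class = "blup_fit"))
  }
  if (zeroD || zeroL) stop("one-sided zero GCA variance is not supported")
  ZD <- Matrix::sparseMatrix(i = seq_len(nr), j = d, x = 1, dims = c(nr, nD))
  ZL <- Matrix::sparseMatrix(i = seq_len(nr), j = l, x = 1, dims = c(nr, nL))
  SDi <- spd_inv(vc$terms$deli)
  SLi <- spd_inv(vc$terms$lame)
  KDi <- kernel_inv(K_deli)
  KLi <- kernel_inv(K_lame)
  m <- 2L + 2L * nD + 2L * nL
  # solution order: muBW, muBN, uD_bw, uD_bn, uL_bw, uL_bn
  oMu <- 1:2
  oD <- function(t) 2L + (t - 1L) * nD + seq_len(nD)
  oL <- function(t) 2L + 2L * nD + (t - 1L) * nL + seq_len(nL)
  C <- matrix(0, m, m)
  rhs <- numeric(m)
  ZDtZD <- as.matrix(Matrix::crossprod(ZD))
  ZLtZL <- as.matrix(Matrix::crossprod(ZL))
  ZDtZL <- as.matrix(Matrix::crossprod(ZD, ZL))
  cD <- Matrix::colSums(ZD); cL <- Matrix::colSums(ZL)
  for (t in 1:2) {
    ri <- 1 / re[t]
    C[oMu[t], oMu[t]] <- nr * ri
    C[oMu[t], oD(t)] <- C[oD(t), oMu[t]] <- cD * ri
    C[oMu[t], oL(t)] <- C[oL(t), oMu[t]] <- cL * ri
    C[oD(t), oD(t)] <- ZDtZD * ri
    C[oL(t), oL(t)] <- ZLtZL * ri
    C[oD(t), oL(t)] <- ZDtZL * ri
    C[oL(t), oD(t)] <- t(ZDtZL) * ri
    rhs[oMu[t]] <- sum(y[, t]) * ri
    rhs[oD(t)] <- as.vector(Matrix::crossprod(ZD, y[, t])) * ri
    rhs[oL(t)] <- as.vector(Matrix::crossprod(ZL, y[, t])) * ri
  }
  for (t1 in 1:2) for (t2 in 1:2) {
    C[oD(t1), oD(t2)] <- C[oD(t1), oD(t2)] + SDi[t1, t2] * KDi
    C[oL(t1), oL(t2)] <- C[oL(t1), oL(t2)] + SLi[t1, t2] * KLi
  }
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("singular mixed-model equations: ", conditionMessage(e)))
  rel <- sqrt(sum((C %*% sol - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  gD <- cbind(bw = sol[oD(1)], bn = sol[oD(2)])
  gL <- cbind(bw = sol[oL(1)], bn = sol[oL(2)])
  rownames(gD) <- rownames(K_deli); rownames(gL) <- rownames(K_lame)
  structure(list(mu = setNames(sol[oMu], c("bw", "bn")),
                 gca = list(deli = gD, lame = gL), vc = vc,
                 rel_residual = rel),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("blup_fit: mu = (%.3f, %.3f), relative MME residual %.2e\n",
              x$mu[1], x$mu[2], x$rel_residual))
  invisible(x)
}

#' Bivariate single-step GBLUP (RRGS_HYB)
#'
#' Fits the single-relationship bivariate model in which every individual
#' (parents and hybrids, genotyped or not) carries one breeding value per
#' trait, with covariance the 2x2 additive matrix Kronecker H. Hybrid
#' phenotypes are the records; parents are connected through H. Solved by
#' preconditioned conjugate gradients on the mixed-model equations using
#' the structured H^-1 (sparse pedigree inverse plus dense genotyped-block
#' correction), or densely for small systems.
#'
#' @param records Data frame with `ind` (position of the phenotyped
#'   individual in the H order) and `y_bw`, `y_bn`.
#' @param Hinv An `h_inverse` (or a plain matrix taken as the dense
#'   kernel inverse).
#' @param vc A `varcomps` with a single term `a`.
#' @param method `"auto"`, `"dense"` or `"pcg"`.
#' @param tol Relative-residual convergence tolerance for PCG.
#' @param maxit Maximum PCG iterations.
#' @return A `blup_fit` with `mu`, `a` (matrix n x 2 of breeding values
#'   for every individual) and diagnostics.
#' @export
solve_ssgblup_bivariate <- function(records, Hinv, vc,
                                    method = c("auto", "dense", "pcg"),
                                    tol = 1e-8, maxit = 5000L) {
  method <- match.arg(method)
  stopifnot(inherits(vc, "varcomps"), "a" %in% names(vc$terms))
  n <- if (inherits(Hinv, "h_inverse")) Hinv$n else nrow(Hinv)
  ind <- as.integer(records$ind)
  stopifnot(min(ind) >= 1L, max(ind) <= n)
  y <- cbind(records$y_bw, records$y_bn)
  nr <- nrow(y)
  re <- vc$resid
  if (max(abs(vc$terms$a)) == 0) {
    return(structure(list(mu = setNames(colMeans(y), c("bw", "bn")),
                          a = matrix(0, n, 2,
                                     dimnames = list(NULL, c("bw", "bn"))),
                          vc = vc, rel_residual = 0, iterations = 0L),
                     class = "blup_fit"))
  }
  Si <- spd_inv(vc$terms$a)
  counts <- tabulate(ind, n)
  hmult <- if (inherits(Hinv, "h_inverse")) {
    function(x) hinv_mult(Hinv, x)
  } else {
    function(x) Hinv %*% x
  }
  hdiag <- if (inherits(Hinv, "h_inverse")) hinv_diag(Hinv) else diag(Hinv)
  # unknown vector: c(muBW, muBN, u_bw (n), u_bn (n))
  apply_C <- function(v) {
    mu <- v[1:2]
    U <- matrix(v[-(1:2)], n, 2L)
    HU <- hmult(U)
    out_mu <- numeric(2L)
    out_U <- matrix(0, n, 2L)
    for (t in 1:2) {
      ri <- 1 / re[t]
      fitted_at_rec <- mu[t] + U[ind, t]
      out_mu[t] <- sum(fitted_at_rec) * ri
      zr <- numeric(n)
      zr[ind] <- fitted_at_rec * ri
      out_U[, t] <- zr
    }
    out_U <- out_U + HU %*% t(Si)
    c(out_mu, as.vector(out_U))
  }
  rhs <- c(sum(y[, 1]) / re[1], sum(y[, 2]) / re[2],
           { z <- numeric(n); z[ind] <- y[, 1] / re[1]; z },
           { z <- numeric(n); z[ind] <- y[, 2] / re[2]; z })
  m <- 2L + 2L * n
  if (method == "dense" || (method == "auto" && m <= 3000L)) {
    Hd <- if (inherits(Hinv, "h_inverse")) as.matrix(Hinv) else as.matrix(Hinv)
    C <- matrix(0, m, m)
    oU <- function(t) 2L + (t - 1L) * n + seq_len(n)
    for (t in 1:2) {
      ri <- 1 / re[t]
      C[t, t] <- nr * ri
      C[t, oU(t)] <- C[oU(t), t] <- counts * ri
      D <- matrix(0, n, n)
      D[cbind(ind, ind)] <- ri   # at most one record per individual
      if (any(counts > 1L)) {
        D <- diag(counts * ri, n)
      }
      C[oU(t), oU(t)] <- D
    }
    for (t1 in 1:2) for (t2 in 1:2)
      C[oU(t1), oU(t2)] <- C[oU(t1), oU(t2)] + Si[t1, t2] * Hd
    sol <- solve(C, rhs)
    rel <- sqrt(sum((C %*% sol - rhs)^2)) / sqrt(sum(rhs^2))
    it <- NA_integer_
  } else {
    prec <- c(nr / re[1], nr / re[2],
              counts / re[1] + Si[1, 1] * hdiag,
              counts / re[2] + Si[2, 2] * hdiag)
    prec[prec <= 0] <- 1
    sol <- numeric(m)
    r <- rhs - apply_C(sol)
    z <- r / prec
    p <- z
    rz <- sum(r * z)
    b0 <- sqrt(sum(rhs^2))
    it <- 0L
    while (sqrt(sum(r^2)) / b0 > tol && it < maxit) {
      Cp <- apply_C(p)
      alpha <- rz / sum(p * Cp)
      sol <- sol + alpha * p
      r <- r - alpha * Cp
      z <- r / prec
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
      it <- it + 1L
    }
    rel <- sqrt(sum(r^2)) / b0
    if (rel > tol)
      warning(sprintf("PCG did not reach tolerance (%.1e after %d iters)",
                      rel, it))
  }
  a <- cbind(bw = sol[2L + seq_len(n)], bn = sol[2L + n + seq_len(n)])
  structure(list(mu = setNames(sol[1:2], c("bw", "bn")), a = a, vc = vc,
                 rel_residual = rel, iterations = it),
            class = "blup_fit")
}

#' Expected hybrid bunch production of a cross
#'
#' Predicted hybrid trait = fitted mean + Deli GCA + La Me GCA per trait;
#' expected bunch production is the product of the two predicted traits.
#'
#' @param gca_deli,gca_lame Numeric length-2 vectors (bw, bn) or matrices
#'   n x 2 (recycled row-wise against each other).
#' @param means Fitted per-trait means `c(bw=, bn=)`.
#' @return Numeric vector of expected productions.
#' @export
predict_cross_value <- function(gca_deli, gca_lame, means) {
  gd <- if (is.matrix(gca_deli)) gca_deli else matrix(gca_deli, 1L, 2L)
  gl <- if (is.matrix(gca_lame)) gca_lame else matrix(gca_lame, 1L, 2L)
  n <- max(nrow(gd), nrow(gl))
  if (nrow(gd) == 1L) gd <- gd[rep(1L, n), , drop = FALSE]
  if (nrow(gl) == 1L) gl <- gl[rep(1L, n), , drop = FALSE]
  (means[1] + gd[, 1] + gl[, 1]) * (means[2] + gd[, 2] + gl[, 2])
}

#' EM-REML variance components for the multi-kernel bivariate model
#'
#' Expectation-maximization REML on the dense mixed-model equations: each
#' random term's 2x2 covariance is updated from its BLUP cross-products
#' plus the prediction-error trace, and the per-trait residuals from the
#' residual cross-products. Intended for moderate systems (hundreds of
#' equations); the breeding-scheme engine normally runs with the true
#' simulated components and uses this path only on demand.
#'
#' @param y Matrix n x 2 of records (bw, bn).
#' @param links Data frame, one integer column per kernel, giving each
#'   record's level in that kernel.
#' @param kernels Named list of kernel matrices (names match `links`).
#' @param start A `varcomps` to start from.
#' @param max_iter,tol Iteration control; convergence is declared when the
#'   relative change of every component is below `tol`.
#' @return A `varcomps` with attributes `loglik` (REML log-likelihood
#'   trace, up to a constant), `iterations` and `converged`.
#' @export
estimate_varcomps_em <- function(y, links, kernels, start,
                                 max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(start, "varcomps"),
            all(names(kernels) %in% names(start$terms)),
            all(names(kernels) %in% names(links)))
  nk <- length(kernels)
  kn <- names(kernels)
  nr <- nrow(y)
  q <- vapply(kernels, nrow, integer(1))
  Kinv <- lapply(kernels, kernel_inv)
  logdetK <- vapply(kernels, function(K)
    as.numeric(determinant(as.matrix(K), logarithm = TRUE)$modulus),
    numeric(1))
  Z <- lapply(kn, function(k)
    Matrix::sparseMatrix(i = seq_len(nr), j = links[[k]], x = 1,
                         dims = c(nr, q[[k]])))
  names(Z) <- kn
  terms <- start$terms[kn]
  re <- start$resid
  off <- list(mu = 1:2)
  cur <- 2L
  for (k in kn) {
    off[[k]] <- lapply(1:2, function(t) cur + (t - 1L) * q[[k]] + seq_len(q[[k]]))
    cur <- cur + 2L * q[[k]]
  }
  m <- cur
  ZtZ <- lapply(Z, function(z) as.matrix(Matrix::crossprod(z)))
  ZtZx <- list()
  for (a in seq_len(nk)) for (b in seq_len(nk)) if (a < b)
    ZtZx[[paste(kn[a], kn[b])]] <- as.matrix(Matrix::crossprod(Z[[a]], Z[[b]]))
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    C <- matrix(0, m, m)
    rhs <- numeric(m)
    for (t in 1:2) {
      ri <- 1 / re[t]
      C[t, t] <- nr * ri
      rhs[t] <- sum(y[, t]) * ri
      for (k in kn) {
        cs <- Matrix::colSums(Z[[k]])
        C[t, off[[k]][[t]]] <- C[off[[k]][[t]], t] <- cs * ri
        C[off[[k]][[t]], off[[k]][[t]]] <-
          C[off[[k]][[t]], off[[k]][[t]]] + ZtZ[[k]] * ri
        rhs[off[[k]][[t]]] <- as.vector(Matrix::crossprod(Z[[k]], y[, t])) * ri
      }
      for (a in seq_len(nk)) for (b in seq_len(nk)) if (a < b) {
        M <- ZtZx[[paste(kn[a], kn[b])]] * ri
        C[off[[kn[a]]][[t]], off[[kn[b]]][[t]]] <-
          C[off[[kn[a]]][[t]], off[[kn[b]]][[t]]] + M
        C[off[[kn[b]]][[t]], off[[kn[a]]][[t]]] <-
          C[off[[kn[b]]][[t]], off[[kn[a]]][[t]]] + t(M)
      }
    }
    for (k in kn) {
      Si <- solve(terms[[k]])
      for (t1 in 1:2) for (t2 in 1:2)
        C[off[[k]][[t1]], off[[k]][[t2]]] <-
          C[off[[k]][[t1]], off[[k]][[t2]]] + Si[t1, t2] * Kinv[[k]]
    }
    Cinv <- solve(C)
    sol <- Cinv %*% rhs
    # REML log-likelihood (up to a constant)
    yPy <- sum(y[, 1]^2) / re[1] + sum(y[, 2]^2) / re[2] - sum(sol * rhs)
    logdetG <- sum(vapply(kn, function(k)
      q[[k]] * as.numeric(determinant(terms[[k]], TRUE)$modulus) +
        2 * logdetK[[k]], numeric(1)))
    logdetC <- as.numeric(determinant(C, TRUE)$modulus)
    ll <- -0.5 * (nr * sum(log(re)) + logdetG + logdetC + yPy)
    ll_trace <- c(ll_trace, ll)
    new_terms <- terms
    for (k in kn) {
      U <- cbind(sol[off[[k]][[1]]], sol[off[[k]][[2]]])
      S <- matrix(0, 2, 2)
      for (t1 in 1:2) for (t2 in 1:2) {
        tr_term <- sum(Kinv[[k]] * Cinv[off[[k]][[t1]], off[[k]][[t2]]])
        S[t1, t2] <- (crossprod(U[, t1], Kinv[[k]] %*% U[, t2]) + tr_term) / q[[k]]
      }
      new_terms[[k]] <- (S + t(S)) / 2
    }
    new_re <- re
    for (t in 1:2) {
      fitted <- rep(sol[t], nr)
      Wt_cols <- c(t, unlist(lapply(kn, function(k) off[[k]][[t]])))
      for (k in kn) fitted <- fitted + sol[off[[k]][[t]]][links[[k]]]
      e <- y[, t] - fitted
      # tr(W_t Cinv W_t'): rows of W_t are sparse (1 for mu, 1 per kernel)
      tr_w <- nr * Cinv[t, t]
      for (k in kn) {
        dk <- diag(Cinv[off[[k]][[t]], off[[k]][[t]]])
        tr_w <- tr_w + sum(tabulate(links[[k]], q[[k]]) * dk)
        tr_w <- tr_w + 2 * sum(Cinv[t, off[[k]][[t]]][links[[k]]])
      }
      for (a in seq_len(nk)) for (b in seq_len(nk)) if (a < b) {
        Cab <- Cinv[off[[kn[a]]][[t]], off[[kn[b]]][[t]]]
        tr_w <- tr_w + 2 * sum(Cab[cbind(links[[kn[a]]], links[[kn[b]]])])
      }
      new_re[t] <- (sum(e^2) + tr_w) / nr
    }
    delta <- max(abs(unlist(new_terms) - unlist(terms)),
                 abs(new_re - re)) / max(abs(unlist(terms)), re)
    terms <- new_terms
    re <- new_re
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- varcomps(terms, re)
  attr(out, "loglik") <- ll_trace
  attr(out, "iterations") <- length(ll_trace)
  attr(out, "converged") <- converged
  if (!converged)
    attr(out, "warning") <- "EM-REML did not converge within max_iter"
  out
}
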