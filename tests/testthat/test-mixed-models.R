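test_that("variance component containers validate their inputs", {
  S <- diag(2)
  expect_s3_class(varcomps(list(deli = S, lame = S), c(1, 2)), "varcomps")
  expect_error(varcomps(list(a = matrix(c(1, 2, 3, 4), 2L)), c(1, 1)),
               "symmetric")
  expect_error(varcomps(list(a = matrix(c(1, 2, 2, 1), 2L)), c(1, 1)),
               "definite")
  expect_error(varcomps(list(a = S), c(0, 1)), "positive")
})

test_that("the GCA solver reproduces the closed-form GLS solution per trait", {
  set.seed(31)
  nD <- 5L; nL <- 4L; nr <- 40L
  K_d <- crossprod(matrix(rnorm(nD * nD), nD)) / nD + diag(nD)
  K_l <- crossprod(matrix(rnorm(nL * nL), nL)) / nL + diag(nL)
  d <- sample.int(nD, nr, replace = TRUE)
  l <- sample.int(nL, nr, replace = TRUE)
  s_d <- c(1.5, 0.8); s_l <- c(0.9, 1.2); s_e <- c(2, 3)
  y <- cbind(rnorm(nr, 10, 2), rnorm(nr, 20, 2))
  rec <- data.frame(deli = d, lame = l, y_bw = y[, 1L], y_bn = y[, 2L])
  # with diagonal trait covariances the bivariate model decouples
  vc <- varcomps(list(deli = diag(s_d), lame = diag(s_l)), s_e)
  fit <- solve_gca_bivariate(rec, K_d, K_l, vc)
  ZD <- diag(nD)[d, , drop = FALSE]
  ZL <- diag(nL)[l, , drop = FALSE]
  for (t in 1:2) {
    V <- s_d[t] * ZD %*% K_d %*% t(ZD) + s_l[t] * ZL %*% K_l %*% t(ZL) +
      diag(s_e[t], nr)
    Vi <- solve(V)
    X <- matrix(1, nr, 1L)
    mu <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y[, t])[1L, 1L]
    uD <- as.vector(s_d[t] * K_d %*% t(ZD) %*% Vi %*% (y[, t] - mu))
    uL <- as.vector(s_l[t] * K_l %*% t(ZL) %*% Vi %*% (y[, t] - mu))
    expect_equal(unname(fit$mu[t]), mu, tolerance = 1e-6)
    expect_equal(unname(fit$gca$deli[, t]), uD, tolerance = 1e-6)
    expect_equal(unname(fit$gca$lame[, t]), uL, tolerance = 1e-6)
  }
})

test_that("the single-relationship solver reproduces GLS on a dense kernel", {
  set.seed(32)
  n <- 25L
  H <- crossprod(matrix(rnorm(n * n), n)) / n + diag(n)
  ind <- sample.int(n, 15L)
  s_a <- c(2, 1.2); s_e <- c(1, 2)
  y <- cbind(rnorm(15L, 5), rnorm(15L, 8))
  rec <- data.frame(ind = ind, y_bw = y[, 1L], y_bn = y[, 2L])
  vc <- varcomps(list(a = diag(s_a)), s_e)
  fit <- solve_ssgblup_bivariate(rec, solve(H), vc, method = "dense")
  Z <- diag(n)[ind, , drop = FALSE]
  for (t in 1:2) {
    o <- gls_blup(y[, t], Z, H, s_a[t], s_e[t])
    expect_equal(unname(fit$mu[t]), o$mu, tolerance = 1e-6)
    expect_equal(unname(fit$a[, t]), o$u, tolerance = 1e-6)
  }
})

test_that("iterative and dense solutions of the single-step equations agree", {
  set.seed(33)
  ped <- random_pedigree(5L, 35L, seed = 33)
  n <- nrow(ped)
  ids <- sample(ped$id, 10L)
  M <- matrix(rbinom(10L * 100L, 2L, 0.35), 10L, 100L)
  Hinv <- h_inverse(a_inverse(ped), pedigree_A_subset(ped, ids),
                    vanraden_G(M), match(ids, ped$id))
  ind <- sample.int(n, 20L)
  rec <- data.frame(ind = ind, y_bw = rnorm(20L, 3), y_bn = rnorm(20L, 6))
  vc <- varcomps(list(a = matrix(c(1.5, -0.6, -0.6, 1.0), 2L)), c(1, 1.5))
  f1 <- solve_ssgblup_bivariate(rec, Hinv, vc, method = "dense")
  f2 <- solve_ssgblup_bivariate(rec, Hinv, vc, method = "pcg", tol = 1e-10)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-5)
  expect_equal(f1$a, f2$a, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("predicted cross value is the product of parental-mean trait values", {
  gd <- matrix(c(1, -0.5), 1L, 2L)
  gl <- matrix(c(0.5, 2), 1L, 2L)
  means <- c(bw = 15, bn = 15)
  expect_equal(unname(predict_cross_value(gd, gl, means)),
               (15 + 1 + 0.5) * (15 - 0.5 + 2))
})

test_that("EM-REML recovers simulated variance components with monotone likelihood", {
  set.seed(34)
  n <- 400L
  S <- matrix(c(2, -1, -1, 3), 2L)
  cs <- chol(S)
  U <- matrix(rnorm(2L * n), n, 2L) %*% cs
  E <- cbind(rnorm(n, 0, 1), rnorm(n, 0, sqrt(2)))
  y <- sweep(U + E, 2L, c(10, 20), "+")
  est <- estimate_varcomps_em(y, links = list(a = seq_len(n)),
                              kernels = list(a = diag(n)),
                              start = varcomps(list(a = diag(2)), c(1, 1)),
                              max_iter = 100L)
  Sa <- est$terms$a
  expect_gt(Sa[1, 1] / 2, 0.5); expect_lt(Sa[1, 1] / 2, 1.7)
  expect_gt(Sa[2, 2] / 3, 0.5); expect_lt(Sa[2, 2] / 3, 1.7)
  expect_lt(Sa[1, 2], 0)
  trace <- attr(est, "loglik")
  expect_true(all(diff(trace) > -1e-6))
})
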