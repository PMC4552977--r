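test_that("the numerator relationship matrix matches the classic full-sib example", {
  # 1 and 2 founders; 3 and 4 full sibs (1 x 2); 5 = 3 x 4
  ped <- data.frame(id = 1:5, sire = c(NA, NA, 1L, 1L, 3L),
                    dam = c(NA, NA, 2L, 2L, 4L))
  A <- pedigree_A(ped)
  expect_equal(unname(diag(A)[1:4]), rep(1, 4))
  expect_equal(A[1, 2], 0)
  expect_equal(A[3, 4], 0.5)
  expect_equal(A[1, 3], 0.5)
  expect_equal(A[1, 5], 0.5)
  expect_equal(A[5, 5], 1.25)          # F = 0.25 from a full-sib mating
  expect_equal(unname(attr(A, "F")[5]), 0.25)
  expect_equal(unname(pedigree_inbreeding(ped, 1:5)), unname(diag(A) - 1))
})

test_that("the sparse pedigree inverse is the exact inverse of A", {
  ped <- random_pedigree(6L, 40L, seed = 21)
  A <- pedigree_A(ped)
  Ai <- as.matrix(a_inverse(ped))
  expect_equal(unname(Ai %*% A), diag(nrow(ped)), tolerance = 1e-8)
})

test_that("the indirect subset method equals slicing the full A", {
  ped <- random_pedigree(5L, 60L, seed = 22)
  ids <- c(3L, 17L, 40L, 41L, 65L)
  A <- pedigree_A(ped)
  A22 <- pedigree_A_subset(ped, ids)
  expect_equal(unname(A22), unname(A[ids, ids]), tolerance = 1e-10)
})

test_that("the genomic relationship matrix matches its brute-force definition", {
  set.seed(23)
  M <- matrix(rbinom(20L * 60L, 2L, 0.4), 20L, 60L)
  G <- vanraden_G(M)
  p <- colMeans(M) / 2
  Z <- sweep(M, 2L, 2 * p)
  G0 <- (Z %*% t(Z)) / (2 * sum(p * (1 - p)))
  expect_equal(unname(G), unname(G0 / mean(diag(G0))), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mean(diag(G)), 1)
  # identical genotypes share the largest relationship with themselves
  M2 <- rbind(M, M[1L, ])
  G2 <- vanraden_G(M2)
  expect_equal(G2[1L, 21L], G2[1L, 1L])
})

test_that("the origin-aware G equals the explicit four-class construction", {
  set.seed(24)
  L <- 30L
  dd <- matrix(rbinom(4L * L, 2L, 0.5), 4L, L)
  dl <- matrix(rbinom(3L * L, 2L, 0.3), 3L, L)
  hg_d <- matrix(rbinom(2L * L, 1L, 0.5), 2L, L)
  hg_l <- matrix(rbinom(2L * L, 1L, 0.3), 2L, L)
  G <- origin_aware_G(dd, dl, hg_d, hg_l)
  # explicit class-dosage matrix: 1_Deli, 0_Deli, 1_LaMe, 0_LaMe
  zd <- matrix(0, 3L, L); zl <- matrix(0, 4L, L)
  M <- cbind(rbind(dd, zd, hg_d), rbind(2 - dd, zd, 1 - hg_d),
             rbind(zl, dl, hg_l), rbind(zl, 2 - dl, 1 - hg_l))
  p <- colMeans(M) / 2
  Z <- sweep(M, 2L, 2 * p)
  G0 <- (Z %*% t(Z)) / sum(p * (1 - p))
  expect_equal(unname(G), unname(G0 / mean(diag(G0))), tolerance = 1e-12,
               ignore_attr = TRUE)
  # every individual carries exactly two class alleles per locus
  expect_true(all(rowSums(M) == 2L * L))
})

test_that("the combined inverse reduces to the pedigree inverse when G equals A22", {
  ped <- random_pedigree(5L, 30L, seed = 25)
  ids <- c(10L, 20L, 30L, 35L)
  Ai <- a_inverse(ped)
  A22 <- pedigree_A_subset(ped, ids)
  H <- h_inverse(Ai, A22, G = A22, genotyped_index = ids, blend = 0)
  expect_equal(as.matrix(H), as.matrix(Ai), tolerance = 1e-8)
})

test_that("the structured combined inverse agrees with its dense form", {
  ped <- random_pedigree(5L, 30L, seed = 26)
  ids <- c(6L, 12L, 25L, 33L)
  Ai <- a_inverse(ped)
  A22 <- pedigree_A_subset(ped, ids)
  set.seed(27)
  M <- matrix(rbinom(length(ids) * 80L, 2L, 0.4), length(ids), 80L)
  G <- vanraden_G(M)
  H <- h_inverse(Ai, A22, G, ids, blend = 0.01)
  Hd <- as.matrix(H)
  x <- matrix(rnorm(nrow(ped) * 2L), ncol = 2L)
  expect_equal(hinv_mult(H, x), Hd %*% x, tolerance = 1e-10)
  expect_equal(hinv_diag(H), diag(Hd), tolerance = 1e-12)
  # dense check of the correction structure
  Gb <- 0.99 * G + 0.01 * A22
  corr <- solve(Gb) - solve(A22)
  Hd2 <- as.matrix(Ai)
  Hd2[ids, ids] <- Hd2[ids, ids] + corr
  expect_equal(Hd, Hd2, tolerance = 1e-6)
})

test_that("pedigrees with offspring listed before parents are rejected", {
  bad <- data.frame(id = 1:3, sire = c(2L, NA, NA), dam = c(3L, NA, NA))
  expect_error(validate_pedigree(bad), "parents-first")
  dup <- data.frame(id = c(1L, 1L), sire = c(NA, NA), dam = c(NA, NA))
  expect_error(validate_pedigree(dup), "duplicated")
})
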