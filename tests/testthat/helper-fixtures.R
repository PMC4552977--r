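# Shared toy fixture, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- make_toy_fixture("tiny", seed = 42)
  .fixture_cache$fx
}

# A small random pedigree with parents always preceding offspring.
random_pedigree <- function(n_founders, n_offspring, seed = 1) {
  set.seed(seed)
  n <- n_founders + n_offspring
  sire <- dam <- rep(NA_integer_, n)
  for (i in (n_founders + 1L):n) {
    p <- sample.int(i - 1L, 2L)
    sire[i] <- p[1L]; dam[i] <- p[2L]
  }
  data.frame(id = seq_len(n), sire = sire, dam = dam)
}

# Univariate GLS animal-model oracle: y = 1 mu + Z u + e with
# var(u) = s_u K, var(e) = s_e I. Returns mu and u computed from the
# closed-form BLUE/BLUP expressions, independently of the MME solvers.
gls_blup <- function(y, Z, K, s_u, s_e) {
  V <- s_u * (Z %*% K %*% t(Z)) + diag(s_e, length(y))
  Vi <- solve(V)
  X <- matrix(1, length(y), 1L)
  mu <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)[1L, 1L]
  u <- as.vector(s_u * K %*% t(Z) %*% Vi %*% (y - mu))
  list(mu = mu, u = u)
}
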