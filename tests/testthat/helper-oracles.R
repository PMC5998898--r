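# Independent reference implementations used as oracles. These deliberately
# take the slow, obvious route and never call the package's own fast path.

oracle_angdiff <- function(a, b) {
  vapply(seq_along(a), function(i) {
    d <- abs(a[i] - b[i]) %% 360
    min(d, 360 - d)
  }, numeric(1))
}

oracle_entropy <- function(p) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi)
  s
}

oracle_entropy_loss <- function(p0, probs) {
  h0 <- oracle_entropy(p0)
  hs <- numeric(nrow(probs))
  for (i in seq_len(nrow(probs))) hs[i] <- oracle_entropy(probs[i, ])
  h0 - mean(hs)
}

# naive mixture log-likelihood: double loop, densities by direct quadrature-
# normalized formula
oracle_mixture_loglik <- function(phi, psi, probs, params) {
  n <- length(phi)
  tot <- 0
  for (i in seq_len(n)) {
    fi <- 0
    for (k in seq_along(params)) {
      fi <- fi + probs[i, k] * dbvm(phi[i], psi[i], params[[k]])
    }
    tot <- tot + log(fi)
  }
  tot / n
}

# the printed pairwise renormalization formulas, evaluated literally
oracle_mix <- function(p, centers) {
  v <- as.numeric(p %*% centers)
  c0 <- v[1] / sqrt(v[1]^2 + v[2]^2)
  s0 <- v[2] / sqrt(v[1]^2 + v[2]^2)
  c1 <- v[3] / sqrt(v[3]^2 + v[4]^2)
  s1 <- v[4] / sqrt(v[3]^2 + v[4]^2)
  c(phi = atan2(s0, c0) * 180 / pi, psi = atan2(s1, c1) * 180 / pi)
}

# torus quadrature of an unnormalized or normalized density on an n x n
# midpoint grid (spectrally accurate for smooth periodic integrands)
torus_quadrature <- function(f, n = 512) {
  g <- seq(-180, 180, length.out = n + 1)[seq_len(n)]
  h <- 2 * pi / n
  sum(outer(g, g, f)) * h * h
}

# random unit-simplex rows
random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}
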