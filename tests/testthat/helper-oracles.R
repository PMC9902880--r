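# Independent oracles used across the suite. These deliberately take different
# computational routes than the package code they check.

# Exact minimum of total within-segment RSS + pen * (number of change points)
# by dynamic programming over all segmentations. Returns 0-based change frames
# (first frame of each later segment), like count_steps().
dp_optimal_changepoints <- function(x, pen) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) {
    s <- cs[b + 1] - cs[a]
    cs2[b + 1] - cs2[a] - s^2 / (b - a + 1)
  }
  F <- c(0, rep(Inf, n))
  prev <- integer(n + 1)
  for (b in 1:n) {
    for (a in 1:b) {
      v <- F[a] + segcost(a, b) + if (a > 1) pen else 0
      if (v < F[b + 1] - 1e-9) {
        F[b + 1] <- v
        prev[b + 1] <- a
      }
    }
  }
  cps <- integer(0)
  b <- n
  while (b > 0) {
    a <- prev[b + 1]
    if (a > 1) cps <- c(a - 1L, cps)
    b <- a - 1L
  }
  cps
}

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Numerical solve of the mass-action competitive surface equilibrium: find the
# free-site fraction such that theta_free + theta_target + theta_probe2 = 1
# with theta_target = (cT e / KT) theta_free, theta_probe2 = (c2/K2) theta_free.
equilibrium_oracle <- function(cT, KT, c2, K2, e = 1) {
  a <- if (cT > 0) cT * e / KT else 0
  b <- if (c2 > 0) c2 / K2 else 0
  f <- uniroot(function(tf) tf + a * tf + b * tf - 1, c(0, 1),
               tol = 1e-12)$root
  c(theta_target = a * f, theta_probe2 = b * f, theta_free = f)
}

# Fraction of a pixel-integrated Gaussian PSF centred at (x, y) falling in the
# aperture of radius r around the rounded centre pixel.
aperture_mass_oracle <- function(x, y, sigma, r) {
  x0 <- round(x); y0 <- round(y)
  w <- ceiling(r)
  total <- 0
  for (dy in -w:w) for (dx in -w:w) {
    if (sqrt(dx^2 + dy^2) <= r) {
      px <- x0 + dx; py <- y0 + dy
      mx <- pnorm((px + 0.5 - x) / sigma) - pnorm((px - 0.5 - x) / sigma)
      my <- pnorm((py + 0.5 - y) / sigma) - pnorm((py - 0.5 - y) / sigma)
      total <- total + mx * my
    }
  }
  total
}
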