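# Independent oracles used by the tests. These deliberately avoid the
# package's fitting code paths.

# Dense grid search for the 3-parameter decay: for every T2 on a fine
# grid, amplitude and offset are solved by linear least squares; the
# grid point with the smallest residual sum of squares wins.
# The amplitude and offset live on the same constrained domain as the
# package's solver (A >= 0, C >= 0); for this simple nonnegativity
# constraint the exact solution is the unconstrained optimum when it is
# feasible, else the best of the two boundary solutions (KKT).
grid_search_t2 <- function(signal, TEs, t2_grid = seq(1, 500, by = 0.1)) {
  B <- exp(-outer(TEs, t2_grid, "/"))          # decay basis per grid T2
  n <- length(TEs)
  ss <- sum(signal^2)
  s11 <- colSums(B^2)
  s12 <- colSums(B)
  b1 <- as.numeric(crossprod(B, signal))
  b2 <- sum(signal)
  det <- s11 * n - s12^2
  A <- (b1 * n - s12 * b2) / det               # closed-form 2x2 solve
  C <- (s11 * b2 - s12 * b1) / det
  rss <- ss - (A * b1 + C * b2)
  # boundary solutions where the interior optimum is infeasible
  A0 <- pmax(b1 / s11, 0)                      # C = 0
  rss_c0 <- ss - A0 * (2 * b1 - A0 * s11)
  C0 <- max(b2 / n, 0)                         # A = 0
  rss_a0 <- ss - C0 * (2 * b2 - C0 * n)
  infeasible <- A < 0 | C < 0
  rss[infeasible] <- pmin(rss_c0, rss_a0)[infeasible]
  t2_grid[which.min(rss)]
}

# Analytic mean of a Rician variate with underlying amplitude nu and
# channel sigma: sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2)),
# written via exponentially-scaled Bessel functions for stability.
rician_mean <- function(nu, sigma) {
  # E[M] = sigma sqrt(pi/2) e^{-x/2} [(1+x) I0(x/2) + x I1(x/2)],
  # x = nu^2 / (2 sigma^2); the e^{-x/2} cancels the Bessel scaling
  x <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}
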