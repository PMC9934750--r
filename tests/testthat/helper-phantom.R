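# Shared fixtures, built in code at test time.

# default dynamic time grid: 60 frames at 8.3 s
phantomTimes <- function(n = 60) (seq_len(n) - 1) * 8.3 / 60

# default synthetic AIF on that grid
testAIF <- function(times = phantomTimes()) {
  aifFromPlasma(populationAIF(times), times)
}

# a small phantom spec (24 x 24 x 3 grid, compact regions) for tests where
# the full default grid would be needlessly slow; same acquisition settings
smallPhantomSpec <- function(..., nPerRegion = 2L) {
  grid <- c(24L, 24L, 3L)
  m <- array(0L, grid)
  r <- seq_len(nPerRegion)
  m[4L + r, 4L + r, 1:2] <- 1L          # cancer
  m[4L + r, 14L + r, 1:2] <- 2L         # normal
  m[14L + r, 4L + r, 1:2] <- 3L         # false-positive candidate
  m[17:20, 17:20, 1L] <- 4L             # blood
  phantomSpec(gridShape = grid, regionMap = m, ...)
}

# brute-force trapezoidal convolution oracle on an refine-x finer grid:
# trapezoid rule applied to cp_lin(tau) * exp(-k (t - tau)), evaluated via
# the algebraically identical running form exp(-k t) * cumtrapz(cp e^{k tau})
# independent Newton-Raphson MLE for logistic regression, written against
# the log-likelihood directly
.logisticNewton <- function(X, y, iter = 200) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (i in seq_len(iter)) {
    eta <- as.vector(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- t(X1) %*% (X1 * W)
    g <- t(X1) %*% (y - p)
    beta <- beta + as.vector(solve(H + diag(1e-12, ncol(X1)), g))
    if (max(abs(g)) < 1e-12) break
  }
  beta
}

bruteConvolve <- function(cp, times, k, refine = 100) {
  nf <- (length(times) - 1) * refine + 1
  tf <- seq(times[1], times[length(times)], length.out = nf)
  cpf <- stats::approx(times, cp, tf)$y
  g <- cpf * exp(k * (tf - tf[1]))
  ct <- c(0, cumsum(diff(tf) * (g[-nf] + g[-1]) / 2))
  (ct * exp(-k * (tf - tf[1])))[seq(1, nf, by = refine)]
}
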