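test_that("expConvolve matches closed forms for degenerate and constant inputs", {
  t <- seq(0, 2, length.out = 61)
  expect_equal(expConvolve(rep(0, 61), t, 1.3), rep(0, 61))
  # constant input: int_0^t e^{-k(t-tau)} dtau = (1 - e^{-kt})/k
  out <- expConvolve(rep(1, 61), t, 0.5)
  expect_equal(out, (1 - exp(-0.5 * t)) / 0.5, tolerance = 1e-12)
  expect_identical(out[1], 0)
  # k = 0 reduces to the cumulative trapezoid integral
  cp <- populationAIF(phantomTimes())
  ct <- c(0, cumsum(diff(phantomTimes()) * (cp[-60] + cp[-1]) / 2))
  expect_equal(expConvolve(cp, phantomTimes(), 0), ct, tolerance = 1e-12)
  expect_error(expConvolve(cp, phantomTimes(), -0.1), "k must be")
  expect_error(expConvolve(cp, rev(phantomTimes()), 1), "increasing")
})

test_that("expConvolve agrees with a refined-grid trapezoidal oracle", {
  t <- phantomTimes()
  set.seed(101)
  for (i in 1:10) {
    k <- runif(1, 0.05, 0.8)
    cp <- populationAIF(t, scale = runif(1, 0.5, 2))
    ref <- bruteConvolve(cp, t, k, refine = 100)
    expect_lt(max(abs(expConvolve(cp, t, k) - ref)) / max(abs(ref)), 1e-6)
  }
  # faster washout rates against a finer reference (quadrature-converged)
  for (k in c(1.5, 3, 6)) {
    cp <- populationAIF(t)
    ref <- bruteConvolve(cp, t, k, refine = 1000)
    expect_lt(max(abs(expConvolve(cp, t, k) - ref)) / max(abs(ref)), 1e-6)
  }
  # non-uniform grids take the loop path; same answer as closed forms
  tn <- cumsum(c(0, runif(30, 0.05, 0.3)))
  out <- expConvolve(rep(1, 31), tn, 0.7)
  expect_equal(out, (1 - exp(-0.7 * tn)) / 0.7, tolerance = 1e-12)
})

test_that("Tofts forward curve follows the exponential-convolution form", {
  t <- seq(0, 2, length.out = 41)
  a <- list(cp = rep(1, 41), times = t)
  expect_equal(toftsForward(list(ktrans = 0, kep = 0.5), a), rep(0, 41))
  # constant cp = 1 mM, ktrans 0.2, kep 0.5: C(2) = 0.4 (1 - e^-1)
  out <- toftsForward(list(ktrans = 0.2, kep = 0.5), a)
  expect_equal(out[41], 0.4 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(out[41], 0.25285, tolerance = 1e-4)
  # linear in ktrans
  expect_equal(toftsForward(list(ktrans = 0.4, kep = 0.5), a), 2 * out,
               tolerance = 1e-14)
})

test_that("2TCM factored and two-term forms agree and nest the Tofts model", {
  t <- phantomTimes()
  aif <- testAIF(t)
  set.seed(7)
  for (i in 1:25) {
    p <- list(k1trans = runif(1, 0, 1), kep1 = runif(1, 0, 3),
              eps = runif(1, 0, 10), lam = runif(1, 0, 5))
    d <- max(abs(twoTCMForward(p, aif, "factored") -
                   twoTCMForward(p, aif, "two-term")))
    expect_lt(d, 1e-12)
  }
  # eps = 0: exactly the Tofts curve
  expect_equal(
    twoTCMForward(list(k1trans = 0.3, kep1 = 0.9, eps = 0, lam = 2), aif),
    toftsForward(list(ktrans = 0.3, kep = 0.9), aif), tolerance = 1e-14)
  # lam = 0: Tofts with amplitude (1 + eps) ktrans
  expect_equal(
    twoTCMForward(list(k1trans = 0.2, kep1 = 0.5, eps = 0.5, lam = 0), aif),
    toftsForward(list(ktrans = 0.3, kep = 0.5), aif), tolerance = 1e-13)
  # constant-input closed form via the lam = 0 reduction
  tc <- seq(0, 2, length.out = 41)
  out <- twoTCMForward(list(k1trans = 0.2, kep1 = 0.5, eps = 0.5, lam = 0),
                       list(cp = rep(1, 41), times = tc))
  expect_equal(out[41], 1.5 * 0.4 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(out[41], 0.37927, tolerance = 1e-4)
  expect_error(
    twoTCMForward(list(k1trans = 0.2, kep1 = 0.5, eps = 0.5, lam = -1), aif),
    "lam")
})

test_that("rmse is the root mean square of residuals", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0.01, -0.01, 0.01, -0.01), rep(0, 4)), 0.01)
  x <- c(0.3, 0.1, 0.7); y <- c(0.2, 0.4, 0.6)
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y))
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("canonical ordering keeps the larger amplitude as compartment 1", {
  can <- canonicalize2TCM(list(k1trans = 0.05, kep1 = 0.3,
                               k2trans = 0.20, kep2 = 1.1))
  expect_equal(can[c("k1trans", "kep1", "k2trans", "kep2")],
               list(k1trans = 0.20, kep1 = 1.1, k2trans = 0.05, kep2 = 0.3))
  expect_equal(can$ve1, 0.20 / 1.1)
  # idempotent
  expect_equal(canonicalize2TCM(can)[1:4], can[1:4])
  # already ordered input unchanged
  ok <- list(k1trans = 0.3, kep1 = 1.0, k2trans = 0.1, kep2 = 0.2)
  expect_equal(canonicalize2TCM(ok)[1:4], ok)
  # fit-space input: amplitudes eps * k1trans, rate kep1 + lam
  can2 <- canonicalize2TCM(list(k1trans = 0.05, kep1 = 0.2, eps = 5,
                                lam = 1.0))
  expect_equal(can2[1:4], list(k1trans = 0.25, kep1 = 1.2,
                               k2trans = 0.05, kep2 = 0.2))
  # equal amplitudes: the faster efflux rate takes the 1 label
  tie <- canonicalize2TCM(list(k1trans = 0.1, kep1 = 0.4,
                               k2trans = 0.1, kep2 = 1.5))
  expect_equal(tie$kep1, 1.5)
  expect_equal(tie$kep2, 0.4)
})

test_that("fitTofts inverts its own forward model and finds the global minimum", {
  aif <- testAIF()
  c <- toftsForward(list(ktrans = 0.3, kep = 0.8), aif)
  fit <- fitTofts(c, aif)
  expect_true(isConverged(fit))
  expect_equal(fitParams(fit)$ktrans, 0.3, tolerance = 1e-4)
  expect_equal(fitParams(fit)$kep, 0.8, tolerance = 1e-4)
  expect_equal(fitParams(fit)$ve, 0.3 / 0.8, tolerance = 1e-3)
  # all-zero curve: ktrans 0, rmse 0, no error
  z <- fitTofts(rep(0, 60), aif)
  expect_identical(fitParams(z)$ktrans, 0)
  expect_identical(fitRMSE(z), 0)
  expect_true(isConverged(z))
  # grid-search oracle: the LM minimum beats every node of a 200 x 200 grid
  kts <- seq(0, 1, length.out = 200)
  keps <- seq(0, 3, length.out = 200)
  sseGrid <- sapply(keps, function(ke) {
    conv <- expConvolve(aif@cpMM, aif@timesMin, ke)
    vapply(kts, function(kt) sum((c - kt * conv)^2), numeric(1))
  })
  best <- which(sseGrid == min(sseGrid), arr.ind = TRUE)[1, ]
  expect_lt(abs(fitParams(fit)$ktrans - kts[best[1]]), diff(kts[1:2]) * 1.5)
  expect_lt(abs(fitParams(fit)$kep - keps[best[2]]), diff(keps[1:2]) * 1.5)
  expect_lte(sum(fit@residuals^2), min(sseGrid) + 1e-12)
})

test_that("fit2TCM recovers true parameters and degrades gracefully to Tofts", {
  aif <- testAIF()
  # self-inversion at the cancer-like operating point
  truth <- list(k1trans = 0.25, kep1 = 1.2, k2trans = 0.05, kep2 = 0.2)
  c2 <- twoTCMForward(truth, aif, form = "two-term")
  fit <- fit2TCM(c2, aif)
  p <- fitParams(fit)
  for (nm in names(truth))
    expect_lt(abs(p[[nm]] / truth[[nm]] - 1), 0.01)
  expect_lt(fitRMSE(fit), 1e-6)
  # a pure Tofts process: canonical fast compartment reproduces it
  cT <- toftsForward(list(ktrans = 0.3, kep = 0.8), aif)
  tfit <- fitTofts(cT, aif)
  f2 <- fit2TCM(cT, aif, toftsFit = tfit)
  expect_lte(fitRMSE(f2), fitRMSE(tfit) + 1e-9)
  reproduces <- abs(fitParams(f2)$k1trans / 0.3 - 1) < 0.02 &&
    abs(fitParams(f2)$kep1 / 0.8 - 1) < 0.02
  degenerate <- abs(fitParams(f2)$lam) < 1e-3 ||
    fitParams(f2)$k2trans < 1e-3
  expect_true(reproduces || degenerate)
  # zero curve
  z <- fit2TCM(rep(0, 60), aif)
  expect_identical(fitParams(z)$k1trans, 0)
  expect_identical(fitRMSE(z), 0)
})
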