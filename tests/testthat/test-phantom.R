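test_that("population AIF is a nonnegative bolus with a known integral", {
  t <- phantomTimes()
  expect_identical(populationAIF(t, scale = 0), rep(0, 60))
  cp <- populationAIF(t)
  expect_identical(cp[1], 0)
  expect_true(all(cp >= 0 & is.finite(cp)))
  # single dominant peak after the bolus-arrival parameter
  expect_gt(t[which.max(cp)], 0.5)
  pk <- which.max(cp)
  expect_true(all(diff(cp[1:pk]) >= 0))
  expect_true(all(cp[pk:60] <= cp[pk]))
  expect_error(populationAIF(c(0, 2, 1)), "increasing")

  # trapezoid integral over [0, 8 min] vs the closed-form integral:
  # gamma-variate A s^alpha e^{-s/beta} integrates to
  #   A beta^(alpha+1) Gamma(alpha+1) pgamma(S/beta, alpha+1),
  # washout c (1 - e^{-s/tau}) to c (S - tau (1 - e^{-S/tau})), S = T - t0
  tt <- seq(0, 8, length.out = 4001)
  cpFine <- populationAIF(tt)
  trap <- sum(diff(tt) * (cpFine[-1] + cpFine[-length(tt)]) / 2)
  alpha <- 2; beta <- 0.12; t0 <- 0.5; peak <- 5; wAmp <- 1; wTau <- 0.5
  A <- peak / ((alpha * beta)^alpha * exp(-alpha))
  S <- 8 - t0
  closed <- A * beta^(alpha + 1) * gamma(alpha + 1) *
    pgamma(S / beta, alpha + 1) +
    wAmp * (S - wTau * (1 - exp(-S / wTau)))
  expect_lt(abs(trap / closed - 1), 0.005)
})

test_that("phantom synthesis is deterministic and respects the zero-noise limit", {
  spec <- smallPhantomSpec(noiseSd = 0, seed = 5L)
  ph <- buildPhantom(spec)
  # background voxels: constant signal over all frames
  bg <- which(ph$roiMasks == 0, arr.ind = TRUE)[1, ]
  sig <- ph$dynamic@signal[bg[1], bg[2], bg[3], ]
  expect_equal(sig, rep(sig[1], length(sig)))
  # and zero true concentration at all times
  expect_true(all(ph$groundTruth$concentration[bg[1], bg[2], bg[3], ] == 0))
  # determinism: same spec and seed -> bit-identical; new seed -> different
  phA <- buildPhantom(smallPhantomSpec(seed = 11L))
  phB <- buildPhantom(smallPhantomSpec(seed = 11L))
  phC <- buildPhantom(smallPhantomSpec(seed = 12L))
  expect_identical(phA$dynamic@signal, phB$dynamic@signal)
  expect_identical(phA$vfa@signal, phB$vfa@signal)
  expect_false(identical(phA$dynamic@signal, phC$dynamic@signal))
  # invalid noise settings are rejected
  expect_error(smallPhantomSpec(noiseSd = -1), "noiseSd")
  expect_error(smallPhantomSpec(noiseModel = "poisson"))
  # ground truth covers every non-background voxel with matching parameters
  gt <- ph$groundTruth$table
  expect_equal(nrow(gt), sum(ph$roiMasks > 0))
  expect_equal(unique(gt$k1trans[gt$label == 1]), 0.25)
  expect_equal(unique(gt$kep1[gt$label == 2]), 0.6)
})

test_that("acquisition defaults mirror the target protocol", {
  spec <- phantomSpec()
  expect_identical(spec@nFrames, 60L)
  expect_equal(spec@frameIntervalS, 8.3)
  expect_equal(spec@flipDeg, 10)
  expect_equal(spec@vfaAnglesDeg, c(3, 5, 10, 15, 20, 30))
  expect_equal(spec@hct, 0.42)
  ph <- buildPhantom(smallPhantomSpec())
  expect_equal(frameTimes(ph$dynamic)[2] * 60, 8.3)
  expect_identical(ph$dynamic@baselineFrames, 4L)  # 30 s bolus arrival
})

test_that("fitted-parameter error grows monotonically with noise level", {
  # single-curve replicate study through the signal chain: synthesize the
  # dynamic signal for a Tofts voxel, add noise, invert to concentration
  # with the true T1, fit, and measure the RMSE of ktrans across replicates
  t <- phantomTimes()
  aif <- testAIF(t)
  truth <- list(ktrans = 0.22, kep = 0.4)
  ct <- toftsForward(truth, aif)
  t10 <- 1.4
  sig <- spgrSignal(1000, 1 / (1 / t10 + 5.5 * ct), 4.6, 10)
  t1map <- new("T1Map", t1S = array(t10, c(1, 1, 1)),
               m0 = array(1000, c(1, 1, 1)),
               validMask = array(TRUE, c(1, 1, 1)))
  nrep <- 100
  set.seed(314)
  ktransRMSE <- sapply(c(0.5, 1.5, 4.5), function(sd) {
    errs <- replicate(nrep, {
      dyn <- new("DynamicSeries",
                 signal = array(sig + rnorm(60, 0, sd), c(1, 1, 1, 60)),
                 timesMin = t, trMs = 4.6, flipDeg = 10,
                 baselineFrames = 4L)
      cc <- as.vector(concentration(signalToConcentration(dyn, t1map)))
      if (anyNA(cc)) return(NA_real_)
      fitParams(fitTofts(cc, aif))$ktrans - truth$ktrans
    })
    sqrt(mean(errs^2, na.rm = TRUE))
  })
  expect_true(all(diff(ktransRMSE) > 0))
})

test_that("Rician noise matches the Gaussian limit at high SNR", {
  # same seed, both noise models, SNR > 20 throughout the dynamic range
  pg <- buildPhantom(smallPhantomSpec(noiseSd = 1, noiseModel = "gaussian",
                                      seed = 99L))
  pr <- buildPhantom(smallPhantomSpec(noiseSd = 1, noiseModel = "rician",
                                      seed = 99L))
  aif <- pg$groundTruth$aif
  t1map <- new("T1Map", t1S = pg$groundTruth$t10Map,
               m0 = array(1000, dim(pg$roiMasks)),
               validMask = array(TRUE, dim(pg$roiMasks)))
  fitOne <- function(ph, vox) {
    cc <- concentration(signalToConcentration(ph$dynamic, t1map))
    fitParams(fitTofts(cc[vox[1], vox[2], vox[3], ], aif))$ktrans
  }
  vox <- which(pg$roiMasks == 3, arr.ind = TRUE)[1, ]
  kg <- fitOne(pg, vox)
  kr <- fitOne(pr, vox)
  expect_lt(abs(kr / kg - 1), 0.02)
})
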