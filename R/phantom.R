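## Synthetic digital-phantom generator. Produces complete DCE-MRI studies
## (dynamic series, VFA series, ROI label masks, ground truth) with the
## statistical structure the analysis pipeline assumes: voxels governed by
## one fast plus one slow exchanging compartment, cancer regions with higher
## rate constants than normal tissue, a Tofts-like "false positive" region,
## and a blood region carrying the input function.

#' Population arterial input function
#'
#' A parametric bolus model: a gamma-variate first pass plus a saturating
#' washout/plateau term, both starting at the bolus arrival time `t0Min`:
#'
#' `Cp(t) = scale * [ A s^alpha exp(-s / beta) + washoutAmp (1 - exp(-s / washoutTau)) ]`
#'
#' with `s = max(t - t0Min, 0)` and `A` chosen so the gamma-variate peak
#' equals `gammaPeak` (mM). The curve is zero before arrival, rises to a
#' single dominant peak and decays toward a plateau.
#'
#' @param timesMin frame times (minutes), strictly increasing from 0.
#' @param scale overall multiplier (default 1).
#' @param shapeParams named list: `t0Min` bolus arrival (min, default 0.5),
#'   `alpha` gamma shape (default 2), `beta` gamma time scale (min, default
#'   0.12, peak `alpha*beta` after arrival), `gammaPeak` first-pass peak
#'   (mM, default 5), `washoutAmp` plateau level (mM, default 1),
#'   `washoutTau` plateau time constant (min, default 0.5).
#' @return plasma concentration (mM) on the time grid; `Cp(0) = 0`.
#' @export
populationAIF <- function(timesMin, scale = 1,
                          shapeParams = list()) {
  if (length(timesMin) > 1 && any(diff(timesMin) <= 0))
    stop("timesMin must be strictly increasing")
  p <- utils::modifyList(
    list(t0Min = 0.5, alpha = 2, beta = 0.12, gammaPeak = 5,
         washoutAmp = 1, washoutTau = 0.5), shapeParams)
  s <- pmax(timesMin - p$t0Min, 0)
  A <- p$gammaPeak / ((p$alpha * p$beta)^p$alpha * exp(-p$alpha))
  scale * (A * s^p$alpha * exp(-s / p$beta) +
             p$washoutAmp * (1 - exp(-s / p$washoutTau)))
}

#' Default region geometry for the digital phantom
#'
#' Lays out four rectangular regions on the first two slices of the grid:
#' label 1 = cancer, 2 = normal tissue, 3 = false-positive candidate tissue,
#' 4 = blood (input-function ROI, slice 1 only). The rest is background (0).
#'
#' @param gridShape integer (rows, cols, slices); needs at least 24 x 24 x 1.
#' @return integer 3D array of region labels.
#' @export
defaultRegionMap <- function(gridShape = c(32L, 32L, 3L)) {
  gridShape <- as.integer(gridShape)
  if (any(gridShape[1:2] < 24L)) stop("grid must be at least 24 x 24 in-plane")
  m <- array(0L, gridShape)
  sl <- seq_len(min(2L, gridShape[3]))
  m[5:10, 5:10, sl] <- 1L     # cancer
  m[5:10, 15:20, sl] <- 2L    # normal tissue
  m[15:20, 5:10, sl] <- 3L    # false-positive candidate
  m[16:19, 16:19, 1L] <- 4L   # blood / input function ROI
  m
}

#' Default per-region ground-truth kinetic records
#'
#' Cancer has a dominant fast plus a slow exchanging compartment; normal
#' tissue the same structure with lower rate constants throughout; the
#' false-positive region is a single-compartment (Tofts-like) tissue with a
#' transfer constant close to cancer's but no strong fast pool; the blood
#' region carries the input function itself. Rates in min^-1, T1 in seconds.
#'
#' @return named list keyed by region label.
#' @export
defaultRegionParams <- function() {
  list(
    "1" = list(model = "2tcm",
               params = c(k1trans = 0.25, kep1 = 1.2,
                          k2trans = 0.05, kep2 = 0.2),
               t10S = 1.4),
    "2" = list(model = "2tcm",
               params = c(k1trans = 0.08, kep1 = 0.6,
                          k2trans = 0.02, kep2 = 0.15),
               t10S = 1.4),
    "3" = list(model = "tofts",
               params = c(ktrans = 0.22, kep = 0.4),
               t10S = 1.4),
    "4" = list(model = "blood", params = numeric(0), t10S = 1.66))
}

#' Construct a phantom specification
#'
#' Defaults emulate the target acquisition: 60 dynamic frames at 8.3 s per
#' frame with a 10 degree flip angle and TR 4.6 ms, a six-angle VFA series
#' (3, 5, 10, 15, 20, 30 degrees) at TR 12 ms, hematocrit 0.42, bolus
#' arrival 30 s after the first frame, on a 32 x 32 x 3 grid.
#'
#' @param gridShape voxels per axis (rows, cols, slices).
#' @param regionMap integer label array; default [defaultRegionMap()].
#' @param regionParams per-region kinetic records; default
#'   [defaultRegionParams()].
#' @param backgroundT10S background T1 (s).
#' @param nFrames,frameIntervalS dynamic frame count and spacing (s).
#' @param trMs,flipDeg dynamic TR (ms) and flip angle (deg).
#' @param vfaAnglesDeg,vfaTrMs VFA angles (deg) and TR (ms).
#' @param m0 equilibrium signal (a.u.).
#' @param noiseSd noise standard deviation on the signal scale (a.u.).
#'   The default 1.5 is about 1 percent of the peak dynamic signal under the
#'   default settings (the SPGR signal at TR 4.6 ms / 10 degrees is a few
#'   percent of `m0`), giving a pre-contrast tissue SNR of roughly 20.
#' @param noiseModel "gaussian" (default) or "rician".
#' @param hct hematocrit used for the blood region.
#' @param relaxivityR1 contrast relaxivity (s^-1 mM^-1).
#' @param bolusArrivalS bolus arrival after the first frame (s).
#' @param aifParams population AIF shape overrides (see [populationAIF()]).
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(32L, 32L, 3L),
                        regionMap = defaultRegionMap(gridShape),
                        regionParams = defaultRegionParams(),
                        backgroundT10S = 1.0,
                        nFrames = 60L, frameIntervalS = 8.3,
                        trMs = 4.6, flipDeg = 10,
                        vfaAnglesDeg = c(3, 5, 10, 15, 20, 30),
                        vfaTrMs = 12,
                        m0 = 1000, noiseSd = 1.5,
                        noiseModel = c("gaussian", "rician"),
                        hct = 0.42, relaxivityR1 = 5.5,
                        bolusArrivalS = 30, aifParams = list(),
                        seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      regionMap = regionMap, regionParams = regionParams,
      backgroundT10S = backgroundT10S, nFrames = as.integer(nFrames),
      frameIntervalS = frameIntervalS, trMs = trMs, flipDeg = flipDeg,
      vfaAnglesDeg = vfaAnglesDeg, vfaTrMs = vfaTrMs, m0 = m0,
      noiseSd = noiseSd, noiseModel = noiseModel, hct = hct,
      relaxivityR1 = relaxivityR1, bolusArrivalS = bolusArrivalS,
      aifParams = aifParams, seed = as.integer(seed))
}

# run expr with the RNG seeded locally, restoring global RNG state after
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.addNoise <- function(x, sd, model) {
  if (sd == 0) return(x)
  if (model == "gaussian") {
    x + stats::rnorm(length(x), 0, sd)
  } else {
    sqrt((x + stats::rnorm(length(x), 0, sd))^2 +
           stats::rnorm(length(x), 0, sd)^2)
  }
}

#' Synthesize a complete DCE-MRI study from a phantom specification
#'
#' The forward chain runs ground-truth kinetics -> concentration C(t)
#' (via the kinetic forward models, or the blood curve Cb = Cp (1 - Hct)
#' for the blood region) -> longitudinal relaxation rate
#' `R1(t) = 1/T10 + r1 C(t)` -> SPGR signal at the dynamic acquisition
#' settings -> additive noise. The VFA series is synthesized from the same
#' T10 map and M0 at the VFA settings. Background voxels have zero
#' concentration at all times. The same spec and seed give bit-identical
#' output.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `dynamic` ([DynamicSeries-class]), `vfa`
#'   ([VFASeries-class]), `roiMasks` (integer label array = the region map),
#'   `groundTruth` (list: `table` data.frame with one row per non-background
#'   voxel, `t10Map` 3D array, `aif` [AIF-class], `concentration` 4D array
#'   of true C(t)), and `spec`.
#' @export
buildPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@gridShape
  nf <- spec@nFrames
  times <- (seq_len(nf) - 1) * spec@frameIntervalS / 60
  aifPar <- utils::modifyList(list(t0Min = spec@bolusArrivalS / 60),
                              spec@aifParams)
  cp <- populationAIF(times, shapeParams = aifPar)
  aif <- aifFromPlasma(cp, times, hct = spec@hct, source = "synthetic")
  labs <- sort(unique(as.vector(spec@regionMap)))
  labs <- labs[labs > 0]
  # per-region true concentration curves and T10
  regionCurve <- list()
  t10ByLab <- c("0" = spec@backgroundT10S)
  for (lab in labs) {
    rec <- spec@regionParams[[as.character(lab)]]
    regionCurve[[as.character(lab)]] <- switch(rec$model,
      tofts = toftsForward(as.list(rec$params), aif),
      "2tcm" = twoTCMForward(as.list(rec$params), aif, form = "two-term"),
      blood = aif@cbMM)
    t10ByLab[as.character(lab)] <- rec$t10S
  }
  nvox <- prod(d)
  labVec <- as.vector(spec@regionMap)
  concTrue <- matrix(0, nrow = nvox, ncol = nf)
  for (lab in labs) {
    w <- labVec == lab
    concTrue[w, ] <- matrix(regionCurve[[as.character(lab)]],
                            nrow = sum(w), ncol = nf, byrow = TRUE)
  }
  t10Vec <- unname(t10ByLab[as.character(labVec)])
  # signal synthesis
  r1t <- 1 / t10Vec + spec@relaxivityR1 * concTrue      # s^-1, nvox x nf
  dynClean <- spgrSignal(spec@m0, 1 / r1t, spec@trMs, spec@flipDeg)
  nAng <- length(spec@vfaAnglesDeg)
  vfaClean <- matrix(0, nrow = nvox, ncol = nAng)
  for (j in seq_len(nAng))
    vfaClean[, j] <- spgrSignal(spec@m0, t10Vec, spec@vfaTrMs,
                                spec@vfaAnglesDeg[j])
  noisy <- .withSeed(spec@seed, {
    list(dyn = .addNoise(dynClean, spec@noiseSd, spec@noiseModel),
         vfa = .addNoise(vfaClean, spec@noiseSd, spec@noiseModel))
  })
  # every frame acquired strictly before bolus arrival is pre-contrast
  baseline <- max(1L, min(nf - 1L, sum(times * 60 < spec@bolusArrivalS)))
  dyn <- new("DynamicSeries", signal = array(noisy$dyn, c(d, nf)),
             timesMin = times, trMs = spec@trMs, flipDeg = spec@flipDeg,
             baselineFrames = as.integer(baseline))
  vfa <- new("VFASeries", signal = array(noisy$vfa, c(d, nAng)),
             flipAnglesDeg = spec@vfaAnglesDeg, trMs = spec@vfaTrMs)
  # ground-truth table: one row per non-background voxel
  vox <- which(spec@regionMap > 0, arr.ind = TRUE)
  lin <- vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2]
  rows <- lapply(seq_len(nrow(vox)), function(i) {
    lab <- labVec[lin[i]]
    rec <- spec@regionParams[[as.character(lab)]]
    p <- as.list(rec$params)
    data.frame(row = vox[i, 1], col = vox[i, 2], slice = vox[i, 3],
               label = lab, model = rec$model,
               k1trans = p$k1trans %||% p$ktrans %||% NA_real_,
               kep1 = p$kep1 %||% p$kep %||% NA_real_,
               k2trans = p$k2trans %||% NA_real_,
               kep2 = p$kep2 %||% NA_real_,
               t10S = rec$t10S)
  })
  gtTable <- do.call(rbind, rows)
  list(dynamic = dyn, vfa = vfa, roiMasks = spec@regionMap,
       groundTruth = list(table = gtTable,
                          t10Map = array(t10Vec, d),
                          aif = aif,
                          concentration = array(concTrue, c(d, nf))),
       spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
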