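#' @import methods
NULL

.checkMonotoneTimes <- function(times) {
  if (length(times) < 2) return("needs at least 2 frame times")
  if (any(!is.finite(times))) return("frame times must be finite")
  if (any(diff(times) <= 0)) return("frame times must be strictly increasing")
  NULL
}

#' DynamicSeries: a 4D dynamic contrast-enhanced acquisition
#'
#' Holds the magnitude signal of a dynamic T1-weighted series as a 4D array
#' (row, col, slice, frame) together with the acquisition parameters needed to
#' convert signal into contrast-agent concentration.
#'
#' @slot signal 4D numeric array, arbitrary units.
#' @slot timesMin frame times in minutes, t = 0 at the first frame.
#' @slot trMs repetition time of the dynamic sequence (ms).
#' @slot flipDeg excitation flip angle of the dynamic sequence (degrees).
#' @slot baselineFrames number of pre-contrast frames at the start of the
#'   series, used for baseline signal calibration.
#' @export
setClass("DynamicSeries",
  slots = c(signal = "array", timesMin = "numeric", trMs = "numeric",
            flipDeg = "numeric", baselineFrames = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@signal)) != 4L)
      msgs <- c(msgs, "signal must be a 4D array (row, col, slice, frame)")
    else if (dim(object@signal)[4] != length(object@timesMin))
      msgs <- c(msgs, "4th dimension of signal must match length(timesMin)")
    m <- .checkMonotoneTimes(object@timesMin)
    if (!is.null(m)) msgs <- c(msgs, m)
    if (object@trMs <= 0) msgs <- c(msgs, "trMs must be positive")
    if (object@flipDeg <= 0 || object@flipDeg > 90)
      msgs <- c(msgs, "flipDeg must be in (0, 90]")
    if (object@baselineFrames < 1L ||
        object@baselineFrames >= length(object@timesMin))
      msgs <- c(msgs, "baselineFrames must be in [1, nFrames)")
    if (length(msgs)) msgs else TRUE
  })

#' VFASeries: a variable-flip-angle T1-mapping acquisition
#'
#' Spoiled gradient echo signals acquired at several flip angles with fixed TR,
#' stored as a 4D array (row, col, slice, angle).
#'
#' @slot signal 4D numeric array, last dimension indexes flip angles.
#' @slot flipAnglesDeg flip angles in degrees.
#' @slot trMs repetition time (ms).
#' @export
setClass("VFASeries",
  slots = c(signal = "array", flipAnglesDeg = "numeric", trMs = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@signal)) != 4L)
      msgs <- c(msgs, "signal must be a 4D array (row, col, slice, angle)")
    else if (dim(object@signal)[4] != length(object@flipAnglesDeg))
      msgs <- c(msgs, "4th dimension of signal must match flipAnglesDeg")
    a <- object@flipAnglesDeg
    if (length(unique(a)) < 2L)
      msgs <- c(msgs, "need at least 2 distinct flip angles")
    if (any(a <= 0 | a > 90)) msgs <- c(msgs, "flip angles must be in (0, 90]")
    if (object@trMs <= 0) msgs <- c(msgs, "trMs must be positive")
    if (length(msgs)) msgs else TRUE
  })

#' T1Map: voxelwise pre-contrast T1 and equilibrium magnetization
#'
#' @slot t1S T1 per voxel in seconds (3D array); NA where the fit failed.
#' @slot m0 equilibrium signal per voxel (3D array, arbitrary units).
#' @slot validMask logical 3D array flagging voxels with a successful fit.
#' @export
setClass("T1Map",
  slots = c(t1S = "array", m0 = "array", validMask = "array"),
  validity = function(object) {
    msgs <- character()
    d <- dim(object@t1S)
    if (length(d) != 3L) msgs <- c(msgs, "t1S must be a 3D array")
    if (!identical(dim(object@m0), d) || !identical(dim(object@validMask), d))
      msgs <- c(msgs, "t1S, m0, validMask must share dimensions")
    if (!is.logical(object@validMask))
      msgs <- c(msgs, "validMask must be logical")
    v <- object@validMask & !is.na(object@t1S)
    if (any(object@t1S[v] <= 0))
      msgs <- c(msgs, "t1S must be positive where valid")
    if (length(msgs)) msgs else TRUE
  })

#' ConcentrationSeries: voxelwise contrast-agent concentration over time
#'
#' @slot cMM concentration in mmol/L, 4D array (row, col, slice, frame);
#'   NA where the signal could not be inverted or the voxel had no valid T1.
#' @slot timesMin frame times in minutes.
#' @slot relaxivityR1 longitudinal relaxivity of the contrast agent used for
#'   the conversion (s^-1 mM^-1).
#' @slot baselineFrames number of pre-contrast frames averaged for the
#'   baseline signal.
#' @export
setClass("ConcentrationSeries",
  slots = c(cMM = "array", timesMin = "numeric", relaxivityR1 = "numeric",
            baselineFrames = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@cMM)) != 4L)
      msgs <- c(msgs, "cMM must be a 4D array")
    else if (dim(object@cMM)[4] != length(object@timesMin))
      msgs <- c(msgs, "4th dimension of cMM must match timesMin")
    m <- .checkMonotoneTimes(object@timesMin)
    if (!is.null(m)) msgs <- c(msgs, m)
    if (object@relaxivityR1 <= 0) msgs <- c(msgs, "relaxivityR1 must be > 0")
    if (length(msgs)) msgs else TRUE
  })

#' AIF: arterial input function
#'
#' Plasma concentration Cp(t) derived from a whole-blood concentration curve
#' Cb(t) through the hematocrit: Cp = Cb / (1 - Hct).
#'
#' @slot cpMM plasma concentration per frame (mM).
#' @slot cbMM whole-blood concentration per frame (mM).
#' @slot hct hematocrit fraction in [0, 1).
#' @slot timesMin frame times in minutes.
#' @slot source ROI identifier, or "synthetic" for a population curve.
#' @export
setClass("AIF",
  slots = c(cpMM = "numeric", cbMM = "numeric", hct = "numeric",
            timesMin = "numeric", source = "character"),
  validity = function(object) {
    msgs <- character()
    n <- length(object@timesMin)
    if (length(object@cpMM) != n || length(object@cbMM) != n)
      msgs <- c(msgs, "cpMM, cbMM, timesMin must share length")
    m <- .checkMonotoneTimes(object@timesMin)
    if (!is.null(m)) msgs <- c(msgs, m)
    if (object@hct < 0 || object@hct >= 1)
      msgs <- c(msgs, "hct must be in [0, 1)")
    if (any(!is.finite(object@cpMM)))
      msgs <- c(msgs, "cpMM must be finite")
    expected <- object@cbMM / (1 - object@hct)
    if (max(abs(object@cpMM - expected)) >
        1e-8 * max(1, max(abs(expected))))
      msgs <- c(msgs, "cpMM must equal cbMM / (1 - hct)")
    if (length(msgs)) msgs else TRUE
  })

#' KineticFit: result of a single-curve pharmacokinetic fit
#'
#' @slot model "tofts" or "2tcm".
#' @slot params named list of fitted parameters. Tofts: ktrans, kep, ve.
#'   2TCM (canonical): k1trans, kep1, k2trans, kep2, ve1, ve2.
#' @slot rmse root-mean-square error of the fitted curve (mM).
#' @slot converged optimizer convergence flag.
#' @slot nIter number of optimizer iterations of the winning start.
#' @slot residuals per-frame residuals, data minus fit (mM).
#' @slot fitted fitted concentration curve (mM).
#' @export
setClass("KineticFit",
  slots = c(model = "character", params = "list", rmse = "numeric",
            converged = "logical", nIter = "integer", residuals = "numeric",
            fitted = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (!object@model %in% c("tofts", "2tcm"))
      msgs <- c(msgs, "model must be 'tofts' or '2tcm'")
    if (length(object@rmse) != 1L || object@rmse < 0)
      msgs <- c(msgs, "rmse must be a single nonnegative number")
    if (length(object@residuals) != length(object@fitted))
      msgs <- c(msgs, "residuals and fitted must share length")
    if (length(msgs)) msgs else TRUE
  })

#' ParametricMaps: voxelwise kinetic parameter maps
#'
#' One 3D array per fitted parameter plus RMSE and convergence maps for each
#' fitted model. Unfitted voxels carry NA, never zero.
#'
#' @slot maps named list of 3D numeric arrays sharing the grid shape.
#' @slot fittedMask logical 3D array of voxels that were fitted.
#' @slot models character vector of fitted models ("tofts", "2tcm").
#' @export
setClass("ParametricMaps",
  slots = c(maps = "list", fittedMask = "array", models = "character"),
  validity = function(object) {
    msgs <- character()
    d <- dim(object@fittedMask)
    if (length(d) != 3L) msgs <- c(msgs, "fittedMask must be 3D")
    if (!is.logical(object@fittedMask))
      msgs <- c(msgs, "fittedMask must be logical")
    if (is.null(names(object@maps)) || any(names(object@maps) == ""))
      msgs <- c(msgs, "maps must be a named list")
    for (nm in names(object@maps))
      if (!identical(dim(object@maps[[nm]]), d))
        msgs <- c(msgs, sprintf("map '%s' does not share the grid shape", nm))
    if (!all(object@models %in% c("tofts", "2tcm")))
      msgs <- c(msgs, "models must be a subset of tofts/2tcm")
    if (length(msgs)) msgs else TRUE
  })

#' PhantomSpec: full description of a synthetic DCE-MRI study
#'
#' Defines the grid, tissue regions, ground-truth kinetic parameters, T1
#' values, acquisition settings and noise model from which
#' [buildPhantom()] synthesizes a complete study.
#'
#' @slot gridShape integer (rows, cols, slices).
#' @slot regionMap 3D integer array; 0 = background, >= 1 = tissue regions.
#' @slot regionParams named list keyed by region label (as character). Each
#'   entry is a list with fields `model` ("tofts", "2tcm" or "blood"),
#'   `params` (named numeric kinetic parameters, min^-1; empty for blood) and
#'   `t10S` (pre-contrast T1, seconds).
#' @slot backgroundT10S T1 of background voxels (seconds).
#' @slot nFrames number of dynamic frames.
#' @slot frameIntervalS temporal resolution (seconds per frame).
#' @slot trMs,flipDeg dynamic acquisition settings.
#' @slot vfaAnglesDeg,vfaTrMs variable-flip-angle acquisition settings.
#' @slot m0 equilibrium signal (arbitrary units).
#' @slot noiseSd signal-scale noise standard deviation (same units as m0).
#' @slot noiseModel "gaussian" or "rician".
#' @slot hct hematocrit used to derive blood from plasma concentration.
#' @slot relaxivityR1 contrast-agent relaxivity (s^-1 mM^-1).
#' @slot bolusArrivalS bolus arrival time after the first frame (seconds).
#' @slot aifParams named list of population AIF shape parameters
#'   (see [populationAIF()]).
#' @slot seed integer seed making the synthesis reproducible.
#' @export
setClass("PhantomSpec",
  slots = c(gridShape = "integer", regionMap = "array",
            regionParams = "list", backgroundT10S = "numeric",
            nFrames = "integer", frameIntervalS = "numeric",
            trMs = "numeric", flipDeg = "numeric",
            vfaAnglesDeg = "numeric", vfaTrMs = "numeric",
            m0 = "numeric", noiseSd = "numeric", noiseModel = "character",
            hct = "numeric", relaxivityR1 = "numeric",
            bolusArrivalS = "numeric", aifParams = "list",
            seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msgs <- c(msgs, "gridShape must be 3 positive integers")
    if (!identical(dim(object@regionMap), as.integer(object@gridShape)))
      msgs <- c(msgs, "regionMap dimensions must equal gridShape")
    labs <- sort(unique(as.vector(object@regionMap)))
    labs <- labs[labs > 0]
    for (lab in labs) {
      rec <- object@regionParams[[as.character(lab)]]
      if (is.null(rec)) {
        msgs <- c(msgs, sprintf("region %d lacks a kinetic record", lab))
        next
      }
      if (!rec$model %in% c("tofts", "2tcm", "blood"))
        msgs <- c(msgs, sprintf("region %d: unknown model '%s'", lab,
                                rec$model))
      if (!is.null(rec$params) && any(unlist(rec$params) < 0))
        msgs <- c(msgs, sprintf("region %d: rate constants must be >= 0", lab))
      if (is.null(rec$t10S) || rec$t10S <= 0)
        msgs <- c(msgs, sprintf("region %d: t10S must be positive", lab))
    }
    if (object@nFrames < 2L) msgs <- c(msgs, "nFrames must be >= 2")
    if (object@frameIntervalS <= 0)
      msgs <- c(msgs, "frameIntervalS must be positive")
    if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
    if (!object@noiseModel %in% c("gaussian", "rician"))
      msgs <- c(msgs, "noiseModel must be 'gaussian' or 'rician'")
    if (object@hct < 0 || object@hct >= 1)
      msgs <- c(msgs, "hct must be in [0, 1)")
    if (length(msgs)) msgs else TRUE
  })
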