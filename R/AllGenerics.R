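#' Frame times in minutes
#' @param x an object carrying a dynamic time grid
#' @return numeric vector of frame times (minutes, t = 0 at the first frame)
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Number of voxels along each spatial axis
#' @param x an object with a 3D/4D spatial grid
#' @return integer (rows, cols, slices)
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "DynamicSeries", function(x) x@timesMin)
#' @rdname frameTimes
#' @export
setMethod("frameTimes", "ConcentrationSeries", function(x) x@timesMin)
#' @rdname frameTimes
#' @export
setMethod("frameTimes", "AIF", function(x) x@timesMin)

#' @rdname gridShape
#' @export
setMethod("gridShape", "DynamicSeries",
          function(x) dim(x@signal)[1:3])
#' @rdname gridShape
#' @export
setMethod("gridShape", "ConcentrationSeries", function(x) dim(x@cMM)[1:3])
#' @rdname gridShape
#' @export
setMethod("gridShape", "T1Map", function(x) dim(x@t1S))
#' @rdname gridShape
#' @export
setMethod("gridShape", "ParametricMaps", function(x) dim(x@fittedMask))
#' @rdname gridShape
#' @export
setMethod("gridShape", "PhantomSpec", function(x) x@gridShape)

#' Plasma concentration curve of an AIF
#' @param x an [AIF-class] object
#' @return numeric vector, Cp(t) in mM
#' @export
plasmaConcentration <- function(x) {
  stopifnot(is(x, "AIF"))
  x@cpMM
}

#' Whole-blood concentration curve of an AIF
#' @param x an [AIF-class] object
#' @return numeric vector, Cb(t) in mM
#' @export
bloodConcentration <- function(x) {
  stopifnot(is(x, "AIF"))
  x@cbMM
}

#' Hematocrit of an AIF
#' @param x an [AIF-class] object
#' @return hematocrit fraction
#' @export
hematocrit <- function(x) {
  stopifnot(is(x, "AIF"))
  x@hct
}

#' T1 values of a T1 map
#' @param x a [T1Map-class] object
#' @return 3D array of T1 in seconds (NA where invalid)
#' @export
t1Seconds <- function(x) {
  stopifnot(is(x, "T1Map"))
  x@t1S
}

#' Valid-fit mask of a T1 map
#' @param x a [T1Map-class] object
#' @return logical 3D array
#' @export
validMask <- function(x) {
  stopifnot(is(x, "T1Map"))
  x@validMask
}

#' Concentration array of a ConcentrationSeries
#' @param x a [ConcentrationSeries-class] object
#' @return 4D array of concentrations in mM
#' @export
concentration <- function(x) {
  stopifnot(is(x, "ConcentrationSeries"))
  x@cMM
}

#' Extract one parametric map
#' @param x a [ParametricMaps-class] object
#' @param name map name, e.g. "ktrans", "k1trans", "rmse_tofts", "rmse_2tcm"
#' @return 3D numeric array (NA at unfitted voxels)
#' @export
paramMap <- function(x, name) {
  stopifnot(is(x, "ParametricMaps"))
  if (!name %in% names(x@maps))
    stop("no map named '", name, "'; available: ",
         paste(names(x@maps), collapse = ", "))
  x@maps[[name]]
}

#' Names of available parametric maps
#' @param x a [ParametricMaps-class] object
#' @return character vector
#' @export
paramMapNames <- function(x) {
  stopifnot(is(x, "ParametricMaps"))
  names(x@maps)
}

#' Fitted-voxel mask of a set of parametric maps
#' @param x a [ParametricMaps-class] object
#' @return logical 3D array
#' @export
fittedMask <- function(x) {
  stopifnot(is(x, "ParametricMaps"))
  x@fittedMask
}

#' Fitted parameters of a kinetic fit
#' @param x a [KineticFit-class] object
#' @return named list of parameters
#' @export
fitParams <- function(x) {
  stopifnot(is(x, "KineticFit"))
  x@params
}

#' RMSE of a kinetic fit
#' @param x a [KineticFit-class] object
#' @return root-mean-square error in mM
#' @export
fitRMSE <- function(x) {
  stopifnot(is(x, "KineticFit"))
  x@rmse
}

#' Convergence flag of a kinetic fit
#' @param x a [KineticFit-class] object
#' @return logical
#' @export
isConverged <- function(x) {
  stopifnot(is(x, "KineticFit"))
  x@converged
}

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@signal)
  cat(sprintf(
    "DynamicSeries: %dx%dx%d voxels, %d frames (%.1f s/frame)\n",
    d[1], d[2], d[3], d[4],
    if (d[4] > 1) diff(object@timesMin[1:2]) * 60 else NA_real_))
  cat(sprintf("  TR = %.2f ms, flip = %.1f deg, %d baseline frames\n",
              object@trMs, object@flipDeg, object@baselineFrames))
})

setMethod("show", "VFASeries", function(object) {
  d <- dim(object@signal)
  cat(sprintf("VFASeries: %dx%dx%d voxels, angles [%s] deg, TR = %.2f ms\n",
              d[1], d[2], d[3],
              paste(object@flipAnglesDeg, collapse = ", "), object@trMs))
})

setMethod("show", "T1Map", function(object) {
  cat(sprintf("T1Map: %s voxels, %d valid (%.1f%%)\n",
              paste(dim(object@t1S), collapse = "x"),
              sum(object@validMask),
              100 * mean(object@validMask)))
  v <- object@t1S[object@validMask]
  if (length(v))
    cat(sprintf("  T1 range %.3f - %.3f s\n", min(v), max(v)))
})

setMethod("show", "ConcentrationSeries", function(object) {
  d <- dim(object@cMM)
  cat(sprintf(
    "ConcentrationSeries: %dx%dx%d voxels, %d frames, r1 = %.2f /s/mM\n",
    d[1], d[2], d[3], d[4], object@relaxivityR1))
})

setMethod("show", "AIF", function(object) {
  cat(sprintf(
    "AIF (%s): %d frames, Hct = %.2f, peak Cp = %.2f mM at t = %.2f min\n",
    object@source, length(object@cpMM), object@hct, max(object@cpMM),
    object@timesMin[which.max(object@cpMM)]))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit [%s]: rmse = %.4g mM, converged = %s\n",
              object@model, object@rmse, object@converged))
  p <- unlist(object@params)
  cat("  ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "), "\n")
})

setMethod("show", "ParametricMaps", function(object) {
  cat(sprintf("ParametricMaps: %s grid, models: %s\n",
              paste(dim(object@fittedMask), collapse = "x"),
              paste(object@models, collapse = " + ")))
  cat(sprintf("  %d fitted voxels; maps: %s\n", sum(object@fittedMask),
              paste(names(object@maps), collapse = ", ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %s grid, %d frames x %.1f s, noise %s sd = %.3g, seed %d\n",
    paste(object@gridShape, collapse = "x"), object@nFrames,
    object@frameIntervalS, object@noiseModel, object@noiseSd, object@seed))
  labs <- names(object@regionParams)
  for (lab in labs) {
    rec <- object@regionParams[[lab]]
    cat(sprintf("  region %s [%s]: %s; T10 = %.2f s\n", lab, rec$model,
                if (length(rec$params))
                  paste(sprintf("%s=%.3g", names(rec$params),
                                unlist(rec$params)), collapse = ", ")
                else "(input curve)", rec$t10S))
  }
})
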