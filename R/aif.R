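## Arterial input function: extraction from a blood ROI and construction
## from explicit curves. Plasma concentration follows from whole-blood
## concentration through the hematocrit, Cp(t) = Cb(t) / (1 - Hct).

#' Construct an AIF from a whole-blood concentration curve
#'
#' @param cbMM whole-blood concentration per frame (mM).
#' @param timesMin frame times (minutes).
#' @param hct hematocrit fraction; default 0.42.
#' @param source provenance label.
#' @return an [AIF-class] with `cp = cb / (1 - hct)`.
#' @export
aifFromBlood <- function(cbMM, timesMin, hct = 0.42, source = "unknown") {
  if (hct < 0 || hct >= 1) stop("hct must be in [0, 1)")
  new("AIF", cpMM = cbMM / (1 - hct), cbMM = cbMM, hct = hct,
      timesMin = timesMin, source = source)
}

#' Construct an AIF directly from a plasma concentration curve
#'
#' The implied whole-blood curve is `cb = cp (1 - hct)`.
#'
#' @param cpMM plasma concentration per frame (mM).
#' @param timesMin frame times (minutes).
#' @param hct hematocrit fraction; default 0.42.
#' @param source provenance label; default "synthetic".
#' @return an [AIF-class].
#' @export
aifFromPlasma <- function(cpMM, timesMin, hct = 0.42, source = "synthetic") {
  if (hct < 0 || hct >= 1) stop("hct must be in [0, 1)")
  new("AIF", cpMM = cpMM, cbMM = cpMM * (1 - hct), hct = hct,
      timesMin = timesMin, source = source)
}

#' Extract an arterial input function from a blood ROI
#'
#' The whole-blood concentration is the unweighted voxelwise mean over the
#' ROI at each frame; the plasma concentration divides it by (1 - Hct).
#'
#' @param conc a [ConcentrationSeries-class].
#' @param bloodRoi voxel set: an n x 3 integer matrix of (row, col, slice)
#'   indices, or a logical/integer 3D array (nonzero = in ROI).
#' @param hct hematocrit fraction; default 0.42.
#' @param source provenance label for the returned AIF.
#' @return an [AIF-class].
#' @export
extractAIF <- function(conc, bloodRoi, hct = 0.42, source = "blood-roi") {
  stopifnot(is(conc, "ConcentrationSeries"))
  if (hct < 0 || hct >= 1) stop("hct must be in [0, 1)")
  vox <- .asVoxelMatrix(bloodRoi, gridShape(conc))
  if (nrow(vox) == 0L) stop("blood ROI is empty")
  d <- dim(conc@cMM)
  flat <- matrix(conc@cMM, nrow = prod(d[1:3]))
  lin <- vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2]
  curves <- flat[lin, , drop = FALSE]
  if (any(!is.finite(curves)))
    stop("blood ROI contains voxels with invalid concentration")
  cb <- colMeans(curves)
  aifFromBlood(cb, conc@timesMin, hct = hct, source = source)
}

# normalize a voxel-set argument to an n x 3 integer index matrix
.asVoxelMatrix <- function(roi, grid) {
  if (is.matrix(roi) && ncol(roi) == 3L) {
    vox <- matrix(as.integer(roi), ncol = 3L)
  } else if (is.array(roi) && length(dim(roi)) == 3L) {
    if (!identical(dim(roi), as.integer(grid)))
      stop("ROI array dimensions do not match the grid")
    vox <- which(roi != 0 & !is.na(roi), arr.ind = TRUE)
    storage.mode(vox) <- "integer"
  } else {
    stop("ROI must be an n x 3 index matrix or a 3D mask array")
  }
  if (nrow(vox) &&
      (any(vox < 1L) || any(vox[, 1] > grid[1]) ||
       any(vox[, 2] > grid[2]) || any(vox[, 3] > grid[3])))
    stop("ROI voxel indices fall outside the grid")
  vox
}
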