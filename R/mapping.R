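## Voxelwise fitting over ROI-bearing slices, parametric map assembly,
## ROI averaging and the false-positive ROI selection rule.

.emptyMaps <- function(grid, models) {
  nms <- character(0)
  if ("tofts" %in% models)
    nms <- c(nms, "ktrans", "kep", "ve", "rmse_tofts", "converged_tofts")
  if ("2tcm" %in% models)
    nms <- c(nms, "k1trans", "kep1", "k2trans", "kep2", "ve1", "ve2",
             "rmse_2tcm", "converged_2tcm")
  maps <- stats::setNames(
    lapply(nms, function(x) array(NA_real_, grid)), nms)
  new("ParametricMaps", maps = maps,
      fittedMask = array(FALSE, grid), models = models)
}

#' Fit kinetic models voxel by voxel and assemble parametric maps
#'
#' Fits every masked voxel on the listed slices. Maps are generated only for
#' those slices; voxels elsewhere, outside the mask, or without a finite
#' concentration curve carry NA. When `model = "2tcm"` the Tofts model is
#' fitted first for each voxel (it seeds the 2TCM multistart and guarantees
#' RMSE nesting), so both sets of maps are returned.
#'
#' @param conc a [ConcentrationSeries-class].
#' @param aif an [AIF-class] on the same time grid.
#' @param mask logical or integer 3D array of voxels to fit (nonzero = fit),
#'   or an n x 3 voxel index matrix.
#' @param slices integer slice indices to process; default: all slices that
#'   contain masked voxels.
#' @param model "tofts" or "2tcm" (the latter also yields the Tofts maps).
#' @return a [ParametricMaps-class].
#' @export
fitVolume <- function(conc, aif, mask, slices = NULL,
                      model = c("2tcm", "tofts")) {
  stopifnot(is(conc, "ConcentrationSeries"), is(aif, "AIF"))
  model <- match.arg(model)
  models <- if (model == "2tcm") c("tofts", "2tcm") else "tofts"
  grid <- gridShape(conc)
  vox <- .asVoxelMatrix(mask, grid)
  if (is.null(slices)) slices <- sort(unique(vox[, 3]))
  if (length(slices) == 0L) stop("slices must be nonempty")
  vox <- vox[vox[, 3] %in% slices, , drop = FALSE]
  out <- .emptyMaps(grid, models)
  if (nrow(vox) == 0L) {
    warning("no voxels to fit on the requested slices")
    return(out)
  }
  d <- dim(conc@cMM)
  flat <- matrix(conc@cMM, nrow = prod(d[1:3]))
  lin <- vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2]
  maps <- out@maps
  fitted <- array(FALSE, grid)
  nFit <- 0L
  for (i in seq_len(nrow(vox))) {
    curve <- flat[lin[i], ]
    if (any(!is.finite(curve))) next
    tf <- fitTofts(curve, aif)
    v <- lin[i]
    maps$ktrans[v] <- tf@params$ktrans
    maps$kep[v] <- tf@params$kep
    maps$ve[v] <- tf@params$ve
    maps$rmse_tofts[v] <- tf@rmse
    maps$converged_tofts[v] <- as.numeric(tf@converged)
    if ("2tcm" %in% models) {
      f2 <- fit2TCM(curve, aif, toftsFit = tf)
      maps$k1trans[v] <- f2@params$k1trans
      maps$kep1[v] <- f2@params$kep1
      maps$k2trans[v] <- f2@params$k2trans
      maps$kep2[v] <- f2@params$kep2
      maps$ve1[v] <- f2@params$ve1
      maps$ve2[v] <- f2@params$ve2
      maps$rmse_2tcm[v] <- f2@rmse
      maps$converged_2tcm[v] <- as.numeric(f2@converged)
    }
    fitted[v] <- TRUE
    nFit <- nFit + 1L
  }
  if (nFit == 0L) warning("no valid voxels could be fitted")
  out@maps <- maps
  out@fittedMask <- fitted
  out
}

#' Per-parameter mean over an ROI
#'
#' Arithmetic mean of each parametric map over the ROI voxels, ignoring
#' NA sentinels (unfitted voxels).
#'
#' @param maps a [ParametricMaps-class].
#' @param roi voxel set (n x 3 index matrix or 3D mask array).
#' @return named numeric vector of per-parameter means.
#' @export
roiMean <- function(maps, roi) {
  stopifnot(is(maps, "ParametricMaps"))
  grid <- gridShape(maps)
  vox <- .asVoxelMatrix(roi, grid)
  if (nrow(vox) == 0L) stop("ROI is empty")
  lin <- vox[, 1] + (vox[, 2] - 1L) * grid[1] +
    (vox[, 3] - 1L) * grid[1] * grid[2]
  if (!any(maps@fittedMask[lin]))
    stop("ROI lies entirely outside the fitted mask")
  vapply(maps@maps, function(m) mean(m[lin], na.rm = TRUE), numeric(1))
}

#' Select a false-positive ROI by the cancer-referenced cutoff rule
#'
#' High transfer-constant regions are not necessarily cancer. Given a nearby
#' cancer ROI, the cutoff is the cancer ROI's mean Ktrans minus
#' `sdMultiplier` times its (sample, n-1) standard deviation; candidate
#' voxels at or above the cutoff form the selected false-positive ROI, whose
#' mean Ktrans is therefore close to the cancer mean by construction.
#'
#' @param ktransMap 3D Ktrans map (min^-1).
#' @param cancerRoi voxel set of the reference cancer ROI (>= 2 voxels).
#' @param candidateRegion voxel set of candidate tissue, disjoint from the
#'   cancer ROI.
#' @param sdMultiplier number of standard deviations subtracted; default 1.
#' @return list with `voxels` (n x 3 matrix of selected voxels, possibly
#'   empty), `cutoff`, `cancerMean`, `cancerSd`.
#' @export
selectFalsePositiveROI <- function(ktransMap, cancerRoi, candidateRegion,
                                   sdMultiplier = 1) {
  grid <- dim(ktransMap)
  canc <- .asVoxelMatrix(cancerRoi, grid)
  cand <- .asVoxelMatrix(candidateRegion, grid)
  if (nrow(canc) < 2L) stop("cancer ROI needs >= 2 voxels for an SD")
  if (nrow(cand) == 0L) stop("candidate region is empty")
  linC <- canc[, 1] + (canc[, 2] - 1L) * grid[1] +
    (canc[, 3] - 1L) * grid[1] * grid[2]
  linQ <- cand[, 1] + (cand[, 2] - 1L) * grid[1] +
    (cand[, 3] - 1L) * grid[1] * grid[2]
  if (any(linQ %in% linC))
    stop("candidate region must be disjoint from the cancer ROI")
  kC <- ktransMap[linC]
  mu <- mean(kC, na.rm = TRUE)
  sd <- stats::sd(kC, na.rm = TRUE)
  cutoff <- mu - sdMultiplier * sd
  kQ <- ktransMap[linQ]
  keep <- !is.na(kQ) & kQ >= cutoff
  if (!any(keep))
    warning("no candidate voxel reaches the cutoff; empty ROI returned")
  list(voxels = cand[keep, , drop = FALSE], cutoff = cutoff,
       cancerMean = mu, cancerSd = sd)
}
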