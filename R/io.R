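## Format handling: NIfTI volumes through RNifti, AIF and ROI tables as CSV,
## phantom specifications as YAML.

#' Write a 3D/4D array as NIfTI
#' @param x numeric array.
#' @param path output path (".nii" or ".nii.gz").
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path path to a NIfTI file.
#' @return numeric array.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Export an AIF as a two-column CSV (time_min, cp_mM)
#' @param aif an [AIF-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeAIF <- function(aif, path) {
  stopifnot(is(aif, "AIF"))
  utils::write.csv(data.frame(time_min = aif@timesMin, cp_mM = aif@cpMM),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an AIF from a two-column CSV (time_min, cp_mM)
#' @param path CSV path.
#' @param hct hematocrit recorded with the curve; default 0.42.
#' @return an [AIF-class] (`cb` reconstructed as `cp (1 - hct)`).
#' @export
readAIF <- function(path, hct = 0.42) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  aifFromPlasma(df$cp_mM, df$time_min, hct = hct, source = path)
}

#' Read an ROI voxel list from CSV
#'
#' Expects columns `row`, `col`, `slice` (1-based voxel indices) and
#' optionally `label`.
#'
#' @param path CSV path.
#' @param label if given, keep only rows with this label.
#' @return n x 3 integer matrix of voxel indices.
#' @export
readROICSV <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("row", "col", "slice") %in% names(df)))
    stop("ROI CSV needs columns row, col, slice")
  if (!is.null(label)) df <- df[df$label == label, , drop = FALSE]
  as.matrix(df[, c("row", "col", "slice")])
}

#' Serialize a phantom specification to YAML
#'
#' All scalar fields and the per-region kinetic records go into the YAML
#' file; the region label map is written alongside as NIfTI and referenced
#' by relative filename.
#'
#' @param spec a [PhantomSpec-class].
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  mapFile <- paste0(sub("\\.ya?ml$", "", path), "_regions.nii.gz")
  writeVolume(spec@regionMap, mapFile)
  rp <- lapply(spec@regionParams, function(rec)
    list(model = rec$model, params = as.list(rec$params), t10S = rec$t10S))
  yaml::write_yaml(list(
    gridShape = as.integer(spec@gridShape),
    regionMapFile = basename(mapFile),
    regionParams = rp,
    backgroundT10S = spec@backgroundT10S,
    nFrames = spec@nFrames, frameIntervalS = spec@frameIntervalS,
    trMs = spec@trMs, flipDeg = spec@flipDeg,
    vfaAnglesDeg = spec@vfaAnglesDeg, vfaTrMs = spec@vfaTrMs,
    m0 = spec@m0, noiseSd = spec@noiseSd, noiseModel = spec@noiseModel,
    hct = spec@hct, relaxivityR1 = spec@relaxivityR1,
    bolusArrivalS = spec@bolusArrivalS, aifParams = spec@aifParams,
    seed = spec@seed), path)
  invisible(path)
}

#' Read a phantom specification from YAML
#' @param path YAML path written by [writePhantomSpec()].
#' @return a [PhantomSpec-class].
#' @export
readPhantomSpec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  mapFile <- file.path(dirname(path), y$regionMapFile)
  regionMap <- array(as.integer(round(readVolume(mapFile))),
                     as.integer(y$gridShape))
  rp <- lapply(y$regionParams, function(rec)
    list(model = rec$model, params = unlist(rec$params), t10S = rec$t10S))
  phantomSpec(gridShape = y$gridShape, regionMap = regionMap,
              regionParams = rp, backgroundT10S = y$backgroundT10S,
              nFrames = y$nFrames, frameIntervalS = y$frameIntervalS,
              trMs = y$trMs, flipDeg = y$flipDeg,
              vfaAnglesDeg = y$vfaAnglesDeg, vfaTrMs = y$vfaTrMs,
              m0 = y$m0, noiseSd = y$noiseSd, noiseModel = y$noiseModel,
              hct = y$hct, relaxivityR1 = y$relaxivityR1,
              bolusArrivalS = y$bolusArrivalS,
              aifParams = if (length(y$aifParams)) y$aifParams else list(),
              seed = y$seed)
}

#' Export parametric maps as one NIfTI file per parameter
#' @param maps a [ParametricMaps-class].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeParametricMaps <- function(maps, dir) {
  stopifnot(is(maps, "ParametricMaps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps@maps), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    writeVolume(maps@maps[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Dump per-voxel fitted parameters as a CSV table
#' @param maps a [ParametricMaps-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeVoxelTable <- function(maps, path) {
  stopifnot(is(maps, "ParametricMaps"))
  idx <- which(maps@fittedMask, arr.ind = TRUE)
  grid <- gridShape(maps)
  lin <- idx[, 1] + (idx[, 2] - 1L) * grid[1] +
    (idx[, 3] - 1L) * grid[1] * grid[2]
  df <- data.frame(row = idx[, 1], col = idx[, 2], slice = idx[, 3])
  for (nm in names(maps@maps)) df[[nm]] <- maps@maps[[nm]][lin]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
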