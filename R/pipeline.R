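## End-to-end pipeline: (optional) phantom synthesis -> T1 map ->
## concentration -> AIF -> voxelwise kinetic fits -> parametric maps ->
## ROI summaries and false-positive selection -> statistical report.
## A manifest records the configuration and seed; the same manifest
## reproduces every numeric output exactly.

#' Default pipeline configuration
#'
#' Phantom-mode configuration: synthesize the study from a
#' [phantomSpec()] (any fields in `phantom` override its defaults), then
#' analyze it. For patient-style data set `phantom = NULL` and provide
#' `paths` with `dynamic`, `vfa` and `roiMasks` NIfTI files plus acquisition
#' metadata.
#'
#' @param ... overrides merged into the default configuration.
#' @return a configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    phantom = list(),          # phantomSpec() overrides; NULL = file mode
    paths = list(),            # file mode: dynamic, vfa, roiMasks, aif
    relaxivityR1 = 5.5,        # s^-1 mM^-1
    hct = 0.42,
    baselineFrames = NULL,     # NULL = derived from bolus arrival
    model = "2tcm",            # fits Tofts too (nesting/init)
    sdMultiplier = 1,          # false-positive cutoff rule
    cancerLabel = 1L, normalLabel = 2L, fpCandidateLabel = 3L,
    bloodLabel = 4L,
    seed = 1L)
  utils::modifyList(cfg, list(...))
}

.statsReport <- function(maps, roiMasks, cfg) {
  grid <- gridShape(maps)
  lab <- as.vector(roiMasks)
  fitted <- as.vector(maps@fittedMask)
  get <- function(nm) as.vector(maps@maps[[nm]])
  report <- list()
  # paired t-test on voxelwise RMSE of the two models
  w <- fitted & !is.na(get("rmse_tofts")) & !is.na(get("rmse_2tcm"))
  if (sum(w) >= 2) {
    pt <- pairedTTest(get("rmse_tofts")[w], get("rmse_2tcm")[w])
    report$rmse <- list(
      toftsMean = mean(get("rmse_tofts")[w]),
      toftsSd = stats::sd(get("rmse_tofts")[w]),
      twotcmMean = mean(get("rmse_2tcm")[w]),
      twotcmSd = stats::sd(get("rmse_2tcm")[w]),
      pairedT = pt,
      nestedFraction = mean(get("rmse_2tcm")[w] <=
                              get("rmse_tofts")[w] + 1e-9))
  }
  isCan <- fitted & lab == cfg$cancerLabel
  isNorm <- fitted & lab == cfg$normalLabel
  # Pearson correlations between Tofts and 2TCM parameters (cancer voxels)
  if (sum(isCan) >= 3) {
    # degenerate (zero-variance) voxel sets, e.g. noiseless phantoms, have
    # no defined correlation; report NULL rather than fail
    safeCor <- function(x, y) tryCatch(pearsonR(x, y),
                                       error = function(e) NULL)
    report$correlation <- list(
      ktrans_vs_k1trans = safeCor(get("ktrans")[isCan],
                                  get("k1trans")[isCan]),
      kep_vs_kep1 = safeCor(get("kep")[isCan], get("kep1")[isCan]))
  }
  # false-positive ROI from the Ktrans map
  cancVox <- which(roiMasks == cfg$cancerLabel & maps@fittedMask,
                   arr.ind = TRUE)
  candVox <- which(roiMasks == cfg$fpCandidateLabel & maps@fittedMask,
                   arr.ind = TRUE)
  fpVox <- NULL
  if (nrow(cancVox) >= 2 && nrow(candVox) >= 1) {
    fp <- selectFalsePositiveROI(maps@maps$ktrans, cancVox, candVox,
                                 sdMultiplier = cfg$sdMultiplier)
    fpVox <- fp$voxels
    report$falsePositive <- list(cutoff = fp$cutoff,
                                 cancerMean = fp$cancerMean,
                                 cancerSd = fp$cancerSd,
                                 nSelected = nrow(fp$voxels))
  }
  # ANOVA + Tukey across tissue classes, per parameter
  fpLin <- if (!is.null(fpVox) && nrow(fpVox) >= 2)
    fpVox[, 1] + (fpVox[, 2] - 1L) * grid[1] +
      (fpVox[, 3] - 1L) * grid[1] * grid[2] else integer(0)
  pars <- intersect(c("ktrans", "kep", "k1trans", "kep1", "k2trans", "kep2"),
                    names(maps@maps))
  if (sum(isCan) >= 2 && sum(isNorm) >= 2) {
    report$anova <- lapply(stats::setNames(pars, pars), function(nm) {
      v <- c(get(nm)[isCan], get(nm)[isNorm])
      g <- c(rep("cancer", sum(isCan)), rep("normal", sum(isNorm)))
      if (length(fpLin) >= 2) {
        v <- c(v, maps@maps[[nm]][fpLin])
        g <- c(g, rep("false_positive", length(fpLin)))
      }
      anovaTukey(v, g)
    })
    # ROC cancer vs normal per parameter, plus combined logistic scores
    report$roc <- lapply(stats::setNames(pars, pars), function(nm)
      rocAUC(get(nm)[isCan], get(nm)[isNorm]))
    y <- c(rep(1, sum(isCan)), rep(0, sum(isNorm)))
    Xt <- cbind(ktrans = c(get("ktrans")[isCan], get("ktrans")[isNorm]),
                kep = c(get("kep")[isCan], get("kep")[isNorm]))
    report$combinedTofts <- logisticCombine(Xt, y)
    if (all(c("k1trans", "kep1", "k2trans", "kep2") %in% pars)) {
      X2 <- cbind(
        k1trans = c(get("k1trans")[isCan], get("k1trans")[isNorm]),
        kep1 = c(get("kep1")[isCan], get("kep1")[isNorm]),
        k2trans = c(get("k2trans")[isCan], get("k2trans")[isNorm]),
        kep2 = c(get("kep2")[isCan], get("kep2")[isNorm]))
      report$combined2TCM <- logisticCombine(X2, y)
    }
  }
  report
}

.roiSummary <- function(maps, roiMasks) {
  labs <- sort(unique(as.vector(roiMasks)))
  labs <- labs[labs > 0]
  rows <- lapply(labs, function(lab) {
    vox <- which(roiMasks == lab & maps@fittedMask, arr.ind = TRUE)
    if (nrow(vox) == 0) return(NULL)
    mns <- roiMean(maps, vox)
    cbind(data.frame(label = lab, nVoxels = nrow(vox)),
          as.data.frame(as.list(mns)))
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes phantom synthesis (phantom mode) or data loading (file mode),
#' VFA T1 mapping, signal-to-concentration conversion, AIF extraction from
#' the blood ROI, voxelwise Tofts and two-compartment fitting on the
#' ROI-bearing slices, parametric map and ROI-summary export, the
#' false-positive ROI rule, and the statistical report. Identical
#' configuration and seed give identical outputs.
#'
#' @param config configuration list from [pipelineConfig()], or a YAML path.
#' @param outDir output directory (created).
#' @return invisibly, a list with the in-memory results (`maps`, `aif`,
#'   `t1map`, `conc`, `roiSummary`, `stats`, `outDir`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- utils::modifyList(pipelineConfig(), yaml::read_yaml(config))
  }
  cfg <- config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$phantom)) {
    spec <- do.call(phantomSpec, utils::modifyList(
      list(seed = cfg$seed), cfg$phantom))
    ph <- buildPhantom(spec)
    dyn <- ph$dynamic; vfa <- ph$vfa; roiMasks <- ph$roiMasks
    writePhantomSpec(spec, file.path(outDir, "phantom_spec.yaml"))
    utils::write.csv(ph$groundTruth$table,
                     file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE)
    writeVolume(dyn@signal, file.path(outDir, "dynamic.nii.gz"))
    writeVolume(vfa@signal, file.path(outDir, "vfa.nii.gz"))
    writeVolume(roiMasks, file.path(outDir, "roi_masks.nii.gz"))
  } else {
    for (p in c("dynamic", "vfa", "roiMasks"))
      if (is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]]))
        stop("missing required input: paths$", p,
             if (!is.null(cfg$paths[[p]])) paste0(" (", cfg$paths[[p]], ")"))
    dynArr <- readVolume(cfg$paths$dynamic)
    meta <- cfg$acquisition
    if (is.null(meta))
      stop("file mode requires an 'acquisition' block ",
           "(timesMin, trMs, flipDeg, baselineFrames, vfaAnglesDeg, vfaTrMs)")
    dyn <- new("DynamicSeries", signal = dynArr, timesMin = meta$timesMin,
               trMs = meta$trMs, flipDeg = meta$flipDeg,
               baselineFrames = as.integer(meta$baselineFrames))
    vfa <- new("VFASeries", signal = readVolume(cfg$paths$vfa),
               flipAnglesDeg = meta$vfaAnglesDeg, trMs = meta$vfaTrMs)
    roiMasks <- array(as.integer(round(readVolume(cfg$paths$roiMasks))),
                      dim(dynArr)[1:3])
  }
  # T1 mapping restricted to labeled voxels plus the blood ROI
  anyRoi <- roiMasks > 0
  t1map <- fitVFAT1(vfa, mask = anyRoi)
  conc <- signalToConcentration(
    dyn, t1map, relaxivityR1 = cfg$relaxivityR1,
    baselineFrames = if (is.null(cfg$baselineFrames)) dyn@baselineFrames
                     else cfg$baselineFrames)
  aif <- if (!is.null(cfg$paths$aif)) readAIF(cfg$paths$aif, hct = cfg$hct)
         else extractAIF(conc, roiMasks == cfg$bloodLabel, hct = cfg$hct)
  writeAIF(aif, file.path(outDir, "aif.csv"))
  writeVolume(ifelse(is.na(t1map@t1S), -1, t1map@t1S),
              file.path(outDir, "t1map.nii.gz"))
  tissueMask <- anyRoi & roiMasks != cfg$bloodLabel
  maps <- fitVolume(conc, aif, tissueMask, model = cfg$model)
  writeParametricMaps(maps, file.path(outDir, "maps"))
  writeVoxelTable(maps, file.path(outDir, "voxel_fits.csv"))
  roiSummary <- .roiSummary(maps, roiMasks)
  utils::write.csv(roiSummary, file.path(outDir, "roi_summary.csv"),
                   row.names = FALSE)
  statsRep <- .statsReport(maps, roiMasks, cfg)
  jsonlite::write_json(statsRep, file.path(outDir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    package = "dce2tcm",
    version = as.character(utils::packageVersion("dce2tcm")),
    config = cfg, seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(maps = maps, aif = aif, t1map = t1map, conc = conc,
                 roiSummary = roiSummary, stats = statsRep,
                 outDir = outDir))
}
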