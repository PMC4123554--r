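# End-to-end pipeline and the phantom evaluation driver.

#' Pipeline configuration
#'
#' All defaults are the method's standard parameters: 15 mm anterior shift,
#' 10 x 10 mm patch averaging, pattern width 15 mm with exponent n = 10,
#' a local search range of 20\% of the scaled generic distance, and the
#' 40\%-of-median fallback rule.
#'
#' @param contrast \code{"t1"} or \code{"t2"}.
#' @param shiftMm anterior shift of the centerline (mm).
#' @param patchLrMm,patchApMm averaging patch extents (mm).
#' @param patternWidthMm,patternN disk-pattern parameters.
#' @param searchFraction,fallbackFraction detection fractions in (0, 1).
#' @param stepMm profile sampling step (mm).
#' @param templatePath optional CSV template path; the packaged phantom
#'   template is used when NULL.
#' @param startLevel optional vertebral level (name or index) of the first
#'   visible disk's upper vertebra when C2 is outside the field of view;
#'   requires \code{startPositionMm}.
#' @param startPositionMm profile position of that first disk (mm).
#' @param seed optional integer seed recorded with outputs.
#' @return a validated named list.
#' @export
pipelineConfig <- function(contrast = "t2", shiftMm = 15, patchLrMm = 10,
                           patchApMm = 10, patternWidthMm = 15,
                           patternN = 10L, searchFraction = 0.2,
                           fallbackFraction = 0.4, stepMm = 1,
                           templatePath = NULL, startLevel = NULL,
                           startPositionMm = NULL, seed = NULL) {
  contrast <- match.arg(contrast, c("t1", "t2"))
  stopifnot(shiftMm >= 0, patchLrMm > 0, patchApMm > 0, patternWidthMm > 0,
            patternN >= 1, stepMm > 0,
            searchFraction > 0, searchFraction < 1,
            fallbackFraction > 0, fallbackFraction < 1)
  if (!is.null(startLevel) && is.null(startPositionMm))
    stop("startLevel requires startPositionMm")
  list(contrast = contrast, shiftMm = shiftMm, patchLrMm = patchLrMm,
       patchApMm = patchApMm, patternWidthMm = patternWidthMm,
       patternN = as.integer(patternN), searchFraction = searchFraction,
       fallbackFraction = fallbackFraction, stepMm = stepMm,
       templatePath = templatePath, startLevel = startLevel,
       startPositionMm = startPositionMm, seed = seed)
}

.stage <- function(name, expr, hint = NULL) {
  tryCatch(expr, error = function(e) {
    msg <- sprintf("[%s] %s", name, conditionMessage(e))
    if (!is.null(hint)) msg <- paste0(msg, " (", hint, ")")
    stop(msg, call. = FALSE)
  })
}

.resolveTemplate <- function(config) {
  if (is.null(config$templatePath)) defaultPhantomTemplate()
  else readDiskTemplate(config$templatePath)
}

# In-memory pipeline on already-loaded objects; returns all intermediates.
.runPipeline <- function(volume, centerline, config, template,
                         verbose = FALSE) {
  shifted <- .stage("shift", shiftCenterlineAnterior(centerline, config$shiftMm))
  prof <- .stage("sample",
                 sampleProfile(volume, shifted, config$patchLrMm,
                               config$patchApMm, config$stepMm))
  det <- .stage("detrend", detrendProfile(prof))
  norm <- .stage("normalize", normalizeProfile(det))
  pattern <- makePattern(config$patternWidthMm, config$patternN, config$stepMm)
  start <- if (is.null(config$startLevel)) "auto"
           else list(level = config$startLevel,
                     positionMm = config$startPositionMm)
  dets <- .stage("detect",
                 detectAllDisks(norm, template, pattern, start = start,
                                searchFraction = config$searchFraction,
                                fallbackFraction = config$fallbackFraction,
                                verbose = verbose),
                 hint = "supply startLevel/startPositionMm when C2 is not in the FOV")
  proj <- .stage("project", projectDisks(dets, centerline))
  lc <- .stage("label", labelCenterline(centerline, proj))
  list(profile = norm, detections = dets, projected = proj, labeled = lc)
}

#' Run the full labeling pipeline on files
#'
#' Reads the volume and centerline, executes centerline shift, profile
#' sampling, detrending, normalization, first-disk detection (or the
#' user-start path), peak normalization, sequential disk detection,
#' projection and labeling, and writes all outputs to \code{outDir}:
#' labeled centerline NIfTI, labeled cord-surface NIfTI (when the
#' centerline input was a mask), detections CSV, disk label-point NIfTI,
#' evaluation-ready detections, and the resolved configuration JSON. Any
#' stage failure is reported with the stage name.
#'
#' @param volumePath NIfTI volume path.
#' @param centerlinePath centerline path (NIfTI cord mask or x-y-z text).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory.
#' @param verbose log each detection decision.
#' @return invisibly, a list with the pipeline intermediates and the output
#'   paths.
#' @export
runLabel <- function(volumePath, centerlinePath, config = pipelineConfig(),
                     outDir, verbose = TRUE) {
  t0 <- Sys.time()
  polarity <- if (config$contrast == "t1") "t1_like" else "t2_like"
  volume <- .stage("read_volume", readVolume(volumePath, polarity))
  isMask <- grepl("\\.nii(\\.gz)?$", centerlinePath)
  cordMask <- NULL
  if (isMask) {
    cordMask <- .stage("read_centerline", readVolume(centerlinePath))
    centerline <- .stage("centerline", centerlineFromMask(cordMask))
  } else {
    centerline <- .stage("read_centerline", readCenterline(centerlinePath))
  }
  template <- .stage("template", .resolveTemplate(config))
  res <- .runPipeline(volume, centerline, config, template, verbose = verbose)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(detections = file.path(outDir, "detections.csv"),
                labeledCenterline = file.path(outDir, "labeled_centerline.nii.gz"),
                diskPoints = file.path(outDir, "disk_labels.nii.gz"),
                config = file.path(outDir, "config.json"))
  utils::write.csv(cbind(res$projected,
                         max_corr = res$detections@detections$max_corr),
                   paths$detections, row.names = FALSE)
  # labeled centerline volume: each centerline sample's voxel gets its label
  lcArr <- array(0, dim = dim(volume@imageData))
  ci <- round(sweep(res$labeled@centerline@coords, 2, volume@voxelMm, `/`)) + 1
  ok <- ci[, 1] >= 1 & ci[, 1] <= dim(lcArr)[1] &
        ci[, 2] >= 1 & ci[, 2] <= dim(lcArr)[2] &
        ci[, 3] >= 1 & ci[, 3] <= dim(lcArr)[3]
  lcArr[ci[ok, , drop = FALSE]] <- res$labeled@labels[ok]
  writeVolume(new("SpineVolume", imageData = lcArr, voxelMm = volume@voxelMm,
                  polarity = polarity), paths$labeledCenterline)
  writeDiskLabelVolume(res$detections, volume, paths$diskPoints)
  if (!is.null(cordMask)) {
    paths$labeledSurface <- file.path(outDir, "labeled_surface.nii.gz")
    writeVolume(labelSurface(cordMask, res$labeled), paths$labeledSurface)
  }
  jsonlite::write_json(config[!vapply(config, is.null, logical(1))],
                       paths$config, auto_unbox = TRUE, digits = NA)
  if (verbose)
    message(sprintf("labeled %d disks in %.1f s",
                    length(res$detections),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(c(res, list(paths = paths)))
}

#' Run a phantom labeling experiment
#'
#' Generates \code{nVolumes} phantoms of the requested contrast (per-volume
#' seeds derived from the master seed), runs the full in-memory pipeline on
#' each, scores it against the phantom ground truth and aggregates: mean
#' all-or-nothing accuracy, pooled per-level absolute errors, and fallback
#' counts. With \code{artifact = TRUE} each phantom carries a 90\%
#' signal-dropout slab over vertebral levels C4-C6, emulating a metallic
#' implant.
#'
#' @param nVolumes number of phantoms.
#' @param contrast \code{"t1"} or \code{"t2"}.
#' @param artifact simulate the three-level dropout artifact.
#' @param seed master integer seed.
#' @param config a \code{\link{pipelineConfig}}.
#' @param phantomArgs named list of overrides for
#'   \code{\link{defaultPhantomConfig}}.
#' @return list with \code{accuracy_pct} (mean across volumes),
#'   \code{mae_mm}, \code{sd_mm} (pooled across levels and volumes),
#'   \code{errors_mm} (all per-level errors), \code{nFallback}, and
#'   \code{perVolume} (per-volume summaries).
#' @export
runExperiment <- function(nVolumes, contrast = "t2", artifact = FALSE,
                          seed = 1L, config = pipelineConfig(contrast = contrast),
                          phantomArgs = list()) {
  polarity <- if (config$contrast == "t1") "t1_like" else "t2_like"
  template <- .resolveTemplate(config)
  perVolume <- vector("list", nVolumes)
  errors <- numeric()
  for (i in seq_len(nVolumes)) {
    args <- utils::modifyList(list(
      polarity = polarity, seed = as.integer(seed * 100 + i)), phantomArgs)
    if (artifact)
      args <- utils::modifyList(list(dropoutLevels = 4:6,
                                     dropoutAttenuation = 0.9), args)
    ph <- generatePhantom(do.call(defaultPhantomConfig, args))
    centerline <- centerlineFromMask(ph$cordMask)
    res <- .runPipeline(ph$volume, centerline, config, template)
    ev <- evaluateLabeling(res$projected, ph$truth)
    nf <- sum(res$detections@detections$mode == "template_fallback")
    perVolume[[i]] <- list(accuracy_pct = ev$accuracy_pct,
                           mae_mm = ev$mae_mm, nFallback = nf,
                           perLevel = ev$perLevel)
    errors <- c(errors, ev$perLevel$error_mm)
  }
  acc <- vapply(perVolume, `[[`, numeric(1), "accuracy_pct")
  list(accuracy_pct = mean(acc), mae_mm = mean(errors),
       sd_mm = stats::sd(errors), errors_mm = errors,
       nFallback = sum(vapply(perVolume, `[[`, numeric(1), "nFallback")),
       perVolume = perVolume)
}
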