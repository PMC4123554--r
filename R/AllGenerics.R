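#' @rdname SpineVolume-class
#' @param object,x an object.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname SpineVolume-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname SpineVolume-class
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))
#' @rdname Centerline-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname Centerline-class
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))
#' @rdname IntensityProfile-class
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname IntensityProfile-class
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname IntensityProfile-class
#' @export
setGeneric("sourceCoords", function(x) standardGeneric("sourceCoords"))
#' @rdname DiskTemplate-class
#' @export
setGeneric("templateGaps", function(x) standardGeneric("templateGaps"))
#' @rdname DiskDetections-class
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))
#' @rdname LabeledCenterline-class
#' @export
setGeneric("vertebraLabels", function(x) standardGeneric("vertebraLabels"))

#' @rdname SpineVolume-class
setMethod("imageData", "SpineVolume", function(x) x@imageData)
#' @rdname SpineVolume-class
setMethod("voxelSize", "SpineVolume", function(x) x@voxelMm)
#' @rdname SpineVolume-class
setMethod("polarity", "SpineVolume", function(x) x@polarity)
#' @rdname IntensityProfile-class
setMethod("polarity", "IntensityProfile", function(x) x@polarity)
#' @rdname Centerline-class
setMethod("coords", "Centerline", function(x) x@coords)
#' @rdname Centerline-class
setMethod("arcLength", "Centerline", function(x) x@arcLengthMm)
#' @rdname IntensityProfile-class
setMethod("profileValues", "IntensityProfile", function(x) x@values)
#' @rdname IntensityProfile-class
setMethod("profilePositions", "IntensityProfile", function(x) x@positionsMm)
#' @rdname IntensityProfile-class
setMethod("sourceCoords", "IntensityProfile", function(x) x@sourceCoords)
#' @rdname DiskTemplate-class
setMethod("templateGaps", "DiskTemplate", function(x) x@gaps)
#' @rdname DiskDetections-class
setMethod("detections", "DiskDetections", function(x) x@detections)
#' @rdname LabeledCenterline-class
setMethod("vertebraLabels", "LabeledCenterline", function(x) x@labels)
#' @rdname LabeledCenterline-class
setMethod("coords", "LabeledCenterline", function(x) x@centerline@coords)

#' @rdname DiskDetections-class
#' @param row.names,optional passed on for the data.frame contract.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "DiskDetections",
  function(x, row.names = NULL, optional = FALSE, ...) x@detections)
#' @rdname DiskTemplate-class
setMethod("as.data.frame", "DiskTemplate",
  function(x, row.names = NULL, optional = FALSE, ...) x@gaps)
#' @rdname DiskDetections-class
setMethod("length", "DiskDetections", function(x) nrow(x@detections))

setMethod("show", "SpineVolume", function(object) {
  d <- dim(object@imageData)
  cat(sprintf("SpineVolume: %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %s\n",
              d[1], d[2], d[3], object@voxelMm[1], object@voxelMm[2],
              object@voxelMm[3], object@polarity))
})
setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d points, length %.1f mm (rostral to caudal)\n",
              nrow(object@coords), max(object@arcLengthMm)))
})
setMethod("show", "IntensityProfile", function(object) {
  st <- if (length(object@positionsMm) > 1L) diff(object@positionsMm[1:2]) else NA
  cat(sprintf(
    "IntensityProfile: %d samples, step %.3g mm, span %.1f mm, %s (%d missing)\n",
    length(object@values), st, diff(range(object@positionsMm)),
    object@polarity, sum(is.na(object@values))))
})
setMethod("show", "DiskTemplate", function(object) {
  g <- object@gaps
  cat(sprintf("DiskTemplate: %d gaps (%s to %s)\n", nrow(g),
              diskPairName(g$upper_level[1]),
              diskPairName(g$upper_level[nrow(g)])))
  print(g, row.names = FALSE)
})
setMethod("show", "DiskDetections", function(object) {
  d <- object@detections
  cat(sprintf("DiskDetections: %d disks, %d by correlation, %d by template fallback\n",
              nrow(d), sum(d$mode == "correlated"),
              sum(d$mode == "template_fallback")))
  print(d, row.names = FALSE, digits = 4)
})
setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf(
    "PhantomConfig: FOV %s mm, %d disks (%s..%s), %s, contrast %.3g, noise SD %.3g, seed %d\n",
    paste(object@fovMm, collapse = "x"), length(object@diskPositionsMm),
    levelName(object@firstDiskLevel),
    levelName(object@firstDiskLevel + length(object@diskPositionsMm)),
    object@polarity, object@diskContrast, object@noiseSd, object@seed))
})
setMethod("show", "LabeledCenterline", function(object) {
  lv <- range(object@labels)
  cat(sprintf("LabeledCenterline: %d samples, labels %s (%d) to %s (%d)\n",
              length(object@labels), levelName(lv[1]), lv[1],
              levelName(lv[2]), lv[2]))
})
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d disks (%s..%s), centerline %.1f mm\n",
              length(object@diskLevels), diskPairName(object@diskLevels[1]),
              diskPairName(object@diskLevels[length(object@diskLevels)]),
              max(object@centerline@arcLengthMm)))
})
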