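#' @import methods
NULL

#' Spine image volume
#'
#' A 3D scalar image on an axis-aligned RAS grid (x increases to the right,
#' y to anterior, z to superior). World coordinates are in millimetres with
#' voxel (1,1,1) centred at the origin, so world = (index - 1) * voxel size.
#' The polarity tag records the disk/vertebral-body contrast convention:
#' \code{"t2_like"} volumes show bright disks, \code{"t1_like"} dark disks.
#'
#' @slot imageData 3D numeric array of intensities.
#' @slot voxelMm numeric(3), voxel edge lengths in mm.
#' @slot polarity \code{"t1_like"} or \code{"t2_like"}.
#' @export
setClass("SpineVolume",
  representation(imageData = "array", voxelMm = "numeric",
                 polarity = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@imageData)) != 3L)
      msg <- c(msg, "imageData must be a 3D array")
    if (length(object@voxelMm) != 3L || any(object@voxelMm <= 0))
      msg <- c(msg, "voxelMm must be 3 positive values")
    if (!object@polarity %in% c("t1_like", "t2_like"))
      msg <- c(msg, "polarity must be 't1_like' or 't2_like'")
    if (length(msg)) msg else TRUE
  })

#' Spinal cord centerline
#'
#' An ordered 3D polyline in world millimetres, rostral (superior) end first,
#' together with the cumulative arc length of each point.
#'
#' @slot coords N x 3 numeric matrix (x, y, z in mm), rostral to caudal.
#' @slot arcLengthMm cumulative arc length per point, starting at 0.
#' @export
setClass("Centerline",
  representation(coords = "matrix", arcLengthMm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
    if (nrow(object@coords) < 2L) msg <- c(msg, "centerline needs >= 2 points")
    if (length(object@arcLengthMm) != nrow(object@coords))
      msg <- c(msg, "arcLengthMm length must match number of points")
    if (length(object@arcLengthMm) >= 2L &&
        any(diff(object@arcLengthMm) <= 0))
      msg <- c(msg, "arcLengthMm must be strictly increasing")
    if (length(object@arcLengthMm) && abs(object@arcLengthMm[1L]) > 1e-9)
      msg <- c(msg, "arcLengthMm must start at 0")
    if (length(msg)) msg else TRUE
  })

#' Intensity profile along the spine
#'
#' The 1D signal sampled at uniform arc-length steps along the anteriorly
#' shifted centerline. \code{sourceCoords} keeps the 3D point each sample was
#' taken at so detections can be projected back onto the cord.
#'
#' @slot positionsMm arc-length sample positions (uniform step).
#' @slot values one intensity per position; NA marks a sample whose whole
#'   averaging patch fell outside the field of view.
#' @slot polarity contrast polarity tag (after \code{normalizeProfile} the
#'   profile presents positive peaks and is tagged \code{"t2_like"}).
#' @slot sourceCoords N x 3 matrix of world coordinates (mm).
#' @export
setClass("IntensityProfile",
  representation(positionsMm = "numeric", values = "numeric",
                 polarity = "character", sourceCoords = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- length(object@positionsMm)
    if (length(object@values) != n)
      msg <- c(msg, "values and positionsMm must have equal length")
    if (nrow(object@sourceCoords) != n || ncol(object@sourceCoords) != 3L)
      msg <- c(msg, "sourceCoords must be an N x 3 matrix")
    if (n >= 3L) {
      st <- diff(object@positionsMm)
      if (max(st) - min(st) > 1e-6)
        msg <- c(msg, "positions must be uniformly spaced (1e-6 mm)")
    }
    if (!object@polarity %in% c("t1_like", "t2_like"))
      msg <- c(msg, "polarity must be 't1_like' or 't2_like'")
    if (length(msg)) msg else TRUE
  })

#' Template of generic intervertebral distances
#'
#' One row per gap between adjacent disks, rostral to caudal: the upper and
#' lower vertebral index of the bounding disks (numeric scheme, 1 = C1, ...,
#' 8 = T1, ..., 20 = L1), the across-subject mean distance, its standard
#' deviation and the number of subjects covering that gap.
#'
#' @slot gaps data.frame with columns upper_level, lower_level, mean_mm,
#'   sd_mm, n.
#' @export
setClass("DiskTemplate",
  representation(gaps = "data.frame"),
  validity = function(object) {
    g <- object@gaps
    need <- c("upper_level", "lower_level", "mean_mm", "sd_mm", "n")
    if (!all(need %in% names(g)))
      return(paste("gaps must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(g)) {
      if (any(g$lower_level != g$upper_level + 1L))
        msg <- c(msg, "each gap must join adjacent levels")
      if (nrow(g) > 1L && any(diff(g$upper_level) != 1L))
        msg <- c(msg, "gaps must cover a contiguous, increasing level range")
      if (any(!is.finite(g$mean_mm)) || any(g$mean_mm <= 0))
        msg <- c(msg, "mean_mm must be positive")
      if (any(g$sd_mm[!is.na(g$sd_mm)] < 0))
        msg <- c(msg, "sd_mm must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Disk-matching correlation pattern
#'
#' Eleven samples of a powered normalized sinc, pattern(x) =
#' sinc(x / width)^(2n), evaluated at offsets -5..+5 profile steps. The
#' even power removes the side lobes and negative values, leaving a single
#' smooth peak of unit height approximating an intervertebral disk.
#'
#' @slot samples numeric(11) pattern values, centre value 1.
#' @slot offsetsMm arc-length offsets of the samples.
#' @slot widthMm full width at half maximum of the underlying sinc (mm).
#' @slot n half the sinc exponent.
#' @export
setClass("DiskPattern",
  representation(samples = "numeric", offsetsMm = "numeric",
                 widthMm = "numeric", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@samples) != 11L) msg <- c(msg, "pattern has 11 samples")
    if (abs(object@samples[6L] - 1) > 1e-12)
      msg <- c(msg, "centre sample must equal 1")
    if (any(object@samples < 0)) msg <- c(msg, "samples must be non-negative")
    if (max(abs(object@samples - rev(object@samples))) > 1e-12)
      msg <- c(msg, "pattern must be symmetric")
    if (length(msg)) msg else TRUE
  })

#' Detected intervertebral disks
#'
#' Ordered rostral-to-caudal result of the sequential disk detection. Each
#' row is one disk: the upper vertebral index of its pair (2 for C2-C3), its
#' arc-length position on the profile, the accepted cross-correlation score
#' (NA for fallback placements), the detection mode (\code{"correlated"} or
#' \code{"template_fallback"}) and the 3D world coordinate on the shifted
#' sampling curve.
#'
#' @slot detections data.frame with columns level, level_name, position_mm,
#'   max_corr, mode, x, y, z.
#' @export
setClass("DiskDetections",
  representation(detections = "data.frame"),
  validity = function(object) {
    d <- object@detections
    need <- c("level", "level_name", "position_mm", "max_corr", "mode",
              "x", "y", "z")
    if (!all(need %in% names(d)))
      return(paste("detections must have columns:", paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(d) > 1L) {
      if (any(diff(d$position_mm) <= 0))
        msg <- c(msg, "positions must strictly increase rostral to caudal")
      if (any(diff(d$level) != 1L))
        msg <- c(msg, "levels must be consecutive")
    }
    if (nrow(d) && !all(d$mode %in% c("correlated", "template_fallback")))
      msg <- c(msg, "mode must be 'correlated' or 'template_fallback'")
    if (length(msg)) msg else TRUE
  })

#' Phantom generator configuration
#'
#' Parameters of the synthetic spine phantom: field of view and voxel size,
#' the arc-length positions of the disk centres along the curved column axis,
#' disk width and disk/body contrast, contrast polarity, curvature and bias
#' field amplitudes, additive noise, and an optional signal-dropout slab over
#' named vertebral levels (emulating a metallic implant artifact).
#'
#' @slot fovMm numeric(3) field of view (mm).
#' @slot voxelMm numeric(3) voxel size (mm), default 1 mm isotropic.
#' @slot diskPositionsMm strictly increasing disk-centre arc lengths, measured
#'   caudally from the rostral end of the volume along the column axis.
#' @slot firstDiskLevel upper vertebral index of the most rostral disk
#'   (2 = the C2-C3 disk).
#' @slot diskWidthMm full width at half maximum of the raised-cosine disk
#'   intensity profile (mm).
#' @slot diskContrast absolute disk-minus-body intensity difference; the
#'   contrast-to-noise ratio is diskContrast / noiseSd.
#' @slot polarity \code{"t2_like"} (bright disks) or \code{"t1_like"}.
#' @slot curvatureAmplitudeMm amplitude of the sinusoidal bending of the
#'   column axis in both anteroposterior and mediolateral directions.
#' @slot biasFieldAmplitude peak fractional amplitude of the multiplicative
#'   low-order polynomial intensity inhomogeneity.
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @slot dropoutLevels integer vertebral indices to attenuate (e.g. 4:6).
#' @slot dropoutAttenuation fraction of signal removed in the slab, in [0,1].
#' @slot seed integer random seed; equal configurations with equal seeds give
#'   bit-identical volumes.
#' @export
setClass("PhantomConfig",
  representation(fovMm = "numeric", voxelMm = "numeric",
                 diskPositionsMm = "numeric", firstDiskLevel = "integer",
                 diskWidthMm = "numeric", diskContrast = "numeric",
                 polarity = "character", curvatureAmplitudeMm = "numeric",
                 biasFieldAmplitude = "numeric", noiseSd = "numeric",
                 dropoutLevels = "integer", dropoutAttenuation = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@fovMm) != 3L || any(object@fovMm <= 0))
      msg <- c(msg, "fovMm must be 3 positive values")
    if (length(object@voxelMm) != 3L || any(object@voxelMm <= 0))
      msg <- c(msg, "voxelMm must be 3 positive values")
    if (length(object@diskPositionsMm) < 2L)
      msg <- c(msg, "need at least 2 disks")
    if (any(diff(object@diskPositionsMm) <= 0))
      msg <- c(msg, "diskPositionsMm must be strictly increasing")
    if (!object@polarity %in% c("t1_like", "t2_like"))
      msg <- c(msg, "polarity must be 't1_like' or 't2_like'")
    if (object@dropoutAttenuation < 0 || object@dropoutAttenuation > 1)
      msg <- c(msg, "dropoutAttenuation must lie in [0, 1]")
    if (object@diskWidthMm <= 0) msg <- c(msg, "diskWidthMm must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Phantom ground truth
#'
#' The reference against which detections are evaluated: the true disk
#' levels and arc-length positions, and the true cord centerline.
#'
#' @slot diskLevels upper vertebral index per disk (consecutive).
#' @slot diskPositionsMm true arc-length position per disk.
#' @slot centerline the true cord \linkS4class{Centerline}.
#' @export
setClass("GroundTruth",
  representation(diskLevels = "integer", diskPositionsMm = "numeric",
                 centerline = "Centerline"),
  validity = function(object) {
    msg <- character()
    if (length(object@diskLevels) != length(object@diskPositionsMm))
      msg <- c(msg, "one position per disk required")
    if (any(diff(object@diskPositionsMm) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
    if (length(object@diskLevels) > 1L && any(diff(object@diskLevels) != 1L))
      msg <- c(msg, "disk levels must be consecutive")
    if (length(msg)) msg else TRUE
  })

#' Vertebra-labeled centerline
#'
#' A centerline whose every sample carries the numeric index of the vertebra
#' it lies against (1 = C1, ..., 8 = T1, ..., 20 = L1). Labels are
#' non-decreasing rostral to caudal and change exactly at the projected disk
#' positions.
#'
#' @slot centerline the labeled \linkS4class{Centerline}.
#' @slot labels integer vertebral index per centerline sample.
#' @export
setClass("LabeledCenterline",
  representation(centerline = "Centerline", labels = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@labels) != nrow(object@centerline@coords))
      msg <- c(msg, "one label per centerline sample required")
    if (length(object@labels) > 1L && any(diff(object@labels) < 0L))
      msg <- c(msg, "labels must be non-decreasing rostral to caudal")
    if (length(msg)) msg else TRUE
  })
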