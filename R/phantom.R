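# Synthetic spine phantom: a curved vertebral column with alternating
# body/disk intensities, a spinal cord 15 mm posterior to the column axis,
# caudally increasing intervertebral distances, a smooth multiplicative bias
# field, additive Gaussian noise and an optional signal-dropout slab.

# Fixed anatomy of the phantom (mm). The averaging patch of the profile
# extractor (10 x 10 mm) must stay inside the column, so the column radius
# comfortably exceeds half the patch diagonal (~7.1 mm).
.PH_COLUMN_RADIUS <- 12
.PH_CORD_RADIUS <- 4
.PH_CORD_OFFSET <- 15   # cord runs this far posterior to the column axis
.PH_BODY <- 100
.PH_CORD <- 60
.PH_BACKGROUND <- 10

#' Default caudally increasing intervertebral gaps of the phantom
#'
#' Thirteen gap distances (mm) between the fourteen default disks (C2-C3
#' down to T8-T9), increasing from 16 mm to 28 mm in the caudal direction as
#' adult intervertebral distances do. These values parameterize the phantom
#' generator; they are a synthetic fixture, not population measurements.
#'
#' @return numeric vector of gap distances in mm.
#' @export
defaultDiskGaps <- function() seq(16, 28, by = 1)

#' @rdname defaultDiskGaps
#' @param firstDiskMm arc-length position of the first (C2-C3) disk centre.
#' @export
defaultDiskPositions <- function(firstDiskMm = 40)
  firstDiskMm + cumsum(c(0, defaultDiskGaps()))

#' Construct a phantom configuration
#'
#' Defaults describe a 1 mm isotropic cervicothoracic acquisition with
#' moderate curvature (5 mm), a 20\% bias field, and disk/body contrast 30
#' over noise SD 3 (contrast-to-noise ratio 10).
#'
#' @param fovMm,voxelMm field of view and voxel size (mm).
#' @param diskPositionsMm disk-centre arc lengths from the rostral volume end.
#' @param firstDiskLevel upper vertebral index of the first disk (2 = C2-C3).
#' @param diskWidthMm,diskContrast disk FWHM and absolute disk-body contrast.
#' @param polarity \code{"t1_like"} or \code{"t2_like"}.
#' @param curvatureAmplitudeMm,biasFieldAmplitude,noiseSd degradation levels.
#' @param dropoutLevels,dropoutAttenuation vertebral indices (or names) whose
#'   axial slab is attenuated, and the attenuation fraction in [0,1].
#' @param seed integer random seed.
#' @return a validated \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- defaultPhantomConfig(polarity = "t2_like", seed = 7L)
#' @export
defaultPhantomConfig <- function(fovMm = c(64, 96, 360), voxelMm = c(1, 1, 1),
                                 diskPositionsMm = defaultDiskPositions(),
                                 firstDiskLevel = 2L, diskWidthMm = 4,
                                 diskContrast = 30, polarity = "t2_like",
                                 curvatureAmplitudeMm = 5,
                                 biasFieldAmplitude = 0.2, noiseSd = 3,
                                 dropoutLevels = integer(),
                                 dropoutAttenuation = 0, seed = 1L) {
  new("PhantomConfig", fovMm = as.numeric(fovMm), voxelMm = as.numeric(voxelMm),
      diskPositionsMm = as.numeric(diskPositionsMm),
      firstDiskLevel = as.integer(levelIndex(firstDiskLevel)),
      diskWidthMm = diskWidthMm, diskContrast = diskContrast,
      polarity = polarity, curvatureAmplitudeMm = curvatureAmplitudeMm,
      biasFieldAmplitude = biasFieldAmplitude, noiseSd = noiseSd,
      dropoutLevels = if (length(dropoutLevels))
        as.integer(levelIndex(dropoutLevels)) else integer(),
      dropoutAttenuation = dropoutAttenuation, seed = as.integer(seed))
}

# Column-axis geometry: gentle sinusoidal bending in the mediolateral (x)
# and anteroposterior (y) directions, one period over the z span. u is the
# distance (mm) below the rostral (top) face of the volume.
.phantomAxis <- function(config, u) {
  zSpan <- config@fovMm[3]
  a <- config@curvatureAmplitudeMm
  cx <- config@fovMm[1] / 2
  cy <- config@fovMm[2] - .PH_COLUMN_RADIUS - a - 3
  list(x = cx + a * sin(2 * pi * u / zSpan),
       y = cy + 0.6 * a * sin(2 * pi * u / zSpan + pi / 3),
       cy = cy, cx = cx)
}

# Map between depth-below-top u and arc length s along the column axis.
.phantomArcMap <- function(config) {
  zTop <- (round(config@fovMm[3] / config@voxelMm[3]) - 1) * config@voxelMm[3]
  u <- seq(0, zTop, by = 0.25)
  ax <- .phantomAxis(config, u)
  seg <- sqrt(diff(ax$x)^2 + diff(ax$y)^2 + diff(u)^2)
  s <- c(0, cumsum(seg))
  list(u = u, s = s, x = ax$x, y = ax$y, zTop = zTop)
}

#' Generate a synthetic spine phantom
#'
#' Renders the configured volume together with a binary cord mask and the
#' ground truth (true disk levels/positions and the true cord centerline).
#' Identical configurations with identical seeds give bit-identical volumes.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return list with elements \code{volume} (\linkS4class{SpineVolume}),
#'   \code{cordMask} (binary \linkS4class{SpineVolume}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @examples
#' ph <- generatePhantom(defaultPhantomConfig(seed = 1L))
#' ph$volume
#' @export
generatePhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  set.seed(config@seed)
  vx <- config@voxelMm
  n <- round(config@fovMm / vx)
  arc <- .phantomArcMap(config)
  sMax <- max(arc$s)
  over <- which(config@diskPositionsMm + config@diskWidthMm > sMax)
  if (length(over)) {
    lev <- config@firstDiskLevel + over[1] - 1L
    stop(sprintf("FOV too small: disk %s at %.1f mm exceeds the %.1f mm column",
                 diskPairName(lev), config@diskPositionsMm[over[1]], sMax))
  }
  ax <- .phantomAxis(config, 0)
  halfSpan <- .PH_COLUMN_RADIUS + config@curvatureAmplitudeMm
  if (ax$cx - halfSpan < 0 || ax$cx + halfSpan > config@fovMm[1] ||
      ax$cy - config@curvatureAmplitudeMm - .PH_CORD_OFFSET -
        .PH_CORD_RADIUS < 0 || ax$cy + halfSpan > config@fovMm[2])
    stop("FOV too small to contain the column and cord laterally")

  # per-slice axis position and arc length
  zw <- (seq_len(n[3]) - 1) * vx[3]
  u <- arc$zTop - zw                       # depth below the rostral face
  xs <- stats::approx(arc$u, arc$x, xout = u)$y
  ys <- stats::approx(arc$u, arc$y, xout = u)$y
  ss <- stats::approx(arc$u, arc$s, xout = u)$y

  # raised-cosine disk modulation along arc length (FWHM = diskWidthMm)
  w <- config@diskWidthMm
  bump <- rowSums(vapply(config@diskPositionsMm, function(sd) {
    dlt <- ss - sd
    ifelse(abs(dlt) <= w, 0.5 * (1 + cos(pi * dlt / w)), 0)
  }, numeric(length(ss))))

  xw <- (seq_len(n[1]) - 1) * vx[1]
  yw <- (seq_len(n[2]) - 1) * vx[2]
  nv <- prod(n)
  xv <- rep(xw, times = n[2] * n[3])
  yv <- rep(rep(yw, each = n[1]), times = n[3])
  perSlice <- function(v) rep(v, each = n[1] * n[2])
  x0 <- perSlice(xs); y0 <- perSlice(ys)
  bumpV <- perSlice(bump)

  img <- rep(.PH_BACKGROUND, nv)
  dCol2 <- (xv - x0)^2 + (yv - y0)^2
  colMask <- dCol2 <= .PH_COLUMN_RADIUS^2
  sgn <- if (config@polarity == "t2_like") 1 else -1
  img[colMask] <- .PH_BODY + sgn * config@diskContrast * bumpV[colMask]
  dCord2 <- (xv - x0)^2 + (yv - (y0 - .PH_CORD_OFFSET))^2
  cordMask <- dCord2 <= .PH_CORD_RADIUS^2
  img[cordMask] <- .PH_CORD

  # signal-dropout slab over the named vertebral levels, disks included;
  # the margins taper over ~5 mm (susceptibility dropout has smooth edges,
  # not a step)
  if (length(config@dropoutLevels) && config@dropoutAttenuation > 0) {
    lv <- range(config@dropoutLevels)
    dl <- config@firstDiskLevel
    posOf <- function(level) {
      k <- level - dl + 1L
      if (k < 1L) return(0)
      if (k > length(config@diskPositionsMm)) return(sMax)
      config@diskPositionsMm[k]
    }
    sTop <- posOf(lv[1] - 1L) - w      # disk above the first affected vertebra
    sBot <- posOf(lv[2]) + w           # disk below the last affected vertebra
    taper <- 5
    ramp <- function(s) {
      r <- rep(0, length(s))
      r[s >= sTop & s <= sBot] <- 1
      up <- s > sTop - taper & s < sTop
      r[up] <- 0.5 * (1 + cos(pi * (sTop - s[up]) / taper))
      dn <- s > sBot & s < sBot + taper
      r[dn] <- 0.5 * (1 + cos(pi * (s[dn] - sBot) / taper))
      r
    }
    img <- img * perSlice(1 - config@dropoutAttenuation * ramp(ss))
  }

  # smooth multiplicative low-order polynomial bias field
  if (config@biasFieldAmplitude > 0) {
    xn <- 2 * xv / max(xw) - 1
    yn <- 2 * yv / max(yw) - 1
    zn <- perSlice(2 * zw / max(zw) - 1)
    poly <- (0.8 * zn + 0.5 * zn^2 + 0.3 * yn - 0.2 * xn * zn) / 1.8
    img <- img * (1 + config@biasFieldAmplitude * poly)
  }

  if (config@noiseSd > 0) img <- img + stats::rnorm(nv, 0, config@noiseSd)

  vol <- new("SpineVolume", imageData = array(img, dim = n), voxelMm = vx,
             polarity = config@polarity)
  msk <- new("SpineVolume", imageData = array(as.numeric(cordMask), dim = n),
             voxelMm = vx, polarity = config@polarity)

  # true cord centerline, rostral first, resampled to 1 mm arc steps
  cordPts <- cbind(arc$x, arc$y - .PH_CORD_OFFSET, arc$zTop - arc$u)
  truth <- new("GroundTruth",
               diskLevels = config@firstDiskLevel +
                 seq_along(config@diskPositionsMm) - 1L,
               diskPositionsMm = config@diskPositionsMm,
               centerline = newCenterline(cordPts, stepMm = 1))
  list(volume = vol, cordMask = msk, truth = truth)
}

#' Default phantom disk-distance template
#'
#' The gap layout used by the phantom generator's default disk positions,
#' packaged as a \linkS4class{DiskTemplate}. This is the synthetic fixture
#' template shipped with the package: gaps strictly increase in the caudal
#' direction and the across-subject SD grows caudally (8\% of the mean),
#' mirroring the larger thoracolumbar variability of adult spines.
#'
#' @return a \linkS4class{DiskTemplate} covering C2-C3 through T8-T9.
#' @export
defaultPhantomTemplate <- function() {
  gaps <- defaultDiskGaps()
  upper <- 2L + seq_along(gaps) - 1L
  new("DiskTemplate", gaps = data.frame(
    upper_level = upper, lower_level = upper + 1L, mean_mm = gaps,
    sd_mm = 0.08 * gaps, n = 6L))
}

#' Write a generated phantom to disk
#'
#' Writes the volume and cord mask as NIfTI-1, the ground truth as JSON
#' (disk pair name to arc-length mm) and the true centerline as
#' whitespace-delimited text (x y z per line, mm, rostral first).
#'
#' @param phantom result of \code{\link{generatePhantom}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(volume = file.path(dir, "phantom.nii.gz"),
             cordMask = file.path(dir, "cord_mask.nii.gz"),
             truth = file.path(dir, "ground_truth.json"),
             centerline = file.path(dir, "centerline.txt"))
  writeVolume(phantom$volume, paths[["volume"]])
  writeVolume(phantom$cordMask, paths[["cordMask"]])
  tr <- phantom$truth
  jsonlite::write_json(
    list(disks = stats::setNames(as.list(tr@diskPositionsMm),
                                 diskPairName(tr@diskLevels)),
         levels = tr@diskLevels),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  writeCenterline(tr@centerline, paths[["centerline"]])
  invisible(paths)
}
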