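# Building the 1D intensity profile along the spine: centerline extraction
# from a cord mask, the 15 mm anterior shift, orthogonal patch averaging,
# robust sinusoidal detrending and contrast-dependent normalization.

#' Extract a centerline from a binary cord mask
#'
#' Computes the intensity-weighted centroid of every non-empty axial slice,
#' smooths the centroid track with a short running mean (voxelization makes
#' raw centroids jitter by a fraction of a voxel, which would otherwise
#' inflate the cumulative arc length), orders the points rostral (superior)
#' to caudal and resamples the curve to 1 mm arc-length steps.
#'
#' @param mask a \linkS4class{SpineVolume} holding a binary (or weighted)
#'   cord/centerline mask.
#' @param maxGapMm largest tolerated axial gap between occupied slices (mm).
#' @param smoothSlices width (in slices) of the centroid running mean.
#' @return a \linkS4class{Centerline}.
#' @export
centerlineFromMask <- function(mask, maxGapMm = 10, smoothSlices = 7L) {
  stopifnot(is(mask, "SpineVolume"))
  arr <- mask@imageData
  idx <- which(arr > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("centerline extraction failed: empty mask")
  vx <- mask@voxelMm
  w <- arr[idx]
  zs <- sort(unique(idx[, 3]))
  if (length(zs) < 2L)
    stop("centerline extraction failed: mask occupies fewer than 2 slices")
  gaps <- diff(zs) * vx[3]
  if (any(gaps > maxGapMm)) {
    at <- zs[which.max(gaps)]
    stop(sprintf("centerline extraction failed: %.1f mm axial gap above slice z = %.1f mm",
                 max(gaps), (at - 1) * vx[3]))
  }
  cx <- tapply(idx[, 1] * w, idx[, 3], sum) / tapply(w, idx[, 3], sum)
  cy <- tapply(idx[, 2] * w, idx[, 3], sum) / tapply(w, idx[, 3], sum)
  cx <- .runmean(cx[as.character(zs)], smoothSlices)
  cy <- .runmean(cy[as.character(zs)], smoothSlices)
  ord <- order(zs, decreasing = TRUE)   # rostral (= superior, +z) first
  pts <- cbind((cx - 1) * vx[1], (cy - 1) * vx[2],
               (zs - 1) * vx[3])[ord, , drop = FALSE]
  dimnames(pts) <- NULL
  newCenterline(pts, stepMm = 1)
}

#' Shift a centerline anteriorly
#'
#' Translates every centerline point by \code{shiftMm} along the anatomical
#' anterior axis (+y in RAS), moving the sampling curve from the cord onto
#' the vertebral column. The default 15 mm is the typical cord-to-column
#' distance in adults.
#'
#' @param cl a \linkS4class{Centerline}.
#' @param shiftMm anterior shift in mm (default 15).
#' @return the shifted \linkS4class{Centerline}.
#' @export
shiftCenterlineAnterior <- function(cl, shiftMm = 15) {
  stopifnot(is(cl, "Centerline"))
  pts <- cl@coords
  pts[, 2] <- pts[, 2] + shiftMm
  newCenterline(pts)
}

#' Sample the intensity profile along a curve
#'
#' At every arc-length step along the (shifted) centerline the image is
#' averaged over a planar patch orthogonal to the local curve tangent:
#' \code{lrExtentMm} in the left-right direction and \code{apExtentMm} in the
#' tangent-orthogonal anterior-posterior direction, on a 1 mm grid with
#' trilinear interpolation. Patch points outside the field of view are
#' dropped from the average (not zero-filled); a sample whose whole patch is
#' outside is marked missing (NA).
#'
#' @param v the \linkS4class{SpineVolume} to sample.
#' @param curve the (typically anteriorly shifted) \linkS4class{Centerline}.
#' @param lrExtentMm,apExtentMm patch extents in mm (defaults 10 x 10).
#' @param stepMm arc-length sampling step in mm.
#' @param maxMissingFrac largest tolerated fraction of missing samples.
#' @return an \linkS4class{IntensityProfile}.
#' @export
sampleProfile <- function(v, curve, lrExtentMm = 10, apExtentMm = 10,
                          stepMm = 1, maxMissingFrac = 0.2) {
  stopifnot(is(v, "SpineVolume"), is(curve, "Centerline"))
  r <- resamplePolyline(curve@coords, stepMm)
  pts <- r$coords
  n <- nrow(pts)
  if (n < 2L) stop("curve too short to sample")
  # local tangent by centered finite differences
  tg <- rbind(pts[2, ] - pts[1, ],
              pts[seq(3, n), , drop = FALSE] - pts[seq(1, n - 2), , drop = FALSE],
              pts[n, ] - pts[n - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  # patch axes: anatomical left-right, and the tangent-orthogonal part of
  # the anterior direction
  lrAxis <- c(1, 0, 0)
  apRaw <- cbind(-tg[, 2] * tg[, 1], 1 - tg[, 2]^2, -tg[, 2] * tg[, 3])
  apNorm <- sqrt(rowSums(apRaw^2))
  degenerate <- apNorm < 1e-6
  if (any(degenerate)) {   # tangent parallel to y: fall back to +z projection
    apRaw[degenerate, ] <- cbind(-tg[degenerate, 3] * tg[degenerate, 1],
                                 -tg[degenerate, 3] * tg[degenerate, 2],
                                 1 - tg[degenerate, 3]^2)
    apNorm[degenerate] <- sqrt(rowSums(apRaw[degenerate, , drop = FALSE]^2))
  }
  apAxis <- apRaw / apNorm
  lrOff <- seq(-lrExtentMm / 2, lrExtentMm / 2, by = 1)
  apOff <- seq(-apExtentMm / 2, apExtentMm / 2, by = 1)
  grid <- expand.grid(lr = lrOff, ap = apOff)
  m <- nrow(grid)
  # all patch points for all samples at once: (n*m) x 3
  px <- rep(pts[, 1], each = m) + rep(grid$lr, times = n) * lrAxis[1] +
        rep(grid$ap, times = n) * rep(apAxis[, 1], each = m)
  py <- rep(pts[, 2], each = m) + rep(grid$ap, times = n) * rep(apAxis[, 2], each = m)
  pz <- rep(pts[, 3], each = m) + rep(grid$ap, times = n) * rep(apAxis[, 3], each = m)
  vals <- trilinear(v@imageData, cbind(px, py, pz), v@voxelMm)
  g <- rep(seq_len(n), each = m)
  sums <- tapply(vals, g, function(x) mean(x, na.rm = TRUE))
  prof <- as.numeric(sums)
  prof[is.nan(prof)] <- NA_real_
  nMiss <- sum(is.na(prof))
  if (nMiss / n > maxMissingFrac)
    stop(sprintf("profile sampling failed: %d of %d samples (%.0f%%) fall outside the FOV",
                 nMiss, n, 100 * nMiss / n))
  new("IntensityProfile", positionsMm = r$arcLengthMm, values = prof,
      polarity = v@polarity, sourceCoords = pts)
}

# One IRLS pass family: fit a + b*s + c*sin(2*pi*s/lambda) + d*cos(2*pi*s/lambda)
# with soft-L1 weights, returning the fit and its robust loss.
.fitSinusoid <- function(s, y, lambda, iters = 12) {
  X <- cbind(1, s, sin(2 * pi * s / lambda), cos(2 * pi * s / lambda))
  w <- rep(1, length(y))
  beta <- NULL
  for (it in seq_len(iters)) {
    fit <- tryCatch(stats::lm.wfit(X, y, w), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients[c(1, 2)])))
      return(NULL)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    r <- as.numeric(y - X %*% beta)
    sigma <- stats::mad(r)
    if (!is.finite(sigma) || sigma < 1e-12) break
    w <- 1 / sqrt(1 + (r / sigma)^2)
  }
  if (is.null(beta)) return(NULL)
  r <- as.numeric(y - X %*% beta)
  sigma <- max(stats::mad(r), 1e-12)
  loss <- sum(2 * sigma^2 * (sqrt(1 + (r / sigma)^2) - 1))
  list(baseline = as.numeric(X %*% beta), loss = loss)
}

#' Remove the profile baseline by robust sinusoidal fitting
#'
#' Fits a baseline of the form a + b s + c sin(2 pi s / lambda + phi) over
#' arc length s by iteratively reweighted least squares with a soft-L1 loss,
#' so the narrow disk peaks are downweighted and survive subtraction. The
#' period lambda is chosen on a coarse grid between \code{lambdaMinMm} and
#' three profile lengths; the lower bound keeps the sinusoid too slow to
#' absorb individual disk peaks.
#'
#' @param p an \linkS4class{IntensityProfile}.
#' @param lambdaMinMm smallest admissible sinusoid period (mm); the default
#'   is four times the largest adult intervertebral gap.
#' @return the detrended \linkS4class{IntensityProfile} (missing samples stay
#'   missing).
#' @export
detrendProfile <- function(p, lambdaMinMm = 120) {
  stopifnot(is(p, "IntensityProfile"))
  ok <- !is.na(p@values)
  s <- p@positionsMm[ok]
  y <- p@values[ok]
  if (diff(range(p@positionsMm)) < 50)
    stop("profile too short to detrend (< 50 mm)")
  if (all(abs(y - y[1]) < 1e-12)) {   # constant input: baseline is the constant
    out <- p
    out@values[ok] <- 0
    return(out)
  }
  span <- diff(range(s))
  lambdas <- unique(pmax(span * c(0.75, 1, 1.5, 2, 3), lambdaMinMm))
  fits <- lapply(lambdas, function(l) .fitSinusoid(s, y, l))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  out <- p
  if (!length(fits)) {
    warning("robust sinusoidal fit failed to converge; using median-filter baseline")
    k <- min(length(y) - (1 - length(y) %% 2), 2 * floor(span / 6) + 1)
    base <- stats::runmed(y, k = max(3, k))
    out@values[ok] <- y - base
    return(out)
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "loss"))]]
  out@values[ok] <- y - best$baseline
  out
}

#' Normalize a detrended profile per contrast
#'
#' T2-weighted profiles (bright disks) are divided by their maximum;
#' T1-weighted profiles (dark disks, negative excursions after detrending)
#' are divided by the magnitude of their most negative value and sign-flipped.
#' Either way the output presents positive disk peaks with maximum 1 and is
#' re-tagged \code{"t2_like"} (the positive-peak convention), so a single
#' downstream detection path serves both contrasts and the operation is
#' idempotent.
#'
#' @param p a detrended \linkS4class{IntensityProfile}.
#' @return the normalized \linkS4class{IntensityProfile}.
#' @export
normalizeProfile <- function(p) {
  stopifnot(is(p, "IntensityProfile"))
  v <- p@values
  if (all(is.na(v)) || max(abs(v), na.rm = TRUE) < 1e-12)
    stop("cannot normalize an all-zero profile")
  out <- p
  if (p@polarity == "t2_like") {
    out@values <- v / max(v, na.rm = TRUE)
  } else {
    m <- min(v, na.rm = TRUE)
    if (m >= 0) stop("t1_like profile has no negative excursion to normalize by")
    out@values <- -v / abs(m)
  }
  out@polarity <- "t2_like"
  out
}

#' Export a profile as CSV
#'
#' @param p an \linkS4class{IntensityProfile}.
#' @param path output path; columns \code{arc_mm}, \code{value}.
#' @export
writeProfile <- function(p, path) {
  utils::write.csv(data.frame(arc_mm = p@positionsMm, value = p@values),
                   path, row.names = FALSE)
  invisible(path)
}
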