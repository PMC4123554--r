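# Core disk detection: the powered-sinc pattern, first-disk detection by
# moving-window cross-correlation, spline peak-height normalization, and the
# sequential template-guided scan with probabilistic fallback.

#' Build the disk-matching pattern
#'
#' Eleven samples of pattern(x) = sinc(x / width)^(2n) (normalized sinc),
#' taken at offsets -5..+5 profile steps around 0. The even power removes
#' side lobes and negative values; with the defaults (width 15 mm, n = 10)
#' the pattern is a single smooth unit peak about 4 mm wide at half maximum,
#' approximating an intervertebral disk. Detection is insensitive to the
#' exact values over width 10-20 mm and n 8-12.
#'
#' @param widthMm full width at half maximum of the underlying sinc (mm).
#' @param n half the exponent (integer >= 1).
#' @param stepMm spacing of the 11 samples; use the profile step.
#' @return a \linkS4class{DiskPattern}.
#' @examples
#' makePattern()@samples[6]   # centre value, exactly 1
#' @export
makePattern <- function(widthMm = 15, n = 10L, stepMm = 1) {
  if (widthMm <= 0) stop("pattern width must be positive")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("pattern exponent n must be a positive integer")
  offsets <- (-5:5) * stepMm
  x <- offsets / widthMm
  sinc <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  new("DiskPattern", samples = sinc^(2L * n), offsetsMm = offsets,
      widthMm = widthMm, n = n)
}

# Moving-window zero-lag normalized cross-correlation of an 11-sample
# pattern against the profile. Returns one score per profile sample; samples
# whose window would extend past the profile get NA. Missing profile values
# are treated as 0 (the detrended baseline level).
.correlationProfile <- function(values, pattern) {
  v <- values
  v[is.na(v)] <- 0
  n <- length(v)
  half <- 5L
  out <- rep(NA_real_, n)
  if (n < 11L) return(out)
  W <- stats::embed(v, 11L)              # row t = v[t+10] ... v[t]
  W <- W[, 11:1, drop = FALSE]           # restore ascending order
  Wc <- W - rowMeans(W)
  pc <- pattern@samples - mean(pattern@samples)
  denom <- sqrt(rowSums(Wc^2) * sum(pc^2))
  score <- as.numeric(Wc %*% pc)
  score <- ifelse(denom > 1e-12, score / denom, 0)
  out[(half + 1L):(n - half)] <- score
  out
}

#' Detect the first (most rostral) disk
#'
#' Cross-correlates the pattern with the normalized profile using a moving
#' window and returns the most rostral local maximum of the correlation
#' profile — the C2-C3 disk when the field of view includes C2. A local
#' maximum only qualifies if its correlation reaches \code{gateFraction} of
#' the global correlation maximum and the profile's peak-to-trough range
#' under its window clearly exceeds the noise floor (estimated robustly from
#' first differences) — the normalized correlation is scale-invariant, so
#' the amplitude gate is what rejects pattern-shaped noise ripples rostral
#' of the true first disk. On a peak-free profile no maximum qualifies and
#' the caller is told to supply a starting level instead.
#'
#' @param p the normalized \linkS4class{IntensityProfile}.
#' @param pattern a \linkS4class{DiskPattern}.
#' @param gateFraction correlation gate as a fraction of the global
#'   correlation maximum.
#' @param noiseGateK amplitude gate: required window range in units of the
#'   noise standard deviation.
#' @return list with \code{positionMm} and \code{maxCorr}.
#' @export
detectFirstDisk <- function(p, pattern = makePattern(stepMm = profileStep(p)),
                            gateFraction = 0.5, noiseGateK = 8) {
  stopifnot(is(p, "IntensityProfile"))
  cs <- .correlationProfile(p@values, pattern)
  rmax <- suppressWarnings(max(cs, na.rm = TRUE))
  v0 <- ifelse(is.na(p@values), 0, p@values)
  noiseSd <- stats::mad(diff(v0)) / sqrt(2)
  winRange <- vapply(seq_along(v0), function(i) {
    w <- v0[max(1L, i - 5L):min(length(v0), i + 5L)]
    max(w) - min(w)
  }, numeric(1))
  lm <- localMaxima(cs)
  lm <- lm[!is.na(cs[lm]) & cs[lm] > 0 & cs[lm] >= gateFraction * rmax &
           winRange[lm] >= noiseGateK * noiseSd]
  if (!is.finite(rmax) || rmax <= 0 || !length(lm))
    stop("no disk-like correlation peak found; ",
         "supply a starting level and position (start = list(level, positionMm))")
  i <- lm[1L]
  list(positionMm = p@positionsMm[i], maxCorr = cs[i])
}

#' @rdname detectFirstDisk
#' @export
profileStep <- function(p) {
  if (length(p@positionsMm) < 2L) stop("profile has fewer than 2 samples")
  p@positionsMm[2L] - p@positionsMm[1L]
}

# Peak prominence of local maxima: height above the higher of the two
# saddle minima separating the peak from taller terrain on each side.
.prominence <- function(v, peaks) {
  vapply(peaks, function(i) {
    left <- v[seq_len(i)]
    higherL <- which(left > v[i])
    sadL <- if (length(higherL)) min(left[max(higherL):i]) else min(left)
    right <- v[i:length(v)]
    higherR <- which(right > v[i])
    sadR <- if (length(higherR)) min(right[1:min(higherR)]) else min(right)
    v[i] - max(sadL, sadR)
  }, numeric(1))
}

#' Equalize peak heights with an interpolating cubic spline
#'
#' Estimates the envelope of the disk peaks by passing a natural cubic
#' spline through the rough local maxima of the profile (gated by prominence
#' and a minimum separation), then divides the profile by the envelope.
#' Peaks of uneven height — typically depressed in the lumbar region by coil
#' sensitivity — all come out near unit height, which keeps the correlation
#' scores comparable along the whole spine. With fewer than 3 usable maxima
#' the spline is under-determined and the profile is returned unchanged with
#' a warning.
#'
#' @param p a detrended, normalized \linkS4class{IntensityProfile}.
#' @param prominenceFrac minimum peak prominence as a fraction of the
#'   profile maximum.
#' @param minSepMm minimum separation between retained maxima (mm); default
#'   half the smallest adult intervertebral gap.
#' @return the peak-normalized \linkS4class{IntensityProfile}.
#' @export
normalizePeaks <- function(p, prominenceFrac = 0.1, minSepMm = 8) {
  stopifnot(is(p, "IntensityProfile"))
  v <- p@values
  v0 <- ifelse(is.na(v), 0, v)
  vmax <- max(v0)
  peaks <- localMaxima(v0)
  if (length(peaks)) {
    prom <- .prominence(v0, peaks)
    peaks <- peaks[prom >= prominenceFrac * vmax]
  }
  # enforce minimum separation, keeping the taller peak
  if (length(peaks) > 1L) {
    keep <- peaks[order(-v0[peaks])]
    sel <- integer()
    for (i in keep)
      if (!length(sel) ||
          all(abs(p@positionsMm[i] - p@positionsMm[sel]) >= minSepMm))
        sel <- c(sel, i)
    peaks <- sort(sel)
  }
  if (length(peaks) < 3L) {
    warning("fewer than 3 usable local maxima; peak normalization skipped")
    return(p)
  }
  f <- stats::splinefun(p@positionsMm[peaks], v0[peaks], method = "natural")
  env <- f(p@positionsMm)
  env <- pmax(env, 0.05 * vmax)   # guard against spline undershoot
  out <- p
  out@values <- v / env
  out
}

#' Predict the next disk position from the template
#'
#' The probabilistic location of the next disk is the position of the last
#' accepted disk plus the template's generic distance for the current gap,
#' scaled by the subject-morphology ratio.
#'
#' @param lastPositionMm position of the last accepted disk (mm).
#' @param genericDistanceMm template mean distance for this gap (mm).
#' @param ratio current subject scale factor.
#' @return predicted arc-length position (mm).
#' @export
predictLocation <- function(lastPositionMm, genericDistanceMm, ratio = 1) {
  stopifnot(genericDistanceMm > 0, ratio > 0)
  lastPositionMm + genericDistanceMm * ratio
}

#' Update the subject-morphology ratio
#'
#' The ratio rescales the template to the subject: the cumulative detected
#' distance from the first disk to the current disk divided by the
#' cumulative template distance over the same gaps, clamped so an early
#' mis-detection cannot collapse the scan. With fewer than two detections
#' the ratio stays at its neutral value 1.
#'
#' @param firstPositionMm,lastPositionMm positions of the first and the
#'   most recent accepted disk (mm).
#' @param templateSpanMm sum of the template's generic distances over the
#'   gaps between those disks (mm).
#' @param nDetections number of accepted detections so far.
#' @param clampRange admissible ratio range.
#' @return the updated ratio.
#' @export
updateRatio <- function(firstPositionMm, lastPositionMm, templateSpanMm,
                        nDetections, clampRange = c(0.7, 1.3)) {
  if (nDetections < 2L) return(1)
  stopifnot(templateSpanMm > 0)
  clamp((lastPositionMm - firstPositionMm) / templateSpanMm,
        clampRange[1], clampRange[2])
}

#' Refine a predicted disk position by local cross-correlation
#'
#' Evaluates the windowed cross-correlation at every profile sample within
#' \code{searchHalfwidthMm} of the predicted position and returns the argmax
#' with its score. Ties go to the candidate nearest the prediction, then to
#' the more rostral one; on a flat window all scores are 0 and the
#' prediction itself (nearest grid sample) is returned. When no candidate
#' sample has a full correlation window the scan has reached the end of the
#' field of view and NULL is returned.
#'
#' @param p the (peak-normalized) \linkS4class{IntensityProfile}.
#' @param pattern a \linkS4class{DiskPattern}.
#' @param probLocationMm predicted position (mm).
#' @param searchHalfwidthMm half-width of the search window (mm); the scan
#'   uses 20\% of the scaled generic distance.
#' @return list with \code{positionMm} and \code{maxCorr}, or NULL at the
#'   end of the field of view.
#' @export
refineLocation <- function(p, pattern, probLocationMm, searchHalfwidthMm) {
  stopifnot(is(p, "IntensityProfile"), searchHalfwidthMm > 0)
  pos <- p@positionsMm
  n <- length(pos)
  cand <- which(pos >= probLocationMm - searchHalfwidthMm &
                pos <= probLocationMm + searchHalfwidthMm)
  cand <- cand[cand > 5L & cand <= n - 5L]
  if (!length(cand)) return(NULL)
  cs <- .correlationProfile(p@values, pattern)
  sc <- cs[cand]
  best <- cand[sc >= max(sc) - 1e-12]
  d <- abs(pos[best] - probLocationMm)
  best <- best[d <= min(d) + 1e-12]
  i <- best[1L]
  list(positionMm = pos[i], maxCorr = cs[i])
}

#' Correlation-vs-fallback decision
#'
#' A disk is placed by correlation unless its score falls below
#' \code{fallbackFraction} (default 40\%) of the median of the previously
#' accepted correlation scores, in which case the template-predicted
#' position is used instead (the mechanism that rides over missing or
#' artifact-obscured disks). With an empty history the correlation is always
#' accepted.
#'
#' @param maxCorr correlation score of the candidate disk.
#' @param history previously accepted correlation scores (fallback steps
#'   excluded — they carry no meaningful score).
#' @param fallbackFraction the median fraction under which to fall back.
#' @return \code{"correlated"} or \code{"template_fallback"}.
#' @examples
#' acceptOrFallback(0.30, c(0.8, 0.9, 1.0))  # "template_fallback"
#' @export
acceptOrFallback <- function(maxCorr, history, fallbackFraction = 0.4) {
  if (!length(history)) return("correlated")
  if (maxCorr < fallbackFraction * stats::median(history)) "template_fallback"
  else "correlated"
}

#' Detect all intervertebral disks along a profile
#'
#' Runs the full sequential detection: peak-height normalization, detection
#' of the first disk (C2-C3 by correlation when \code{start = "auto"}, or a
#' user-designated level and position when C2 is outside the field of view),
#' then a caudal scan that alternates template prediction, local correlation
#' refinement, the 40\%-of-median fallback decision and the ratio update,
#' until the template or the field of view is exhausted.
#'
#' @param p the detrended, normalized \linkS4class{IntensityProfile}.
#' @param template a \linkS4class{DiskTemplate}.
#' @param pattern a \linkS4class{DiskPattern}; defaults to the standard
#'   pattern at the profile step.
#' @param start \code{"auto"}, or \code{list(level =, positionMm =)} naming
#'   the upper vertebra of the first visible disk and its profile position.
#' The subject ratio is re-estimated after every disk from the span between
#' the first disk and the most recent correlation-detected disk (fallback
#' placements are excluded as anchors: their positions are the template's
#' own predictions and carry no information about the subject). Until the
#' anchoring template span reaches \code{minRatioSpanMm} the ratio stays at
#' its neutral value 1 — over a span of one or two gaps a millimetre-scale
#' localization error already perturbs the ratio by more than typical
#' between-subject scaling, so the prior is the better estimate.
#'
#' @param searchFraction half-width of the local search as a fraction of the
#'   scaled generic distance (default 0.2).
#' @param fallbackFraction see \code{\link{acceptOrFallback}}.
#' @param peakNormalize apply \code{\link{normalizePeaks}} before scanning.
#' @param minRatioSpanMm smallest anchoring template span (mm) over which
#'   the subject ratio is estimated rather than held at 1.
#' @param verbose log each decision with \code{message()}.
#' @return a \linkS4class{DiskDetections}.
#' @export
detectAllDisks <- function(p, template, pattern = makePattern(stepMm = profileStep(p)),
                           start = "auto", searchFraction = 0.2,
                           fallbackFraction = 0.4, peakNormalize = TRUE,
                           minRatioSpanMm = 60, verbose = FALSE) {
  stopifnot(is(p, "IntensityProfile"), is(template, "DiskTemplate"))
  pn <- if (peakNormalize) suppressWarnings(normalizePeaks(p)) else p
  cs <- .correlationProfile(pn@values, pattern)
  pos <- pn@positionsMm
  n <- length(pos)

  if (identical(start, "auto")) {
    fd <- detectFirstDisk(p, pattern)
    firstLevel <- 2L
    firstPos <- fd$positionMm
  } else {
    firstLevel <- levelIndex(start$level)
    near <- refineLocation(pn, pattern, start$positionMm,
                           max(5, 2 * profileStep(p)))
    firstPos <- if (is.null(near)) start$positionMm else near$positionMm
  }
  iFirst <- which.min(abs(pos - firstPos))
  firstCorr <- if (!is.na(cs[iFirst])) cs[iFirst] else 1

  g <- template@gaps
  g <- g[g$upper_level >= firstLevel, , drop = FALSE]
  if (!nrow(g) || g$upper_level[1L] != firstLevel)
    stop(sprintf("template does not cover a gap starting at level %s",
                 levelName(firstLevel)))

  det <- data.frame(level = firstLevel, level_name = diskPairName(firstLevel),
                    position_mm = firstPos, max_corr = firstCorr,
                    mode = "correlated", stringsAsFactors = FALSE)
  history <- firstCorr
  ratio <- 1
  tSpan <- 0
  anchorPos <- firstPos      # last correlation-detected disk
  anchorSpan <- 0            # template span from the first disk to the anchor
  beyond <- 0L
  if (verbose)
    message(sprintf("disk %s at %.1f mm (first, corr %.3f)",
                    diskPairName(firstLevel), firstPos, firstCorr))

  for (k in seq_len(nrow(g))) {
    generic <- g$mean_mm[k]
    lastPos <- det$position_mm[nrow(det)]
    prob <- predictLocation(lastPos, generic, ratio)
    hw <- searchFraction * generic * ratio
    res <- refineLocation(pn, pattern, prob, hw)
    if (is.null(res)) {
      if (verbose) message("search window beyond the field of view; stopping")
      break
    }
    mode <- acceptOrFallback(res$maxCorr, history, fallbackFraction)
    if (mode == "correlated") {
      accepted <- res$positionMm
      history <- c(history, res$maxCorr)
      beyond <- 0L
    } else {
      accepted <- prob
      if (prob + hw > pos[n]) beyond <- beyond + 1L else beyond <- 0L
    }
    newLevel <- g$upper_level[k] + 1L   # the disk below the gap's lower vertebra pair
    det <- rbind(det, data.frame(
      level = newLevel, level_name = diskPairName(newLevel),
      position_mm = accepted,
      max_corr = if (mode == "correlated") res$maxCorr else NA_real_,
      mode = mode, stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf("disk %s: prob %.1f mm, adjusted %.1f mm, corr %.3f, %s",
                      diskPairName(newLevel), prob, accepted,
                      res$maxCorr, mode))
    tSpan <- tSpan + generic
    if (mode == "correlated") {
      anchorPos <- accepted
      anchorSpan <- tSpan
    }
    ratio <- if (anchorSpan < minRatioSpanMm) 1 else
      updateRatio(det$position_mm[1L], anchorPos, anchorSpan, nrow(det))
    if (beyond >= 2L) {   # scanning past the caudal end on template alone
      det <- det[seq_len(nrow(det) - 2L), , drop = FALSE]
      if (verbose) message("two consecutive fallbacks beyond the caudal end; truncating")
      break
    }
  }

  # 3D coordinates on the sampling curve at the accepted positions
  sc <- p@sourceCoords
  xyz <- vapply(1:3, function(j)
    stats::approx(p@positionsMm, sc[, j], xout = det$position_mm, rule = 2)$y,
    numeric(nrow(det)))
  if (nrow(det) == 1L) xyz <- matrix(xyz, nrow = 1L)
  det$x <- xyz[, 1]; det$y <- xyz[, 2]; det$z <- xyz[, 3]
  new("DiskDetections", detections = det)
}

#' Write detections as CSV
#'
#' @param det a \linkS4class{DiskDetections}.
#' @param path output CSV path.
#' @export
writeDetections <- function(det, path) {
  utils::write.csv(det@detections, path, row.names = FALSE)
  invisible(path)
}

#' Write detections as a NIfTI label-point volume
#'
#' One voxel per detected disk, value = vertebral level index, in the grid
#' of a reference volume.
#'
#' @param det a \linkS4class{DiskDetections} (with 3D coordinates).
#' @param reference the \linkS4class{SpineVolume} defining the grid.
#' @param path output NIfTI path.
#' @export
writeDiskLabelVolume <- function(det, reference, path) {
  d <- det@detections
  arr <- array(0, dim = dim(reference@imageData))
  idx <- cbind(round(d$x / reference@voxelMm[1]) + 1L,
               round(d$y / reference@voxelMm[2]) + 1L,
               round(d$z / reference@voxelMm[3]) + 1L)
  ok <- idx[, 1] >= 1 & idx[, 1] <= dim(arr)[1] &
        idx[, 2] >= 1 & idx[, 2] <= dim(arr)[2] &
        idx[, 3] >= 1 & idx[, 3] <= dim(arr)[3]
  arr[idx[ok, , drop = FALSE]] <- d$level[ok]
  writeVolume(new("SpineVolume", imageData = arr,
                  voxelMm = reference@voxelMm,
                  polarity = reference@polarity), path)
}
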