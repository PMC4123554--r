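# Projection of detected disks onto the cord centerline, vertebral labeling
# of the centerline and cord surface, and the evaluation metrics.

#' Project detected disks onto the cord centerline
#'
#' Each detection's 3D coordinate (on the anteriorly shifted sampling curve)
#' is orthogonally projected onto the centerline polyline; the disk inherits
#' the arc length of the foot of the perpendicular. Ordering must be
#' preserved: two disks projecting to crossing or coincident positions are
#' rejected.
#'
#' @param det a \linkS4class{DiskDetections} with 3D coordinates.
#' @param centerline the cord \linkS4class{Centerline}.
#' @return data.frame with columns \code{level}, \code{level_name},
#'   \code{position_mm} (arc length on the centerline), \code{mode},
#'   \code{x}, \code{y}, \code{z} (foot point).
#' @export
projectDisks <- function(det, centerline) {
  stopifnot(is(det, "DiskDetections"), is(centerline, "Centerline"))
  d <- det@detections
  P <- centerline@coords
  s <- centerline@arcLengthMm
  A <- P[-nrow(P), , drop = FALSE]
  B <- P[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  proj1 <- function(q) {
    t <- clamp(((q[1] - A[, 1]) * AB[, 1] + (q[2] - A[, 2]) * AB[, 2] +
                (q[3] - A[, 3]) * AB[, 3]) / len2, 0, 1)
    fx <- A + AB * t
    d2 <- (q[1] - fx[, 1])^2 + (q[2] - fx[, 2])^2 + (q[3] - fx[, 3])^2
    i <- which.min(d2)
    c(arc = s[i] + t[i] * sqrt(len2[i]), fx[i, ])
  }
  res <- t(apply(cbind(d$x, d$y, d$z), 1, proj1))
  out <- data.frame(level = d$level, level_name = d$level_name,
                    position_mm = res[, 1], mode = d$mode,
                    x = res[, 2], y = res[, 3], z = res[, 4],
                    stringsAsFactors = FALSE)
  if (nrow(out) > 1L) {
    bad <- which(diff(out$position_mm) <= 0)
    if (length(bad))
      stop(sprintf("projection inverted the ordering of disks %s and %s",
                   out$level_name[bad[1]], out$level_name[bad[1] + 1L]))
  }
  out
}

#' Label a centerline with vertebral indices
#'
#' Samples between the disk below vertebra n and the disk below vertebra
#' n + 1 are labeled n + 1 (the vertebra between those disks); samples
#' rostral to the first projected disk carry that disk's upper-vertebra
#' index, and samples caudal to the last disk carry the adjacent (next
#' caudal) vertebra's index. A sample exactly at a disk position belongs to
#' the rostral side, so labels change immediately caudal to each disk.
#'
#' @param centerline a \linkS4class{Centerline}.
#' @param projected data.frame from \code{\link{projectDisks}} (columns
#'   \code{level} and \code{position_mm}), or a \linkS4class{DiskDetections}
#'   whose positions already live on the centerline.
#' @return a \linkS4class{LabeledCenterline}.
#' @export
labelCenterline <- function(centerline, projected) {
  stopifnot(is(centerline, "Centerline"))
  if (is(projected, "DiskDetections")) projected <- projected@detections
  if (!nrow(projected)) stop("need at least one projected disk")
  s <- centerline@arcLengthMm
  firstUpper <- projected$level[1L]
  labels <- firstUpper +
    vapply(s, function(si) sum(projected$position_mm < si), integer(1))
  new("LabeledCenterline", centerline = centerline,
      labels = as.integer(labels))
}

#' Label a cord mask with vertebral indices
#'
#' Every voxel of the binary cord mask receives the label of its nearest
#' labeled-centerline sample; background stays 0.
#'
#' @param cordMask a binary \linkS4class{SpineVolume}.
#' @param lc a \linkS4class{LabeledCenterline} in the same space.
#' @return a \linkS4class{SpineVolume} of integer labels.
#' @export
labelSurface <- function(cordMask, lc) {
  stopifnot(is(cordMask, "SpineVolume"), is(lc, "LabeledCenterline"))
  arr <- cordMask@imageData
  idx <- which(arr > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("cannot label an empty cord mask")
  vx <- cordMask@voxelMm
  W <- sweep(idx - 1, 2, vx, `*`)
  C <- lc@centerline@coords
  out <- array(0, dim = dim(arr))
  # chunked nearest-sample search to bound memory
  chunk <- 20000L
  for (a in seq(1, nrow(W), by = chunk)) {
    b <- min(a + chunk - 1L, nrow(W))
    d2 <- outer(rowSums(W[a:b, , drop = FALSE]^2), rowSums(C^2), `+`) -
      2 * W[a:b, , drop = FALSE] %*% t(C)
    nearest <- max.col(-d2, ties.method = "first")
    out[idx[a:b, , drop = FALSE]] <- lc@labels[nearest]
  }
  new("SpineVolume", imageData = out, voxelMm = vx,
      polarity = cordMask@polarity)
}

#' Evaluate detections against ground truth
#'
#' All-or-nothing accuracy per volume: 100 only if every reference vertebra
#' is correctly labeled, i.e. every reference disk level is detected and
#' each detected position is closer to its own level's true disk than to any
#' other level's. Per-level absolute position error |detected - true| is
#' reported for the shared levels, with mean and SD.
#'
#' @param projected data.frame from \code{\link{projectDisks}} (columns
#'   \code{level}, \code{position_mm}).
#' @param truth a \linkS4class{GroundTruth}.
#' @return list with \code{accuracy_pct} (0 or 100), \code{perLevel}
#'   data.frame (\code{level}, \code{level_name}, \code{error_mm}),
#'   \code{mae_mm} and \code{sd_mm}.
#' @export
evaluateLabeling <- function(projected, truth) {
  stopifnot(is(truth, "GroundTruth"))
  if (is(projected, "DiskDetections")) projected <- projected@detections
  shared <- intersect(projected$level, truth@diskLevels)
  if (!length(shared))
    stop("detected and reference labelings cover disjoint level ranges")
  dPos <- projected$position_mm[match(shared, projected$level)]
  tPos <- truth@diskPositionsMm[match(shared, truth@diskLevels)]
  err <- abs(dPos - tPos)
  # a detection is correctly labeled if its own level's true disk is the
  # nearest true disk to it
  nearest <- truth@diskLevels[vapply(dPos, function(x)
    which.min(abs(truth@diskPositionsMm - x)), integer(1))]
  allCovered <- all(truth@diskLevels %in% projected$level)
  correct <- allCovered && all(nearest == shared)
  list(accuracy_pct = if (correct) 100 else 0,
       perLevel = data.frame(level = shared, level_name = diskPairName(shared),
                             error_mm = err),
       mae_mm = mean(err), sd_mm = stats::sd(err))
}
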