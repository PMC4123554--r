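# Internal numeric helpers shared across modules.

# Cumulative arc length of an ordered polyline (N x 3, mm).
polylineArcLength <- function(pts) {
  if (nrow(pts) < 2L) return(rep(0, nrow(pts)))
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

# Resample a polyline to uniform arc-length steps (linear interpolation per
# coordinate over the original cumulative arc length).
resamplePolyline <- function(pts, stepMm = 1) {
  s <- polylineArcLength(pts)
  keep <- c(TRUE, diff(s) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  s <- s[keep]
  sNew <- seq(0, s[length(s)], by = stepMm)
  out <- vapply(1:3, function(j) stats::approx(s, pts[, j], xout = sNew)$y,
                numeric(length(sNew)))
  list(coords = out, arcLengthMm = sNew)
}

newCenterline <- function(pts, stepMm = NULL) {
  if (!is.null(stepMm)) {
    r <- resamplePolyline(pts, stepMm)
    return(new("Centerline", coords = r$coords, arcLengthMm = r$arcLengthMm))
  }
  new("Centerline", coords = pts, arcLengthMm = polylineArcLength(pts))
}

# Trilinear interpolation of a 3D array at world points (M x 3, mm).
# World = (index - 1) * voxel. Points with any corner outside the grid give NA.
trilinear <- function(arr, pts, voxelMm) {
  d <- dim(arr)
  ix <- pts[, 1] / voxelMm[1]
  iy <- pts[, 2] / voxelMm[2]
  iz <- pts[, 3] / voxelMm[3]
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  ok <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
        x0 <= d[1] - 2 + (fx < 1e-9) & y0 <= d[2] - 2 + (fy < 1e-9) &
        z0 <= d[3] - 2 + (fz < 1e-9) &
        ix <= d[1] - 1 + 1e-9 & iy <= d[2] - 1 + 1e-9 & iz <= d[3] - 1 + 1e-9
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  # clamp upper-edge points so the +1 corner stays in range
  x0k <- pmin(x0[ok], d[1] - 2); y0k <- pmin(y0[ok], d[2] - 2)
  z0k <- pmin(z0[ok], d[3] - 2)
  fxk <- ix[ok] - x0k; fyk <- iy[ok] - y0k; fzk <- iz[ok] - z0k
  at <- function(dx, dy, dz)
    arr[cbind(x0k + dx + 1L, y0k + dy + 1L, z0k + dz + 1L)]
  v <- at(0,0,0) * (1-fxk)*(1-fyk)*(1-fzk) + at(1,0,0) * fxk*(1-fyk)*(1-fzk) +
       at(0,1,0) * (1-fxk)*fyk*(1-fzk)     + at(0,0,1) * (1-fxk)*(1-fyk)*fzk +
       at(1,1,0) * fxk*fyk*(1-fzk)         + at(1,0,1) * fxk*(1-fyk)*fzk +
       at(0,1,1) * (1-fxk)*fyk*fzk         + at(1,1,1) * fxk*fyk*fzk
  out[ok] <- v
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Running mean with shrinking windows at the ends.
.runmean <- function(x, width) {
  n <- length(x)
  if (n < 3L || width < 2L) return(x)
  h <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Indices of strict local maxima of a vector (NA treated as -Inf); plateaus
# contribute their first index.
localMaxima <- function(x) {
  x[is.na(x)] <- -Inf
  n <- length(x)
  if (n < 3L) return(integer())
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x > left & x >= right)
}
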