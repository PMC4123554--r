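# Shared fixtures: a small, fast phantom configuration and builders for
# synthetic profiles and templates used across the unit tests.

# Seven disks (C2-C3 .. C8?-level 8), gaps 16..21 mm, in a 50x90x170 mm FOV.
smallGaps <- function() 16:21

smallConfig <- function(...) {
  args <- utils::modifyList(
    list(fovMm = c(50, 90, 170),
         diskPositionsMm = 30 + cumsum(c(0, smallGaps()))),
    list(...))
  do.call(defaultPhantomConfig, args)
}

# Clean variant: no noise, no bias, straight column.
cleanSmallConfig <- function(...) {
  smallConfig(noiseSd = 0, biasFieldAmplitude = 0, curvatureAmplitudeMm = 0,
              ...)
}

# Template matching the small phantom's gap layout (two identical subjects).
smallTemplate <- function() {
  pos <- 30 + cumsum(c(0, smallGaps()))
  buildTemplate(list(list(firstLevel = 2, positionsMm = pos),
                     list(firstLevel = 2, positionsMm = pos)))
}

# A synthetic IntensityProfile on a straight vertical curve.
makeProfile <- function(values, stepMm = 1, polarity = "t2_like",
                        startMm = 0) {
  n <- length(values)
  pos <- startMm + (seq_len(n) - 1) * stepMm
  new("IntensityProfile", positionsMm = pos, values = as.numeric(values),
      polarity = polarity,
      sourceCoords = cbind(rep(0, n), rep(0, n), rev(pos)))
}

# Raised-cosine peak train on a zero baseline.
peakTrain <- function(n, centersMm, heights, widthMm = 4, stepMm = 1) {
  s <- (seq_len(n) - 1) * stepMm
  v <- rep(0, n)
  for (k in seq_along(centersMm)) {
    d <- s - centersMm[k]
    v <- v + ifelse(abs(d) <= widthMm,
                    heights[k] * 0.5 * (1 + cos(pi * d / widthMm)), 0)
  }
  v
}

# Full in-memory pipeline on a generated phantom; returns evaluation pieces.
runPhantomPipeline <- function(ph, template, ...) {
  cl <- centerlineFromMask(ph$cordMask)
  prof <- sampleProfile(ph$volume, shiftCenterlineAnterior(cl, 15))
  nm <- normalizeProfile(detrendProfile(prof))
  dets <- detectAllDisks(nm, template, ...)
  proj <- projectDisks(dets, cl)
  list(centerline = cl, profile = nm, detections = dets, projected = proj,
       eval = evaluateLabeling(proj, ph$truth))
}
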