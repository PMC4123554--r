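test_that("the powered-sinc pattern has the expected closed-form values", {
  pat <- makePattern(widthMm = 15, n = 10L)
  expect_identical(pat@samples[6], 1)
  expect_equal(pat@samples, rev(pat@samples))
  # offset 5 mm: (sin(pi/3) / (pi/3))^20
  expect_equal(pat@samples[11], (sin(pi / 3) / (pi / 3))^20, tolerance = 1e-10)
  expect_equal(pat@samples[11], 0.0224, tolerance = 2e-3)
  expect_error(makePattern(widthMm = 0), "width")
  expect_error(makePattern(n = 0L), "exponent")
})

test_that("first-disk detection returns the most rostral qualifying peak", {
  v <- peakTrain(120, centersMm = c(20, 45), heights = c(1, 1))
  p <- makeProfile(v)
  pat <- makePattern()
  fd <- detectFirstDisk(p, pat)
  expect_lt(abs(fd$positionMm - 20), 1 + 1e-9)
  # score agrees with the brute-force correlation at that offset
  i <- which(profilePositions(p) == fd$positionMm)
  expect_equal(fd$maxCorr, oracleCorrAt(v, pat@samples, i), tolerance = 1e-10)
  # a single peak is found with the brute-force maximum score
  v1 <- peakTrain(120, centersMm = 30, heights = 1)
  fd1 <- detectFirstDisk(makeProfile(v1), pat)
  expect_lt(abs(fd1$positionMm - 30), 1 + 1e-9)
  all_sc <- vapply(6:114, function(i) oracleCorrAt(v1, pat@samples, i),
                   numeric(1))
  expect_equal(fd1$maxCorr, max(all_sc), tolerance = 1e-10)
})

test_that("a pure-noise profile yields no first disk and asks for a start", {
  set.seed(4)
  p <- makeProfile(rnorm(150, sd = 0.05))
  expect_error(detectFirstDisk(p, makePattern()), "starting level")
})

test_that("spline peak normalization equalizes uneven peak heights", {
  v <- peakTrain(120, centersMm = c(20, 55, 90), heights = c(1, 0.5, 0.25))
  out <- profileValues(normalizePeaks(makeProfile(v)))
  expect_equal(out[c(21, 56, 91)], c(1, 1, 1), tolerance = 0.05)
  # already-uniform peaks: the spline is the constant 1, output == input
  u <- peakTrain(120, centersMm = c(20, 50, 80), heights = c(1, 1, 1))
  expect_equal(profileValues(normalizePeaks(makeProfile(u))), u,
               tolerance = 1e-6)
  # monotone decaying train: caudal/rostral height ratio is restored
  dec <- peakTrain(200, centersMm = seq(20, 180, by = 20),
                   heights = seq(1, 0.25, length.out = 9))
  outd <- profileValues(normalizePeaks(makeProfile(dec)))
  expect_gte(outd[181] / outd[21], 0.9)
  expect_warning(normalizePeaks(makeProfile(peakTrain(60, 30, 1))),
                 "fewer than 3")
})

test_that("template prediction and ratio updates follow the scan arithmetic", {
  expect_equal(predictLocation(50, 18, 1), 68)
  expect_equal(predictLocation(68, 20, 0.9), 86)
  expect_equal(predictLocation(68, 20, 1.1), 90)
  expect_equal(updateRatio(50, 86, 40, nDetections = 3), 0.9)
  expect_equal(updateRatio(50, 50, 40, nDetections = 1), 1)
  expect_equal(updateRatio(0, 80, 40, nDetections = 3), 1.3)  # clamped
})

test_that("local refinement equals the brute-force windowed argmax", {
  pat <- makePattern()
  v <- peakTrain(120, centersMm = 70, heights = 1)
  p <- makeProfile(v)
  res <- refineLocation(p, pat, probLocationMm = 68, searchHalfwidthMm = 4)
  expect_lt(abs(res$positionMm - 70), 1 + 1e-9)
  orc <- oracleWindowedArgmax(v, pat@samples, profilePositions(p), 68, 4)
  expect_identical(res$positionMm, orc$positionMm)
  expect_equal(res$maxCorr, orc$maxCorr, tolerance = 1e-12)
  # flat-zero window: score 0, tie broken at the prediction
  flat <- makeProfile(rep(0, 120))
  r0 <- refineLocation(flat, pat, 68, 4)
  expect_identical(r0$maxCorr, 0)
  expect_identical(r0$positionMm, 68)
  # two equal, well-separated peaks equidistant from the prediction:
  # scores tie exactly by symmetry and the rostral one wins
  v2 <- peakTrain(140, centersMm = c(62, 74), heights = c(1, 1))
  r2 <- refineLocation(makeProfile(v2), pat, 68, 8)
  expect_identical(r2$positionMm, 62)
  # window fully outside the profile signals end of FOV
  expect_null(refineLocation(p, pat, 200, 4))
})

test_that("refinement matches the oracle on random profiles", {
  pat <- makePattern()
  set.seed(17)
  for (rep in 1:20) {
    nPk <- sample(2:5, 1)
    v <- peakTrain(150, centersMm = sort(sample(seq(15, 135, by = 5), nPk)),
                   heights = runif(nPk, 0.3, 1)) + rnorm(150, sd = 0.02)
    p <- makeProfile(v)
    prob <- runif(1, 20, 130)
    hw <- runif(1, 3, 10)
    res <- refineLocation(p, pat, prob, hw)
    orc <- oracleWindowedArgmax(v, pat@samples, profilePositions(p), prob, hw)
    expect_identical(res$positionMm, orc$positionMm)
    expect_equal(res$maxCorr, orc$maxCorr, tolerance = 1e-10)
  }
})

test_that("the 40%-of-median rule decides correlation versus fallback", {
  expect_identical(acceptOrFallback(0.30, c(0.8, 0.9, 1.0)), "template_fallback")
  expect_identical(acceptOrFallback(0.50, c(0.8, 0.9, 1.0)), "correlated")
  expect_identical(acceptOrFallback(0.01, numeric()), "correlated")
})

test_that("sequential detection recovers every disk on a clean phantom", {
  ph <- generatePhantom(cleanSmallConfig(seed = 31L))
  r <- runPhantomPipeline(ph, smallTemplate())
  d <- detections(r$detections)
  expect_identical(d$mode, rep("correlated", 7))
  expect_identical(d$level, 2:8)
  expect_true(all(diff(d$position_mm) > 0))
  err <- abs(d$position_mm - ph$truth@diskPositionsMm)
  expect_true(all(err < 1))
})

test_that("an ablated disk peak is bridged by the template fallback", {
  ph <- generatePhantom(cleanSmallConfig(seed = 31L))
  cl <- centerlineFromMask(ph$cordMask)
  prof <- sampleProfile(ph$volume, shiftCenterlineAnterior(cl, 15))
  nm <- normalizeProfile(detrendProfile(prof))
  # flatten the C5-C6 peak (4th disk) on the profile, widely enough that
  # every correlation window inside the search range sees only zeros
  tpos <- ph$truth@diskPositionsMm[4]
  kill <- abs(profilePositions(nm) - tpos) <= 9
  nm@values[kill] <- 0
  d <- detections(detectAllDisks(nm, smallTemplate()))
  expect_identical(d$mode[d$level == 5], "template_fallback")
  localGap <- diff(ph$truth@diskPositionsMm)[3]
  expect_lte(abs(d$position_mm[d$level == 5] - tpos), 0.2 * localGap)
  other <- d$level != 5
  expect_true(all(abs(d$position_mm[other] -
                      ph$truth@diskPositionsMm[match(d$level[other],
                                                     ph$truth@diskLevels)]) < 1))
  expect_identical(d$mode[other], rep("correlated", 6))
})

test_that("a user-specified start level drives a caudal-only scan", {
  ph <- generatePhantom(cleanSmallConfig(seed = 31L))
  cl <- centerlineFromMask(ph$cordMask)
  nm <- normalizeProfile(detrendProfile(
    sampleProfile(ph$volume, shiftCenterlineAnterior(cl, 15))))
  start <- list(level = "C4", positionMm = ph$truth@diskPositionsMm[3])
  d <- detections(detectAllDisks(nm, smallTemplate(), start = start))
  expect_identical(d$level[1], 4L)
  expect_identical(d$level, 4:8)
  expect_true(all(abs(d$position_mm - ph$truth@diskPositionsMm[3:7]) < 1))
})

test_that("detection is insensitive to pattern width and exponent", {
  ph <- generatePhantom(smallConfig(seed = 33L))
  tmpl <- smallTemplate()
  base <- runPhantomPipeline(ph, tmpl)
  for (w in c(10, 20)) for (n in c(8L, 12L)) {
    r <- runPhantomPipeline(ph, tmpl,
                            pattern = makePattern(widthMm = w, n = n))
    expect_identical(detections(r$detections)$level,
                     detections(base$detections)$level)
    expect_equal(r$eval$accuracy_pct, base$eval$accuracy_pct)
  }
})

test_that("uniformly stretched anatomy keeps every level assignment", {
  pos <- 30 + 1.15 * cumsum(c(0, smallGaps()))
  ph <- generatePhantom(cleanSmallConfig(diskPositionsMm = pos))
  r <- runPhantomPipeline(ph, smallTemplate())
  expect_identical(detections(r$detections)$level, 2:8)
  expect_equal(r$eval$accuracy_pct, 100)
})

test_that("halving the profile step moves detected peaks by less than 1 mm", {
  ph <- generatePhantom(cleanSmallConfig(seed = 35L))
  cl <- centerlineFromMask(ph$cordMask)
  sh <- shiftCenterlineAnterior(cl, 15)
  f1 <- detectFirstDisk(normalizeProfile(detrendProfile(
    sampleProfile(ph$volume, sh, stepMm = 1))))
  f05 <- detectFirstDisk(normalizeProfile(detrendProfile(
    sampleProfile(ph$volume, sh, stepMm = 0.5))))
  expect_lt(abs(f1$positionMm - f05$positionMm), 1)
})
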