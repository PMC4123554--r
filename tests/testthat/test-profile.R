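straightMaskVolume <- function(x0, y0, radius = 3, n = c(40, 40, 60)) {
  arr <- array(0, dim = n)
  xw <- (seq_len(n[1]) - 1); yw <- (seq_len(n[2]) - 1)
  disk <- outer((xw - x0)^2, (yw - y0)^2, `+`) <= radius^2
  for (z in seq_len(n[3])) arr[, , z] <- disk
  new("SpineVolume", imageData = arr, voxelMm = c(1, 1, 1),
      polarity = "t2_like")
}

test_that("centerline of a straight cylinder mask is its axis", {
  m <- straightMaskVolume(18, 21)
  cl <- centerlineFromMask(m)
  expect_true(all(abs(coords(cl)[, 1] - 18) <= 0.5))
  expect_true(all(abs(coords(cl)[, 2] - 21) <= 0.5))
  # rostral first: z decreases
  expect_true(all(diff(coords(cl)[, 3]) < 0))
})

test_that("centerline follows a helically displaced cylinder", {
  n <- c(40, 40, 80)
  arr <- array(0, dim = n)
  xw <- (seq_len(n[1]) - 1); yw <- (seq_len(n[2]) - 1)
  hx <- function(z) 20 + 6 * cos(2 * pi * z / 60)
  hy <- function(z) 20 + 6 * sin(2 * pi * z / 60)
  for (z in seq_len(n[3])) {
    zc <- z - 1
    arr[, , z] <- outer((xw - hx(zc))^2, (yw - hy(zc))^2, `+`) <= 3^2
  }
  cl <- centerlineFromMask(new("SpineVolume", imageData = arr,
                               voxelMm = c(1, 1, 1), polarity = "t2_like"))
  pts <- coords(cl)
  err <- sqrt((pts[, 1] - hx(pts[, 3]))^2 + (pts[, 2] - hy(pts[, 3]))^2)
  expect_lt(max(err), 1)
})

test_that("degenerate masks are rejected with informative errors", {
  empty <- new("SpineVolume", imageData = array(0, c(5, 5, 5)),
               voxelMm = c(1, 1, 1), polarity = "t2_like")
  expect_error(centerlineFromMask(empty), "empty mask")
  single <- empty
  single@imageData[3, 3, 3] <- 1
  expect_error(centerlineFromMask(single), "fewer than 2 slices")
  gappy <- new("SpineVolume", imageData = array(0, c(5, 5, 40)),
               voxelMm = c(1, 1, 1), polarity = "t2_like")
  gappy@imageData[3, 3, c(1:5, 30:40)] <- 1
  expect_error(centerlineFromMask(gappy), "axial gap")
})

test_that("anterior shift is a rigid +y translation", {
  pts <- cbind(rep(10, 30), rep(100, 30), seq(60, 31))
  cl <- vertlab:::newCenterline(pts)
  sh <- shiftCenterlineAnterior(cl, 15)
  expect_equal(coords(sh)[, 2], rep(115, 30))
  expect_equal(coords(sh)[, c(1, 3)], pts[, c(1, 3)])
  expect_equal(coords(shiftCenterlineAnterior(cl, 0)), pts)
  # on a curved centerline every point moves exactly 15 mm
  curved <- vertlab:::newCenterline(
    cbind(10 + 3 * sin(seq(0, 2, length.out = 40)),
          100 + 2 * cos(seq(0, 3, length.out = 40)), seq(70, 31)))
  d <- sqrt(rowSums((coords(shiftCenterlineAnterior(curved, 15)) -
                     coords(curved))^2))
  expect_equal(d, rep(15, 40))
})

test_that("profile of a constant volume is that constant", {
  v <- new("SpineVolume", imageData = array(7, c(30, 30, 50)),
           voxelMm = c(1, 1, 1), polarity = "t2_like")
  cl <- vertlab:::newCenterline(cbind(rep(14, 40), rep(14, 40), seq(45, 6)))
  p <- sampleProfile(v, cl)
  expect_equal(profileValues(p), rep(7, length(profileValues(p))))
})

test_that("profile along a z-dependent volume reproduces the axial function", {
  n <- c(30, 30, 60)
  f <- function(z) 50 + 20 * sin(2 * pi * z / 40)
  arr <- array(rep(f((seq_len(n[3]) - 1)), each = n[1] * n[2]), dim = n)
  v <- new("SpineVolume", imageData = arr, voxelMm = c(1, 1, 1),
           polarity = "t2_like")
  cl <- vertlab:::newCenterline(cbind(rep(14, 50), rep(14, 50), seq(54, 5)))
  p <- sampleProfile(v, cl)
  zs <- sourceCoords(p)[, 3]
  expect_equal(profileValues(p), f(zs), tolerance = 0.01)
})

test_that("patch points outside the FOV are excluded, not zero-filled", {
  v <- new("SpineVolume", imageData = array(4, c(30, 30, 40)),
           voxelMm = c(1, 1, 1), polarity = "t2_like")
  # curve 2 mm from the x edge: nearly half of each patch falls outside
  cl <- vertlab:::newCenterline(cbind(rep(2, 30), rep(14, 30), seq(34, 5)))
  p <- sampleProfile(v, cl)
  expect_equal(profileValues(p), rep(4, length(profileValues(p))))
})

test_that("robust detrending recovers a known sinusoidal baseline", {
  s <- 0:299
  base <- 40 + 0.05 * s + 6 * sin(2 * pi * s / 299 + 0.7)
  p <- makeProfile(base)
  r <- profileValues(detrendProfile(p))
  expect_lt(abs(mean(r)), 0.01 * diff(range(base)))
  # narrow peaks survive detrending with their heights nearly intact
  peaks <- peakTrain(300, centersMm = seq(40, 260, by = 20),
                     heights = rep(12, 12))
  p2 <- makeProfile(base + peaks)
  r2 <- profileValues(detrendProfile(p2))
  at <- seq(40, 260, by = 20) + 1
  expect_true(all(abs(r2[at] - 12) < 0.05 * 12))
  # zero signal stays zero
  expect_equal(profileValues(detrendProfile(makeProfile(rep(0, 100)))),
               rep(0, 100))
})

test_that("per-contrast normalization scales peaks to +1", {
  t2 <- makeProfile(c(0.2, 0.8, 0.4), polarity = "t2_like")
  expect_equal(profileValues(normalizeProfile(t2)), c(0.25, 1, 0.5))
  t1 <- makeProfile(c(-0.2, -0.8, -0.1), polarity = "t1_like")
  expect_equal(profileValues(normalizeProfile(t1)), c(0.25, 1, 0.125))
  # idempotence
  n1 <- normalizeProfile(t1)
  expect_equal(profileValues(normalizeProfile(n1)), profileValues(n1))
  expect_error(normalizeProfile(makeProfile(rep(0, 10))), "all-zero")
})

test_that("a t1 phantom and its t2 twin give matching normalized profiles", {
  p1 <- generatePhantom(smallConfig(polarity = "t1_like", seed = 21L))
  p2 <- generatePhantom(smallConfig(polarity = "t2_like", seed = 21L))
  get <- function(ph) {
    cl <- centerlineFromMask(ph$cordMask)
    profileValues(normalizeProfile(detrendProfile(
      sampleProfile(ph$volume, shiftCenterlineAnterior(cl, 15)))))
  }
  v1 <- get(p1); v2 <- get(p2)
  # same seed, opposite polarity: after normalization the disk peaks agree
  expect_gt(stats::cor(v1, v2), 0.95)
})

test_that("patch averaging reduces noise roughly as 1/sqrt(patch size)", {
  set.seed(99)
  v <- new("SpineVolume", imageData = array(rnorm(40 * 40 * 60), c(40, 40, 60)),
           voxelMm = c(1, 1, 1), polarity = "t2_like")
  cl <- vertlab:::newCenterline(cbind(rep(20, 50), rep(20, 50), seq(54, 5)))
  p <- sampleProfile(v, cl)   # 11 x 11 patch = 121 voxels
  expect_lt(sd(profileValues(p)), 2 / sqrt(121))
  expect_gt(sd(profileValues(p)), 0.5 / sqrt(121))
})
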