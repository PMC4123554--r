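mkDetections <- function(level, position, x, y, z,
                         mode = rep("correlated", length(level))) {
  new("DiskDetections", detections = data.frame(
    level = as.integer(level), level_name = diskPairName(level),
    position_mm = position, max_corr = rep(0.9, length(level)),
    mode = mode, x = x, y = y, z = z, stringsAsFactors = FALSE))
}

straightCenterline <- function(zTop = 100, x = 10, y = 50) {
  vertlab:::newCenterline(cbind(rep(x, zTop + 1), rep(y, zTop + 1),
                                seq(zTop, 0)))
}

test_that("projection onto a straight cord preserves the axial coordinate", {
  cl <- straightCenterline()
  det <- mkDetections(2:4, c(30, 48, 68), x = 10, y = 65, z = c(70, 52, 32))
  pr <- projectDisks(det, cl)
  expect_equal(pr$z, c(70, 52, 32))
  expect_equal(pr$position_mm, c(30, 48, 68))
  # coincident projections break the ordering contract
  det2 <- mkDetections(2:3, c(30, 31), x = 10, y = 65, z = c(70, 70))
  expect_error(projectDisks(det2, cl), "ordering")
})

test_that("projection on a curved phantom lands near the true disk positions", {
  # curvature amplitude scaled so the anteroposterior slope matches the
  # full-length phantom (the short FOV halves the bending period)
  ph <- generatePhantom(smallConfig(seed = 41L, noiseSd = 0,
                                    biasFieldAmplitude = 0,
                                    curvatureAmplitudeMm = 2.5))
  r <- runPhantomPipeline(ph, smallTemplate())
  expect_true(all(abs(r$projected$position_mm -
                      ph$truth@diskPositionsMm) < 2))
})

test_that("centerline labels change exactly at the projected disks", {
  cl <- straightCenterline()
  proj <- data.frame(level = c(2L, 3L), position_mm = c(50, 68))
  lc <- labelCenterline(cl, proj)
  s <- arcLength(cl)
  lab <- vertebraLabels(lc)
  expect_true(all(lab[s > 50 & s <= 68] == 3L))
  expect_true(all(lab[s <= 50] == 2L))
  expect_true(all(lab[s > 68] == 4L))
  expect_true(all(diff(lab) >= 0))
  # a single disk splits the centerline into exactly two label values
  lc1 <- labelCenterline(cl, data.frame(level = 2L, position_mm = 40))
  expect_identical(sort(unique(vertebraLabels(lc1))), c(2L, 3L))
})

test_that("surface labeling assigns each cord voxel its nearest sample label", {
  cl <- straightCenterline(zTop = 40, x = 10, y = 10)
  lc <- labelCenterline(cl, data.frame(level = c(2L, 3L),
                                       position_mm = c(15, 32)))
  # mask exactly on the centerline voxels
  arr <- array(0, c(21, 21, 41))
  for (i in seq_len(nrow(coords(cl))))
    arr[11, 11, round(coords(cl)[i, 3]) + 1] <- 1
  mask <- new("SpineVolume", imageData = arr, voxelMm = c(1, 1, 1),
              polarity = "t2_like")
  lab <- labelSurface(mask, lc)
  got <- vapply(seq_len(nrow(coords(cl))), function(i)
    imageData(lab)[11, 11, round(coords(cl)[i, 3]) + 1], numeric(1))
  expect_equal(got, as.numeric(vertebraLabels(lc)))
  # cylinder mask: each axial slice is label-constant, labels stay in range
  cyl <- array(0, c(21, 21, 41))
  for (z in 1:41) cyl[9:13, 9:13, z] <- 1
  maskC <- new("SpineVolume", imageData = cyl, voxelMm = c(1, 1, 1),
               polarity = "t2_like")
  labC <- imageData(labelSurface(maskC, lc))
  for (z in c(2, 20, 40))
    expect_identical(length(unique(as.vector(labC[9:13, 9:13, z]))), 1L)
  expect_true(all(unique(as.vector(labC)) %in% c(0, vertebraLabels(lc))))
  empty <- new("SpineVolume", imageData = array(0, c(5, 5, 5)),
               voxelMm = c(1, 1, 1), polarity = "t2_like")
  expect_error(labelSurface(empty, lc), "empty")
})

test_that("evaluation scores exact, shifted and misassigned labelings", {
  truth <- new("GroundTruth", diskLevels = 2:5,
               diskPositionsMm = c(40, 58, 78, 100),
               centerline = straightCenterline())
  exact <- data.frame(level = 2:5, position_mm = c(40, 58, 78, 100))
  ev <- evaluateLabeling(exact, truth)
  expect_equal(ev$accuracy_pct, 100)
  expect_equal(ev$perLevel$error_mm, rep(0, 4))
  expect_equal(ev$mae_mm, 0)

  shifted <- exact; shifted$position_mm[3] <- 80
  ev2 <- evaluateLabeling(shifted, truth)
  expect_equal(ev2$accuracy_pct, 100)
  expect_equal(ev2$perLevel$error_mm[3], 2)

  wrong <- exact; wrong$position_mm[3] <- 99   # nearest true disk is level 5
  expect_equal(evaluateLabeling(wrong, truth)$accuracy_pct, 0)

  missing <- exact[-2, ]                        # level 3 never detected
  expect_equal(evaluateLabeling(missing, truth)$accuracy_pct, 0)

  far <- data.frame(level = 10:12, position_mm = c(1, 2, 3))
  expect_error(evaluateLabeling(far, truth), "disjoint")
})
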