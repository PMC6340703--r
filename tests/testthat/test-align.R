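test_that("reference frames follow the two channels' centres of mass", {
  g <- data.frame(id = 1:2, frame = 0L, channel = "green",
                  x = c(0, 2), y = 0, z = 0, radius = 5, intensity = 100)
  r <- data.frame(id = 3L, frame = 0L, channel = "red",
                  x = 1, y = 1, z = 0, radius = 5, intensity = 50)
  rf <- computeReferenceFrame(g, r)
  expect_equal(rf@origin, c(1, 0, 0))
  expect_equal(rf@axis, c(0, 1, 0))
  ## degenerate orientation
  r0 <- transform(r, y = 0)
  expect_error(computeReferenceFrame(g, r0), class = "degenerateOrientationError")
  expect_error(computeReferenceFrame(g, r[0, ]), class = "noOrientationError")
  ## single green at p, single red at q
  rf2 <- computeReferenceFrame(g[1, ], r)
  expect_equal(rf2@origin, c(0, 0, 0))
  expect_equal(rf2@axis, c(1, 1, 0) / sqrt(2))
})

test_that("buildBasis yields right-handed orthonormal bases continuously", {
  B <- buildBasis(c(1, 0, 0))
  expect_equal(B[1, ], c(1, 0, 0))
  expect_equal(det(B), 1, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:25) {
    a <- unitVector(rnorm(3))
    B <- buildBasis(a)
    expect_equal(B[1, ], a, tolerance = 1e-12)
    expect_lt(max(abs(crossprod(B) - diag(3))), 1e-12)
    expect_equal(det(B), 1, tolerance = 1e-12)
  }
  ## continuity near an axis tie
  B1 <- buildBasis(c(0, 0, 1))
  B2 <- buildBasis(unitVector(c(1e-7, 0, 1)))
  expect_lt(max(abs(B1 - B2)), 1e-6)
  expect_error(buildBasis(c(1, 1, 0)), "unit")
})

test_that("optimizeRoll recovers known rotations exactly on the 1-degree grid", {
  set.seed(17)
  pts <- matrix(rnorm(18, sd = 15), ncol = 3)   # asymmetric cloud
  for (angle in c(0L, 37L, 123L, 359L)) {
    prev <- pts %*% t(rotationAboutX(angle))
    opt <- optimizeRoll(pts, prev)
    expect_identical(opt$angle, angle)
    expect_lt(opt$drift, 1e-6)
  }
  ## identical clouds -> angle 0
  opt <- optimizeRoll(pts, pts)
  expect_identical(opt$angle, 0L)
  ## rotationally symmetric square about the axis: ties resolve to smallest
  sq <- cbind(0, c(1, 0, -1, 0), c(0, 1, 0, -1)) * 10
  optSq <- optimizeRoll(sq, sq)
  expect_identical(optSq$angle, 0L)
  expect_error(optimizeRoll(pts[0, , drop = FALSE], prev), "non-empty")
})

test_that("alignment is rigid and anchors every frame", {
  for (preset in c("stationary", "rotating")) {
    sim <- simulateEmbryo(simulationPreset(preset, seed = 4L,
                                           nFrames = if (preset == "rotating") 25L else 40L))
    v <- validateSeries(sim$series)
    al <- alignSeries(v$series)
    for (fr in c(0L, 5L, nFrames(v$series) - 1L)) {
      before <- frameSpots(v$series, fr)
      after <- frameSpots(al$series, fr)
      db <- dist(before[, c("x", "y", "z")])
      da <- dist(after[, c("x", "y", "z")])
      expect_lt(max(abs(db - da)), 1e-9)
      ## anchor: weighted green COM at the origin, red COM on the +x ray
      g <- after[after$channel == "green", ]
      r <- after[after$channel == "red", ]
      comG <- colSums(as.matrix(g[, c("x", "y", "z")]) * g$intensity) /
        sum(g$intensity)
      comR <- colSums(as.matrix(r[, c("x", "y", "z")]) * r$intensity) /
        sum(r$intensity)
      expect_lt(max(abs(comG)), 1e-9)
      expect_lt(max(abs(comR[2:3])), 1e-9)
      expect_gt(comR[1], 0)
    }
    ## every transform is a proper rotation
    for (tr in al$result@transforms) {
      expect_lt(max(abs(crossprod(tr@rotation) - diag(3))), 1e-9)
      expect_equal(det(tr@rotation), 1, tolerance = 1e-9)
    }
  }
})

test_that("alignment reduces inter-frame drift on a rotating embryo", {
  sim <- simulateEmbryo(simulationPreset("rotating", seed = 2L, nFrames = 30L))
  v <- validateSeries(sim$series)
  al <- alignSeries(v$series)
  drift <- function(series) {
    mean(vapply(seq_len(nFrames(series) - 1L), function(fr) {
      a <- frameSpots(series, fr, "green")
      b <- frameSpots(series, fr - 1L, "green")
      d <- crossDist(as.matrix(a[, c("x", "y", "z")]),
                     as.matrix(b[, c("x", "y", "z")]))
      mean(apply(d, 1, min))
    }, numeric(1)))
  }
  expect_lt(drift(al$series), drift(v$series))
  ## strong rotation: aligned drift well under 20% of unaligned
  expect_lt(drift(al$series), 0.2 * drift(v$series))
})

test_that("pure translation drift is removed entirely", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 8L, nFrames = 25L,
                                         driftVelocity = c(3, -2, 1)))
  v <- validateSeries(sim$series)
  al <- alignSeries(v$series)
  for (fr in seq_len(nFrames(v$series)) - 1L) {
    g <- frameSpots(al$series, fr, "green")
    comG <- colSums(as.matrix(g[, c("x", "y", "z")]) * g$intensity) /
      sum(g$intensity)
    expect_lt(max(abs(comG)), 1e-9)
  }
  expect_lt(mean(al$result@drift[-1]), 1.5)
})

test_that("a frame without red orientation reuses the previous axis", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 10L, nFrames = 10L))
  s <- spots(sim$series)
  s <- s[!(s$frame == 5L & s$channel == "red"), ]
  ser <- SpotSeries(s, nFrames = 10L, frameInterval = 5)
  v <- validateSeries(ser)
  al <- alignSeries(v$series)
  expect_true(al$result@axisReused[6])
  expect_identical(al$result@referenceFrames[[6]]@axis,
                   al$result@referenceFrames[[5]]@axis)
  ## frame 0 without red is a hard error
  s0 <- s[!(s$frame == 0L & s$channel == "red"), ]
  v0 <- validateSeries(SpotSeries(s0, nFrames = 10L, frameInterval = 5),
                       validationParams(recoveryEnabled = FALSE))
  expect_error(alignSeries(v0$series), "frame 0")
})

test_that("crop bounds cover all spots plus the margin", {
  df <- data.frame(id = 1:3, frame = 0:2, channel = "green",
                   x = c(0, 5, 10), y = c(0, 10, 3), z = c(0, 2, 10),
                   radius = 5, intensity = 1)
  ser <- SpotSeries(df)
  box <- cropBounds(ser, margin = 2)
  expect_equal(box@min, c(-2, -2, -2))
  expect_equal(box@max, c(12, 12, 12))
  box0 <- cropBounds(ser, margin = 0)
  expect_equal(box0@min, c(0, 0, 0))
  single <- cropBounds(SpotSeries(df[2, ]), margin = 3)
  expect_equal(single@min, c(2, 7, -1))
  expect_equal(single@max, c(8, 13, 5))
  expect_error(cropBounds(SpotSeries(), margin = 1), "empty")
})

test_that("resampling is exact for identity and voxel-pitch translations", {
  set.seed(41)
  vox <- array(runif(20 * 24 * 24), c(20, 24, 24))
  vol <- ImageVolume(vox, voxelSize = c(3, 2, 2))
  full <- CropBox(min = c(0, 0, 0), max = c(48, 48, 60))
  out <- resampleVolume(vol, RigidTransform(), full)
  expect_equal(out@voxels, vol@voxels, tolerance = 1e-12)
  ## translation by one voxel pitch in x shifts the content by one voxel
  tr <- RigidTransform(rotation = diag(3), translation = c(2, 0, 0))
  shifted <- resampleVolume(vol, tr, full)
  expect_equal(shifted@voxels[, , 1:23], vol@voxels[, , 2:24], tolerance = 1e-9)
  expect_true(all(shifted@voxels[, , 24] == 0))
})

test_that("a small rotation conserves the integral of an interior blob", {
  vol <- renderBlobVolume(dim = c(40L, 48L, 48L), center = c(48, 48, 60),
                          sigma = 5, amplitude = 50)
  rot <- RigidTransform(rotation = rotationAboutAxis(c(0, 0, 1), 4),
                        translation = c(48, 48, 60))
  box <- CropBox(min = c(18, 18, 25) - c(48, 48, 60),
                 max = c(78, 78, 95) - c(48, 48, 60))
  out <- resampleVolume(vol, rot, box)
  vsize <- prod(vol@voxelSize)
  inBlob <- sum(vol@voxels[9:31, 10:38, 10:38]) * vsize
  expect_lt(abs(sum(out@voxels) * vsize - (2 * pi)^1.5 * 5^3 * 50) /
              ((2 * pi)^1.5 * 5^3 * 50), 0.01)
})
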