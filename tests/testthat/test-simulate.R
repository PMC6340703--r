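test_that("cell counts double per completed division round", {
  sim <- simulateEmbryo(simulationPreset("rotating", seed = 1L))
  counts <- table(sim$truth@cells$frame)
  expect_identical(as.integer(counts[1]), 4L)
  expect_identical(as.integer(counts[length(counts)]), 32L)  # 4 * 2^3
  ## counts never decrease
  expect_true(all(diff(as.integer(counts)) >= 0L))
  ## 2 rounds -> 16
  sim2 <- simulateEmbryo(simulationPreset("crowded", seed = 2L))
  expect_identical(sum(sim2$truth@cells$frame == max(sim2$truth@cells$frame)), 16L)
})

test_that("red cells are exactly the descendants of the converted founder", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 3L,
                                         convertedCellIndex = 2L))
  ped <- sim$truth@pedigree
  descended <- function(cell) {
    repeat {
      row <- ped[ped$cell == cell, ]
      if (is.na(row$parent)) return(cell)
      cell <- row$parent
    }
  }
  founderOf <- vapply(sim$truth@cells$cell, descended, integer(1))
  expect_identical(sim$truth@cells$red, founderOf == 3L)
  ## red spot count per frame equals red cell count
  s <- spots(sim$series)
  expect_identical(as.integer(table(factor(s$frame[s$channel == "red"],
                                           levels = 0:159))),
                   as.integer(table(factor(sim$truth@cells$frame[sim$truth@cells$red],
                                           levels = 0:159))))
})

test_that("red intensity dilutes geometrically with generation", {
  sim <- simulateEmbryo(simulationPreset("rotating", seed = 4L))
  cells <- sim$truth@cells[sim$truth@cells$red, ]
  expect_equal(cells$intensityRed, 100 * 0.5^cells$generation)
  final <- cells[cells$frame == max(cells$frame), ]
  expect_equal(unique(final$intensityRed), 100 * 0.5^3)
})

test_that("a fixed seed reproduces the simulation bitwise", {
  a <- simulateEmbryo(simulationPreset("rotating", seed = 99L, spuriousRate = 1))
  b <- simulateEmbryo(simulationPreset("rotating", seed = 99L, spuriousRate = 1))
  expect_identical(spots(a$series), spots(b$series))
  expect_identical(a$truth@cells, b$truth@cells)
  expect_identical(a$truth@spurious, b$truth@spurious)
  c_ <- simulateEmbryo(simulationPreset("rotating", seed = 100L, spuriousRate = 1))
  expect_false(identical(spots(a$series), spots(c_$series)))
})

test_that("ground-truth transforms reproduce the rigid motion", {
  sim <- simulateEmbryo(simulationPreset("rotating", seed = 5L, nFrames = 20L))
  tc <- sim$truth@cells
  ## mapping every frame into the embryo frame must undo drift+rotation:
  ## a non-dividing cell's embryo-frame path moves only by Brownian steps
  cell <- tc$cell[1]
  path <- tc[tc$cell == cell, ]
  emb <- t(vapply(seq_len(nrow(path)), function(i)
    as.numeric(applyTransform(sim$truth@transforms[[path$frame[i] + 1L]],
                              c(path$x[i], path$y[i], path$z[i]))),
    numeric(3)))
  steps <- sqrt(rowSums(diff(emb)^2))
  world <- as.matrix(path[, c("x", "y", "z")])
  worldSteps <- sqrt(rowSums(diff(world)^2))
  ## embryo-frame motion (Brownian + tiling) is far below the rigid motion
  expect_lt(mean(steps), 2)
  expect_gt(mean(worldSteps), 5)
})

test_that("rendered volumes have the configured geometry and mass", {
  p <- simulationPreset("stationary", seed = 6L, nFrames = 2L,
                        noiseModel = "none", backgroundBase = 0,
                        backgroundRamp = 0)
  sim <- simulateEmbryo(p)
  vols <- renderVolumes(sim$truth, frames = 0L)
  expect_length(vols, 2L)
  expect_identical(dim(vols[[1]]@voxels)[1], 80L)
  expect_equal(dim(vols[[1]]@voxels)[1] * vols[[1]]@voxelSize[1], 240)
  ## total mass of the green channel ~ sum of analytic blob integrals
  total <- sum(vols[[1]]@voxels) * prod(vols[[1]]@voxelSize)
  cells <- sim$truth@cells[sim$truth@cells$frame == 0L, ]
  expect_equal(total, sum(cells$intensityGreen) * (2 * pi)^1.5 *
                 p@nucleusSigma^3, tolerance = 0.01)
  ## zero cells, zero background -> all-zero volume
  empty <- sim$truth
  empty@cells <- empty@cells[0, ]
  expect_true(all(renderVolumes(empty, p, frames = 0L)[[1]]@voxels == 0))
})

test_that("time subsampling renumbers frames and scales the interval", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 7L, nFrames = 9L))
  sub <- subsampleTime(sim$series, 4L)
  expect_identical(nFrames(sub), 3L)
  expect_identical(sort(unique(spots(sub)$frame)), 0:2)
  expect_equal(frameInterval(sub), 20)
  expect_identical(subsampleTime(sim$series, 1L), sim$series)
  expect_error(subsampleTime(sim$series, 0L), "keepEvery")
  ## subsampled truth forest matches the subsampled series frames
  tf <- truthForest(sim$truth, keepEvery = 4L)
  expect_identical(sort(unique(tf@nodes$frame)), 0:2)
})

test_that("detection closure: every true nucleus is found in rendered volumes", {
  p <- simulationPreset("stationary", seed = 8L, nFrames = 2L,
                        noiseModel = "none")
  sim <- simulateEmbryo(p)
  vol <- renderVolumes(sim$truth, frames = 0L, channels = "green")[[1]]
  found <- detectSpots(vol, detectionParams())
  cells <- sim$truth@cells[sim$truth@cells$frame == 0L, ]
  d <- crossDist(as.matrix(cells[, c("x", "y", "z")]),
                 as.matrix(found[, c("x", "y", "z")]))
  expect_true(all(apply(d, 1, min) <= sqrt(3) * p@nucleusSigma))
})
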