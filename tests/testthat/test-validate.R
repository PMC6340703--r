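mkSpots <- function(xyz, channel = "green", frame = 0L, intensity = 100,
                    radius = 5, id0 = 1L) {
  data.frame(id = seq.int(id0, length.out = nrow(xyz)), frame = frame,
             channel = channel, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             radius = radius, intensity = intensity)
}

test_that("embryo extent matches direct enumeration", {
  ## 4 spots at (+-1,0,0),(0,+-1,0): every maximal inter-spot distance is 2
  sq <- mkSpots(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)))
  expect_equal(estimateEmbryoExtent(sq), 2)
  ## collinear x = 0, 1, 3: per-spot maxima 3, 3, 3 -> wait: 3, 2, 3 -> median 3
  col <- mkSpots(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)))
  expect_equal(estimateEmbryoExtent(col), 3)
  expect_error(estimateEmbryoExtent(col[1, ]), "insufficient")
})

test_that("radius filter keeps a closed ball around the green COM", {
  green <- mkSpots(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)))
  params <- validationParams(radiusFactor = 0.5)  # extent 2 -> T = 1
  probe <- mkSpots(rbind(c(0.9, 0, 0), c(1.1, 0, 0), c(0, 0, 1)),
                   channel = "red", id0 = 10L)
  out <- filterOutsideEmbryo(probe, green, params)
  expect_identical(out$kept$id, c(10L, 12L))   # 0.9 kept, boundary 1.0 kept
  expect_identical(out$discarded$id, 11L)
  ## partition is exhaustive and disjoint
  expect_identical(sort(c(out$kept$id, out$discarded$id)), probe$id)
  ## a large factor keeps everything
  all_ <- filterOutsideEmbryo(probe, green, validationParams(radiusFactor = 10))
  expect_identical(nrow(all_$discarded), 0L)
})

test_that("double-spot merging follows transitive components", {
  ## two spots 0.5 um apart merge into their intensity-weighted centroid
  two <- mkSpots(rbind(c(0, 0, 0), c(0.5, 0, 0)), intensity = c(100, 300))
  m <- mergeDoubleSpots(two, mergeDistance = 1)
  expect_identical(nrow(m), 1L)
  expect_equal(m$x, 0.375)                     # weighted midpoint
  expect_equal(m$intensity, 400)
  expect_false(m$id %in% two$id)               # fresh id
  ## chain a-b-c merges wholesale even though a-c exceeds the distance
  chain <- mkSpots(rbind(c(0, 0, 0), c(0.9, 0, 0), c(1.8, 0, 0)))
  m2 <- mergeDoubleSpots(chain, mergeDistance = 1)
  expect_identical(nrow(m2), 1L)
  ## brute-force component oracle
  d <- as.matrix(dist(chain[, c("x", "y", "z")]))
  expect_true(d[1, 3] > 1)                     # the chain really is indirect
  ## distant spots pass through untouched (bitwise)
  apart <- mkSpots(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_identical(mergeDoubleSpots(apart, mergeDistance = 1), apart)
})

test_that("red colocalization keeps exactly the red spots near green", {
  green <- mkSpots(rbind(c(0.3, 0, 0), c(50, 0, 0)))
  red <- mkSpots(rbind(c(0, 0, 0), c(10, 0, 0), c(50.5, 0, 0)),
                 channel = "red", id0 = 11L)
  out <- filterNoncolocalizedRed(red, green, colocDistance = 0.5)
  expect_identical(out$kept$id, c(11L, 13L))
  ## empty green discards all red
  out2 <- filterNoncolocalizedRed(red, green[0, ], colocDistance = 0.5)
  expect_identical(nrow(out2$kept), 0L)
  ## boundary: exactly at the distance is kept (0.5 is representable and
  ## 49.5/50 subtract exactly)
  red3 <- mkSpots(matrix(c(49.5, 0, 0), 1), channel = "red", id0 = 20L)
  expect_identical(nrow(filterNoncolocalizedRed(red3, green, 0.5)$kept), 1L)
})

test_that("red recovery looks one frame back within the search radius", {
  prev <- mkSpots(matrix(c(1.2, 0, 0), 1), channel = "red")
  disc <- mkSpots(rbind(c(1, 0, 0), c(4, 0, 0)), channel = "red",
                  frame = 1L, id0 = 5L)
  rec <- recoverRedSpots(disc, prev, recoveryRadius = 0.5)
  expect_identical(rec$id, 5L)
  expect_identical(nrow(recoverRedSpots(disc, prev, recoveryRadius = 0.1)), 0L)
  ## frame 0 never recovers
  disc0 <- transform(disc, frame = 0L)
  expect_identical(nrow(recoverRedSpots(disc0, prev, 5)), 0L)
})

test_that("validateSeries is the identity on clean simulated data", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 5L, nFrames = 30L))
  v <- validateSeries(sim$series)
  expect_equal(spots(v$series)[, c("frame", "channel", "x", "y", "z")],
               spots(sim$series)[, c("frame", "channel", "x", "y", "z")])
  expect_true(all(v$report$outside == 0L))
  expect_true(all(v$report$merged == 0L))
  expect_true(all(v$report$noncoloc == 0L))
})

test_that("validation filters agree with brute force on contaminated frames", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 9L,
                                         spuriousRate = 2))
  v <- validateSeries(sim$series)
  vs <- spots(v$series)
  truth <- sim$truth
  nWrong <- 0L
  for (fr in unique(vs$frame)) {
    tc <- truth@cells[truth@cells$frame == fr, ]
    for (ch in c("green", "red")) {
      kept <- vs[vs$frame == fr & vs$channel == ch, ]
      want <- if (ch == "green") nrow(tc) else sum(tc$red)
      ## brute-force: every kept spot within 1 um of a true cell and
      ## every true cell covered
      d <- crossDist(as.matrix(kept[, c("x", "y", "z")]),
                     as.matrix(tc[if (ch == "red") tc$red else TRUE,
                                  c("x", "y", "z")]))
      if (nrow(kept) != want || any(apply(d, 1, min) > 1)) nWrong <- nWrong + 1L
    }
  }
  ## background removal is not guaranteed frame-by-frame in every regime,
  ## but on this preset the filters should clean essentially everything
  expect_lte(nWrong, 2L)
  ## report conservation holds exactly
  rep_ <- v$report
  expect_identical(rep_$nIn,
                   rep_$nOut + rep_$outside + rep_$merged + rep_$noncoloc -
                     rep_$recovered)
})

test_that("validateSeries is idempotent with recovery disabled", {
  params <- validationParams(recoveryEnabled = FALSE)
  for (seed in c(2L, 6L)) {
    sim <- simulateEmbryo(simulationPreset("rotating", seed = seed,
                                           spuriousRate = 1))
    once <- validateSeries(sim$series, params)
    twice <- validateSeries(once$series, params)
    expect_equal(spots(twice$series)[, c("frame", "channel", "x", "y", "z")],
                 spots(once$series)[, c("frame", "channel", "x", "y", "z")])
  }
})

test_that("kept unmerged spots are never moved", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 3L,
                                         nFrames = 20L, spuriousRate = 2))
  v <- validateSeries(sim$series)
  raw <- spots(sim$series)
  kept <- spots(v$series)
  surviving <- kept[kept$id %in% raw$id, ]      # merged spots have fresh ids
  match_ <- raw[match(surviving$id, raw$id), ]
  expect_identical(surviving$x, match_$x)
  expect_identical(surviving$y, match_$y)
  expect_identical(surviving$z, match_$z)
})

test_that("an injected far outlier is discarded every frame", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 12L, nFrames = 15L))
  s <- spots(sim$series)
  extra <- do.call(rbind, lapply(0:14, function(fr) {
    com <- colMeans(as.matrix(s[s$frame == fr & s$channel == "green",
                                c("x", "y", "z")]))
    data.frame(id = 90000L + fr, frame = fr, channel = "green",
               x = com[1] + 800, y = com[2], z = com[3],
               radius = 5, intensity = 20)
  }))
  contaminated <- SpotSeries(rbind(s, extra), nFrames = nFrames(sim$series),
                             frameInterval = frameInterval(sim$series))
  v <- validateSeries(contaminated)
  expect_true(all(v$report$outside[v$report$channel == "green"] == 1L))
  expect_false(any(spots(v$series)$id >= 90000L))
})

test_that("red recovery in a series rescues a red spot missing its green partner", {
  base <- rbind(
    mkSpots(rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0)), frame = 0L),
    mkSpots(matrix(c(0, 0, 0), 1), channel = "red", frame = 0L, id0 = 10L),
    mkSpots(rbind(c(0, 0, 0.5), c(20, 0, 0.5), c(0, 20, 0.5)), frame = 1L,
            id0 = 20L),
    mkSpots(matrix(c(25, 25, 25), 1), channel = "red", frame = 1L, id0 = 30L))
  ## red spot 31 at frame 1 near the previous red but with no green partner
  lost <- mkSpots(matrix(c(0.3, 0, 0.5), 1), channel = "red", frame = 1L,
                  id0 = 31L)
  lost$x <- 0.3
  ser <- SpotSeries(rbind(base, lost), frameInterval = 5)
  ## make the green partner disappear: shift greens away from the red
  s <- spots(ser)
  s$x[s$id == 20L] <- 8   # green twin moved beyond coloc distance
  ser <- SpotSeries(s, frameInterval = 5)
  withRec <- validateSeries(ser, validationParams(recoveryEnabled = TRUE,
                                                  recoveryRadius = 2))
  without <- validateSeries(ser, validationParams(recoveryEnabled = FALSE))
  expect_true(31L %in% spots(withRec$series)$id)
  expect_false(31L %in% spots(without$series)$id)
})
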