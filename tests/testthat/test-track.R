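test_that("the assignment solver matches brute force on random instances", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(2:5, 1)
    m <- n + sample(0:2, 1)
    cost <- matrix(runif(n * m, 0, 10), n, m)
    got <- solveAssignment(cost)
    want <- bruteAssignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), want$cost,
                 tolerance = 1e-9)
  }
  ## more rows than columns: every column used once
  cost <- matrix(runif(12), 4, 3)
  a <- solveAssignment(cost)
  expect_identical(sum(is.na(a)), 1L)
  expect_identical(sort(a[!is.na(a)]), 1:3)
})

mkFrame <- function(xyz, frame, channel = "green", id0 = 1L) {
  data.frame(id = seq.int(id0, length.out = nrow(xyz)), frame = frame,
             channel = channel, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             radius = 5, intensity = 100)
}

test_that("linkFrames picks the minimal-cost one-to-one links", {
  a <- mkFrame(rbind(c(0, 0, 0), c(20, 0, 0)), 0L)
  b <- mkFrame(rbind(c(1, 0, 0), c(21, 0, 0)), 1L, id0 = 3L)
  e <- linkFrames(a, b, linkingParams(maxLinkDistance = 5))
  expect_identical(e$from, c(1L, 2L))
  expect_identical(e$to, c(3L, 4L))
  ## brute force over both possible bijections agrees
  d <- crossDist(as.matrix(a[, c("x", "y", "z")]),
                 as.matrix(b[, c("x", "y", "z")]))
  expect_lt(d[1, 1] + d[2, 2], d[1, 2] + d[2, 1])
  ## out-of-range spot starts a new track
  far <- mkFrame(matrix(c(100, 0, 0), 1), 1L, id0 = 9L)
  e2 <- linkFrames(a, rbind(b, far), linkingParams(maxLinkDistance = 5))
  expect_false(9L %in% e2$to)
})

test_that("a division links both daughters to the mother", {
  mother <- mkFrame(matrix(c(0, 0, 0), 1), 0L)
  daughters <- mkFrame(rbind(c(4, 0, 0), c(-4, 0, 0)), 1L, id0 = 2L)
  e <- linkFrames(mother, daughters, linkingParams())
  expect_identical(nrow(e), 2L)
  expect_identical(e$from, c(1L, 1L))
  expect_identical(sort(e$to), c(2L, 3L))
})

test_that("track graphs recover simple ground truths", {
  ## 4 cells, small motion, no divisions
  set.seed(61)
  base <- matrix(rnorm(12, sd = 30), 4, 3)
  rows <- do.call(rbind, lapply(0:9, function(fr)
    mkFrame(base + rnorm(12, sd = 0.3), fr, id0 = fr * 10L + 1L)))
  g <- buildTrackGraph(SpotSeries(rows, frameInterval = 5), linkingParams())
  outdeg <- table(g@edges$from)
  expect_identical(nrow(g@edges), 36L)            # 4 tracks x 9 steps
  expect_true(all(outdeg == 1L))
  ## one division at frame 5
  pos <- matrix(c(0, 0, 0), 1)
  rows <- list()
  for (fr in 0:10) {
    if (fr == 6) pos <- rbind(pos[1, ] + c(4, 0, 0), pos[1, ] - c(4, 0, 0))
    rows[[fr + 1]] <- mkFrame(pos, fr, id0 = fr * 10L + 1L)
    pos <- pos + rnorm(length(pos), sd = 0.2)
  }
  g2 <- buildTrackGraph(SpotSeries(do.call(rbind, rows), frameInterval = 5),
                        linkingParams())
  outdeg2 <- table(g2@edges$from)
  expect_identical(sum(outdeg2 == 2L), 1L)
  divNode <- as.integer(names(outdeg2)[outdeg2 == 2L])
  expect_identical(g2@nodes$frame[match(divNode, g2@nodes$id)], 5L)
})

test_that("gap closing joins interrupted tracks through a synthetic node", {
  rows <- do.call(rbind, lapply(0:6, function(fr)
    mkFrame(matrix(c(fr * 0.5, 0, 0), 1), fr, id0 = fr + 1L)))
  rows <- rows[rows$frame != 3L, ]
  ser <- SpotSeries(rows, nFrames = 7L, frameInterval = 5)
  open <- buildTrackGraph(ser, linkingParams(allowGap = TRUE))
  closed <- buildTrackGraph(ser, linkingParams(allowGap = FALSE))
  rootsOf <- function(g) sum(!g@nodes$id %in% g@edges$to & !g@nodes$synthetic)
  expect_identical(rootsOf(closed), 2L)
  expect_identical(rootsOf(open), 1L)
  expect_identical(sum(open@nodes$synthetic), 1L)
  expect_identical(open@nodes$frame[open@nodes$synthetic], 3L)
})

test_that("green-minus-red subsetting is the exact complement", {
  set.seed(71)
  green <- mkFrame(matrix(rnorm(30, sd = 20), 10, 3), 0L)
  red <- green[c(2, 5), ]
  red$channel <- "red"; red$id <- 101:102
  red$x <- red$x + 0.2
  sub <- subsetGreenMinusRed(green, red, colocDistance = 1)
  expect_identical(sub$id, green$id[-c(2, 5)])
  ## complement property
  coloc <- green[!green$id %in% sub$id, ]
  expect_identical(sort(c(sub$id, coloc$id)), green$id)
  ## empty red keeps everything
  expect_identical(subsetGreenMinusRed(green, red[0, ], 1), green)
})

test_that("two-channel tracing of a clean embryo yields 4 trees, one red", {
  sim <- simulateEmbryo(simulationPreset("stationary", seed = 13L))
  res <- traceSeries(sim$series)
  expect_identical(nrow(res$forest@trees), 4L)
  expect_identical(sum(res$forest@trees$channel == "red"), 1L)
  ## every node appears exactly once
  expect_false(anyDuplicated(res$forest@nodes$id) > 0)
  ## no cross-channel edges
  chOf <- setNames(res$forest@nodes$channel, res$forest@nodes$id)
  expect_true(all(chOf[as.character(res$forest@edges$from)] ==
                    chOf[as.character(res$forest@edges$to)]))
  ## frame-range mismatch raises
  s <- spots(res$validated)
  a <- SpotSeries(s[s$channel == "red", ], nFrames = nFrames(res$validated))
  b <- SpotSeries(s[s$channel == "green" &
                      s$frame < nFrames(res$validated) - 1L, ],
                  nFrames = nFrames(res$validated) - 1L)
  expect_error(traceTwoChannel(a, b), "mismatch")
})
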