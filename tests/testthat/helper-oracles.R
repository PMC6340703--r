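## Independent oracles used across the suite. These deliberately share no
## code with the implementations they check.

## naive exponential ordered-forest edit distance (rightmost-root recursion);
## exact for the small trees used in tests
naiveForestDist <- function(F, G, costs = treeEditCosts()) {
  upd <- costs@update
  rec <- function(F, G) {
    if (!length(F) && !length(G)) return(0)
    best <- Inf
    if (length(F)) {
      Tf <- F[[length(F)]]
      F2 <- c(F[-length(F)], Tf$children)
      best <- min(best, rec(F2, G) + costs@remove)
    }
    if (length(G)) {
      Tg <- G[[length(G)]]
      G2 <- c(G[-length(G)], Tg$children)
      best <- min(best, rec(F, G2) + costs@insert)
    }
    if (length(F) && length(G)) {
      Tf <- F[[length(F)]]; Tg <- G[[length(G)]]
      best <- min(best, rec(F[-length(F)], G[-length(G)]) +
                    rec(Tf$children, Tg$children) +
                    upd(Tf$lengths, Tg$lengths))
    }
    best
  }
  rec(F, G)
}

naiveTreeDist <- function(a, b, costs = treeEditCosts()) {
  naiveForestDist(list(a@root), list(b@root), costs)
}

## random condensed tree with <= maxNodes nodes, binary children,
## branch-length tuples of 1-2 entries in 1..9
randomCondensedTree <- function(maxNodes = 5L) {
  n <- sample.int(maxNodes, 1L)
  parent <- integer(n)
  kids <- integer(n)
  if (n > 1L) for (i in 2:n) {
    open <- which(kids[seq_len(i - 1L)] < 2L)
    p <- open[sample.int(length(open), 1L)]
    parent[i] <- p
    kids[p] <- kids[p] + 1L
  }
  build <- function(i) {
    ch <- which(parent == i)
    list(lengths = sample.int(9L, sample.int(2L, 1L), replace = TRUE),
         children = lapply(ch, build))
  }
  CondensedTree(build(1L), rootFrame = 0L, origin = runif(3, -20, 20))
}

## brute-force linear assignment by permutation enumeration (n <= ~6)
bruteAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, m <= 7)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(m))) {
    sel <- p[seq_len(n)]
    cc <- sum(cost[cbind(seq_len(n), sel)])
    if (cc < bestCost) { bestCost <- cc; best <- sel }
  }
  list(assignment = best, cost = bestCost)
}

## render one isotropic Gaussian blob into an ImageVolume (independent of the
## simulator's renderer: direct triple loop over the full grid)
renderBlobVolume <- function(dim = c(40L, 48L, 48L), voxelSize = c(3, 2, 2),
                             center = c(48, 48, 60), sigma = 4,
                             amplitude = 100, background = 0) {
  zc <- (seq_len(dim[1]) - 0.5) * voxelSize[1]
  yc <- (seq_len(dim[2]) - 0.5) * voxelSize[2]
  xc <- (seq_len(dim[3]) - 0.5) * voxelSize[3]
  gz <- exp(-(zc - center[3])^2 / (2 * sigma^2))
  gy <- exp(-(yc - center[2])^2 / (2 * sigma^2))
  gx <- exp(-(xc - center[1])^2 / (2 * sigma^2))
  vox <- background + amplitude * outer(outer(gz, gy), gx)
  ImageVolume(vox, voxelSize = voxelSize, frame = 0L, channel = "green")
}

## run the in-memory pipeline on a preset and return the distance to truth
presetDistance <- function(preset, seed, align = TRUE, twoChannel = TRUE,
                           keepEvery = 1L, ...) {
  sim <- simulateEmbryo(simulationPreset(preset, seed = as.integer(seed), ...))
  ser <- subsampleTime(sim$series, keepEvery)
  res <- traceSeries(ser, align = align, twoChannel = twoChannel)
  ev <- suppressWarnings(evaluateAgainstTruth(
    res$forest, truthForest(sim$truth, keepEvery = keepEvery),
    transforms = res$alignment))
  ev$totalDistance
}
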