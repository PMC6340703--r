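linearForest <- function(lengths, frames = 0L) {
  ## build a LineageForest that is a single track of `lengths` frames
  n <- lengths
  nodes <- data.frame(id = seq_len(n), tree = 1L, frame = seq_len(n) - 1L,
                      x = 0, y = 0, z = 0, channel = "green", synthetic = FALSE)
  edges <- if (n > 1) data.frame(from = seq_len(n - 1L), to = 2:n) else
    data.frame(from = integer(), to = integer())
  trees <- data.frame(tree = 1L, channel = "green", rootFrame = 0L,
                      rootX = 0, rootY = 0, rootZ = 0)
  LineageForest(nodes, edges, trees)
}

test_that("condensation counts timepoints per branch", {
  ## linear 12-frame track -> a single root node storing 12
  ct <- condenseTree(linearForest(12L), 1L)
  expect_identical(condensedSize(ct), 1L)
  expect_equal(ct@root$lengths, 12)
  ## division at frame 5, daughters to frame 10 -> root 6, tuple (5, 5)
  nodes <- data.frame(id = 1:16, tree = 1L,
                      frame = c(0:5, 6:10, 6:10), x = 0, y = 0, z = 0,
                      channel = "green", synthetic = FALSE)
  edges <- data.frame(from = c(1:5, 6, 7:10, 6, 12:15),
                      to = c(2:6, 7, 8:11, 12, 13:16))
  trees <- data.frame(tree = 1L, channel = "green", rootFrame = 0L,
                      rootX = 0, rootY = 0, rootZ = 0)
  ct2 <- condenseTree(LineageForest(nodes, edges, trees), 1L)
  expect_identical(condensedSize(ct2), 2L)
  expect_equal(ct2@root$lengths, 6)
  expect_equal(ct2@root$children[[1]]$lengths, c(5, 5))
  ## node count = divisions + 1 on simulated trees
  sim <- simulateEmbryo(simulationPreset("rotating", seed = 6L))
  forest <- truthForest(sim$truth)
  for (ct3 in condenseForest(forest)) {
    ndiv <- condensedSize(ct3) - 1L
    expect_identical(condensedSize(ct3), ndiv + 1L)
    expect_gte(min(unlist(rapply(ct3@root, identity, how = "list"))), 1)
  }
})

test_that("zssDistance equals the naive edit-distance oracle on small trees", {
  set.seed(91)
  costs <- treeEditCosts()
  for (i in 1:120) {
    a <- randomCondensedTree(5L)
    b <- randomCondensedTree(5L)
    expect_equal(zssDistance(a, b, costs), naiveTreeDist(a, b, costs),
                 info = sprintf("pair %d", i))
  }
  ## also under asymmetric costs and the length-difference update
  costs2 <- treeEditCosts(insert = 2, remove = 0.5, update = "length")
  for (i in 1:40) {
    a <- randomCondensedTree(4L)
    b <- randomCondensedTree(4L)
    expect_equal(zssDistance(a, b, costs2), naiveTreeDist(a, b, costs2))
  }
})

test_that("zssDistance handles the forced small cases", {
  one <- CondensedTree(list(lengths = 5, children = list()))
  oneKid <- CondensedTree(list(lengths = 5, children = list(
    list(lengths = c(2, 2), children = list()))))
  expect_equal(zssDistance(one, one), 0)
  expect_equal(zssDistance(one, oneKid), 1)      # one insertion
  relabel <- CondensedTree(list(lengths = 7, children = list()))
  expect_equal(zssDistance(one, relabel), 1)     # one update
  expect_equal(zssDistance(oneKid, oneKid), 0)
})

test_that("zssDistance is a metric under unit costs", {
  set.seed(92)
  costs <- treeEditCosts()
  for (i in 1:120) {
    a <- randomCondensedTree(8L)
    b <- randomCondensedTree(8L)
    c_ <- randomCondensedTree(8L)
    dab <- zssDistance(a, b, costs)
    dba <- zssDistance(b, a, costs)
    dac <- zssDistance(a, c_, costs)
    dbc <- zssDistance(b, c_, costs)
    expect_equal(zssDistance(a, a, costs), 0)
    expect_equal(dab, dba)
    expect_lte(dac, dab + dbc)
  }
})

test_that("relinking one early timepoint changes the distance boundedly", {
  ## the motivation for condensation: an early tracking slip must not cost
  ## proportionally to the length of the affected branch
  mk <- function(firstLen) CondensedTree(list(lengths = 10, children = list(
    list(lengths = c(firstLen, 40), children = list()))))
  base <- mk(40)
  slipped <- mk(39)     # one timepoint reassigned near the branch start
  d <- zssDistance(base, slipped)
  expect_lte(d, 1)      # a single update, not ~40
})

test_that("forest matching recovers permutations of origins", {
  set.seed(93)
  origins <- matrix(runif(12, -30, 30), 4, 3)
  mkT <- function(o, fr = 0L) CondensedTree(list(lengths = 10, children = list()),
                                            rootFrame = fr, origin = o)
  a <- lapply(1:4, function(i) mkT(origins[i, ]))
  perm <- c(3L, 1L, 4L, 2L)
  b <- lapply(perm, function(i) mkT(origins[i, ]))
  m <- matchForests(a, b)
  ## pair i of a must map to the b-tree carrying the same origin
  expect_identical(perm[m$pairs$b], m$pairs$a)
  expect_lt(max(m$pairs$cost), 1e-9)
  ## 4 vs 3: one reported unmatched
  m2 <- matchForests(a, b[1:3])
  expect_identical(nrow(m2$pairs), 3L)
  expect_length(m2$unmatchedA, 1L)
  expect_error(matchForests(list(), list()), "empty")
  ## temporal term separates equal positions
  a2 <- list(mkT(c(0, 0, 0), 0L), mkT(c(0, 0, 0), 5L))
  b2 <- list(mkT(c(0, 0, 0), 5L), mkT(c(0, 0, 0), 0L))
  m3 <- matchForests(a2, b2, timeWeight = 1)
  expect_identical(m3$pairs$b, c(2L, 1L))
})

test_that("spurious trees are flagged by root frame and track length", {
  long <- CondensedTree(list(lengths = 50, children = list()), rootFrame = 0L)
  late <- CondensedTree(list(lengths = 50, children = list()), rootFrame = 7L)
  short <- CondensedTree(list(lengths = 3, children = list()), rootFrame = 0L)
  expect_false(flagSpurious(long, minTrackLength = 10, expectedRootFrame = 0L))
  expect_true(flagSpurious(late, minTrackLength = 10, expectedRootFrame = 0L))
  expect_true(flagSpurious(short, minTrackLength = 10, expectedRootFrame = 0L))
})

test_that("total forest distance sums pairs and excludes flagged trees", {
  set.seed(94)
  a <- lapply(1:4, function(i)
    CondensedTree(list(lengths = 10 + i, children = list()),
                  origin = c(i * 10, 0, 0)))
  ## identity
  self <- totalForestDistance(a, a)
  expect_equal(self$total, 0)
  ## an extra flagged junk tree must not change the total
  junk <- CondensedTree(list(lengths = 2, children = list()), rootFrame = 9L,
                        origin = c(99, 0, 0))
  withJunk <- totalForestDistance(c(a, list(junk)), a,
                                  spuriousA = c(rep(FALSE, 4), TRUE))
  expect_equal(withJunk$total, 0)
  expect_identical(withJunk$excludedA, 1L)
  ## unmatched non-spurious trees pay their full node cost
  bigger <- c(a, list(CondensedTree(list(lengths = 30, children = list(
    list(lengths = c(5, 5), children = list()))), origin = c(99, 0, 0))))
  d <- totalForestDistance(bigger, a)
  expect_equal(d$total, 2)   # 2 nodes x unit removal
})

test_that("condensed trees export to Newick with branch tuples", {
  ct <- CondensedTree(list(lengths = 6, children = list(
    list(lengths = c(5, 5), children = list()))))
  expect_identical(condensedToNewick(ct), "([5,5])[6];")
})
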