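## Frame-to-frame linking with division detection and lineage-forest
## extraction, run separately on the red subset and the green-minus-red
## subset so that each channel poses a simpler, disjoint tracking problem.

.LAP_BIG <- 1e9

#' Solve a linear assignment problem
#'
#' Exact minimum-cost one-to-one assignment (Jonker-Volgenant style shortest
#' augmenting paths). Rectangular matrices are allowed; every row of the
#' smaller dimension is assigned.
#'
#' @param cost numeric cost matrix.
#' @return integer vector a with length nrow(cost): a[i] = column assigned to
#'   row i (NA if ncol < nrow leaves row i unassigned).
#' @export
solveAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) {
    cost <- t(cost); transposed <- TRUE
    tmp <- n; n <- nrow(cost); m <- ncol(cost)
  }
  ## shortest augmenting path with potentials; columns 0..m (0 = virtual)
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)          # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          if (j == 0L) u[p[1L]] <- u[p[1L]] + delta
          else {
            u[p[j + 1L]] <- u[p[j + 1L]] + delta
            v[j + 1L] <- v[j + 1L] - delta
          }
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  if (transposed) {
    back <- rep(NA_integer_, m)
    for (i in seq_len(n)) if (!is.na(assign[i])) back[assign[i]] <- i
    return(back)
  }
  assign
}

#' Link spots between two consecutive frames
#'
#' First an optimal one-to-one assignment minimizing total Euclidean distance
#' subject to `maxLinkDistance`; then every unassigned next-frame spot is
#' attached as a second daughter to an assigned mother within
#' `divisionDistance` that still has out-degree < 2. Among candidate
#' mothers the one minimizing the division-symmetry error
#' ||midpoint(assigned daughter, candidate) - mother|| is chosen (daughters
#' of a division straddle the mother, so the midpoint of a true daughter
#' pair falls onto the mother while a false pairing lands half a cell
#' spacing away); ties break by mother-daughter distance, then by smallest
#' mother id. Remaining unassigned next-frame spots start new tracks.
#'
#' @param spotsT,spotsNext spot data.frames of frames t and t + 1.
#' @param params A \linkS4class{LinkingParams}.
#' @return data.frame(from, to) of spot-id edges.
#' @export
linkFrames <- function(spotsT, spotsNext, params = linkingParams()) {
  empty <- data.frame(from = integer(), to = integer())
  if (!nrow(spotsT) || !nrow(spotsNext)) return(empty)
  d <- crossDist(spotCoords(spotsT), spotCoords(spotsNext))
  cost <- d
  cost[cost > params@maxLinkDistance] <- .LAP_BIG
  a <- solveAssignment(cost)
  edges <- empty
  outdeg <- setNames(integer(nrow(spotsT)), spotsT$id)
  assignedNext <- logical(nrow(spotsNext))
  for (i in seq_len(nrow(spotsT))) {
    j <- a[i]
    if (!is.na(j) && d[i, j] <= params@maxLinkDistance) {
      edges <- rbind(edges, data.frame(from = spotsT$id[i], to = spotsNext$id[j]))
      outdeg[i] <- 1L
      assignedNext[j] <- TRUE
    }
  }
  ## division attachment for unassigned daughters, best symmetry first
  firstDaughter <- setNames(edges$to, edges$from)
  nextPos <- spotCoords(spotsNext)
  pending <- which(!assignedNext)
  while (length(pending)) {
    best <- NULL
    for (j in pending) {
      cand <- which(outdeg == 1L & d[, j] <= params@divisionDistance)
      for (m in cand) {
        d1 <- nextPos[match(firstDaughter[as.character(spotsT$id[m])],
                            spotsNext$id), ]
        err <- sqrt(sum(((d1 + nextPos[j, ]) / 2 -
                           spotCoords(spotsT)[m, ])^2))
        key <- c(err, d[m, j], spotsT$id[m])
        if (is.null(best) || err < best$key[1] - 1e-12 ||
            (abs(err - best$key[1]) <= 1e-12 &&
               (d[m, j] < best$key[2] - 1e-12 ||
                  (abs(d[m, j] - best$key[2]) <= 1e-12 &&
                     spotsT$id[m] < best$key[3])))) {
          best <- list(j = j, m = m, key = key)
        }
      }
    }
    if (is.null(best)) break
    edges <- rbind(edges, data.frame(from = spotsT$id[best$m],
                                     to = spotsNext$id[best$j]))
    outdeg[best$m] <- 2L
    pending <- setdiff(pending, best$j)
  }
  rownames(edges) <- NULL
  edges
}

#' Build a track graph over a (single-channel-subset) series
#'
#' Concatenates \code{\link{linkFrames}} over consecutive frames. With
#' `allowGap`, a track ending at frame t is joined to a track starting at
#' frame t + 2 within `maxLinkDistance` through a flagged synthetic midpoint
#' node at t + 1.
#'
#' @param series aligned, validated \linkS4class{SpotSeries} (one channel
#'   subset).
#' @param params A \linkS4class{LinkingParams}.
#' @return A \linkS4class{TrackGraph}.
#' @export
buildTrackGraph <- function(series, params = linkingParams()) {
  s <- spots(series)
  nodes <- data.frame(id = s$id, frame = s$frame, x = s$x, y = s$y, z = s$z,
                      synthetic = FALSE)
  edges <- data.frame(from = integer(), to = integer())
  n <- nFrames(series)
  if (n >= 2L) for (fr in 0:(n - 2L)) {
    e <- linkFrames(s[s$frame == fr, , drop = FALSE],
                    s[s$frame == fr + 1L, , drop = FALSE], params)
    if (nrow(e)) edges <- rbind(edges, e)
  }
  if (params@allowGap && n >= 3L) {
    nextId <- if (nrow(nodes)) max(nodes$id) + 1L else 1L
    for (fr in 0:(n - 3L)) {
      ## track ends at fr: nodes at fr with no outgoing edge
      ends <- nodes[nodes$frame == fr & !nodes$id %in% edges$from &
                      !nodes$synthetic, , drop = FALSE]
      starts <- nodes[nodes$frame == fr + 2L & !nodes$id %in% edges$to &
                        !nodes$synthetic, , drop = FALSE]
      if (!nrow(ends) || !nrow(starts)) next
      d <- crossDist(as.matrix(ends[, c("x", "y", "z")]),
                     as.matrix(starts[, c("x", "y", "z")]))
      cost <- d
      cost[cost > params@maxLinkDistance] <- .LAP_BIG
      a <- solveAssignment(cost)
      for (i in seq_len(nrow(ends))) {
        j <- a[i]
        if (is.na(j) || d[i, j] > params@maxLinkDistance) next
        mid <- data.frame(id = nextId, frame = fr + 1L,
                          x = (ends$x[i] + starts$x[j]) / 2,
                          y = (ends$y[i] + starts$y[j]) / 2,
                          z = (ends$z[i] + starts$z[j]) / 2,
                          synthetic = TRUE)
        nodes <- rbind(nodes, mid)
        edges <- rbind(edges,
                       data.frame(from = c(ends$id[i], nextId),
                                  to = c(nextId, starts$id[j])))
        nextId <- nextId + 1L
      }
    }
  }
  TrackGraph(nodes, edges)
}

#' Green spots that do not colocalize with red spots
#'
#' The complement of the colocalized set: green spots with no red spot within
#' `colocDistance` (closed ball). Together with the red subset this splits
#' the tracking problem in two.
#'
#' @param greenSpots,redSpots same-frame spot data.frames.
#' @param colocDistance micrometres.
#' @return data.frame of the non-colocalized green spots.
#' @export
subsetGreenMinusRed <- function(greenSpots, redSpots, colocDistance) {
  if (!nrow(greenSpots) || !nrow(redSpots)) return(greenSpots)
  d <- crossDist(spotCoords(greenSpots), spotCoords(redSpots))
  greenSpots[apply(d, 1, min) > colocDistance, , drop = FALSE]
}

## extract rooted trees (connected components) from a track graph
graphToForest <- function(graph, channel) {
  nodes <- graph@nodes; edges <- graph@edges
  if (!nrow(nodes))
    return(LineageForest(
      data.frame(id = integer(), tree = integer(), frame = integer(),
                 x = numeric(), y = numeric(), z = numeric(),
                 channel = character(), synthetic = logical()),
      data.frame(from = integer(), to = integer()),
      data.frame(tree = integer(), channel = character(), rootFrame = integer(),
                 rootX = numeric(), rootY = numeric(), rootZ = numeric())))
  idx <- seq_len(nrow(nodes))
  pairs <- cbind(match(edges$from, nodes$id), match(edges$to, nodes$id))
  comp <- connectedComponents(nrow(nodes), pairs)
  ## stable tree numbering: by (root frame, root id)
  indeg <- nodes$id %in% edges$to
  roots <- nodes[!indeg, , drop = FALSE]
  rootComp <- comp[match(roots$id, nodes$id)]
  ord <- order(roots$frame, roots$id)
  treeOfComp <- integer(max(comp))
  treeOfComp[rootComp[ord]] <- seq_along(ord)
  nodes$tree <- treeOfComp[comp]
  nodes$channel <- channel
  roots <- roots[ord, , drop = FALSE]
  trees <- data.frame(tree = seq_len(nrow(roots)), channel = channel,
                      rootFrame = roots$frame, rootX = roots$x,
                      rootY = roots$y, rootZ = roots$z)
  LineageForest(nodes[, c("id", "tree", "frame", "x", "y", "z", "channel",
                          "synthetic")], edges, trees)
}

#' Two-channel lineage tracing
#'
#' Builds a track graph per channel subset independently (the red progeny of
#' the converted cell, and the green-minus-red remainder), extracts rooted
#' trees and returns the combined forest. For an acquisition starting at the
#' 4-cell stage the expected outcome is 1 red tree and 3 green trees.
#'
#' @param redSeries,greenMinusRedSeries aligned \linkS4class{SpotSeries} over
#'   the same frame range.
#' @param params A \linkS4class{LinkingParams}.
#' @return A \linkS4class{LineageForest}; trees are tagged by channel.
#' @export
traceTwoChannel <- function(redSeries, greenMinusRedSeries,
                            params = linkingParams()) {
  if (nFrames(redSeries) != nFrames(greenMinusRedSeries))
    stopf("frame-range mismatch: red has %d frame(s), green-minus-red %d",
          nFrames(redSeries), nFrames(greenMinusRedSeries))
  redForest <- graphToForest(buildTrackGraph(redSeries, params), "red")
  greenForest <- graphToForest(buildTrackGraph(greenMinusRedSeries, params), "green")
  combineForests(redForest, greenForest)
}

## concatenate two forests; node ids are offset only on collision (subsets of
## one series already have disjoint spot ids)
combineForests <- function(a, b) {
  offsetTree <- nrow(a@trees)
  bn <- b@nodes; be <- b@edges; bt <- b@trees
  if (nrow(bn) && any(bn$id %in% a@nodes$id)) {
    offsetId <- max(a@nodes$id)
    bn$id <- bn$id + offsetId
    if (nrow(be)) {
      be$from <- be$from + offsetId
      be$to <- be$to + offsetId
    }
  }
  if (nrow(bn)) bn$tree <- bn$tree + offsetTree
  if (nrow(bt)) bt$tree <- bt$tree + offsetTree
  LineageForest(rbind(a@nodes, bn), rbind(a@edges, be), rbind(a@trees, bt))
}
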