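## Comparative analysis of lineage trees: condensation to division events,
## the Zhang-Shasha ordered-tree edit distance with user-defined costs,
## assignment of forests by their origins, spurious-tree exclusion and the
## summed total distance.

## canonical string signature of a condensed node (used for child ordering)
nodeSignature <- function(node) {
  paste0("[", paste(node$lengths, collapse = ","), ":",
         paste(vapply(node$children, nodeSignature, character(1)), collapse = ""),
         "]")
}

nodeCount <- function(node) 1L + sum(vapply(node$children, nodeCount, integer(1)))

#' Condense a lineage tree to its division events
#'
#' Creates one root node for the tree origin, storing the number of
#' timepoints tracked until the first division or track end, and one node
#' per division storing, for each daughter branch, the number of timepoints
#' the daughter was tracked until its next division or track end. Daughters
#' are put into a canonical order (branch length, then subtree node count,
#' then subtree signature), which makes the ordered-tree edit distance well
#' defined on the unordered biological daughters.
#'
#' @param forest A \linkS4class{LineageForest}.
#' @param tree tree number within the forest.
#' @return A \linkS4class{CondensedTree}.
#' @export
condenseTree <- function(forest, tree) {
  nodes <- forest@nodes[forest@nodes$tree == tree, , drop = FALSE]
  if (!nrow(nodes)) stopf("tree %s not present in forest", tree)
  edges <- forest@edges[forest@edges$from %in% nodes$id &
                          forest@edges$to %in% nodes$id, , drop = FALSE]
  children <- split(edges$to, factor(edges$from, levels = nodes$id))
  rootId <- nodes$id[!nodes$id %in% edges$to]
  stopifnot(length(rootId) == 1L)
  ## follow a chain from `start` until division or end; returns the number of
  ## timepoints in the chain and the division node's children (if any)
  chain <- function(start) {
    len <- 1L
    cur <- start
    repeat {
      ch <- children[[as.character(cur)]]
      if (length(ch) != 1L) return(list(length = len, splitInto = ch))
      cur <- ch
      len <- len + 1L
    }
  }
  buildDivision <- function(daughters) {
    parts <- lapply(daughters, function(d) {
      cc <- chain(d)
      node <- if (length(cc$splitInto)) buildDivision(cc$splitInto) else NULL
      list(length = cc$length, node = node)
    })
    key <- vapply(parts, function(p) {
      nc <- if (is.null(p$node)) 0L else nodeCount(p$node)
      sig <- if (is.null(p$node)) "" else nodeSignature(p$node)
      sprintf("%012d|%012d|%s", p$length, nc, sig)
    }, character(1))
    parts <- parts[order(key)]
    list(lengths = vapply(parts, function(p) as.numeric(p$length), numeric(1)),
         children = Filter(Negate(is.null), lapply(parts, `[[`, "node")))
  }
  rootChain <- chain(rootId)
  rootNode <- list(lengths = as.numeric(rootChain$length),
                   children = if (length(rootChain$splitInto))
                     list(buildDivision(rootChain$splitInto)) else list())
  info <- forest@trees[forest@trees$tree == tree, , drop = FALSE]
  CondensedTree(rootNode, rootFrame = info$rootFrame,
                origin = c(info$rootX, info$rootY, info$rootZ))
}

#' Condense every tree of a forest
#'
#' @param forest A \linkS4class{LineageForest}.
#' @return list of \linkS4class{CondensedTree}.
#' @export
condenseForest <- function(forest) {
  lapply(forest@trees$tree, function(tr) condenseTree(forest, tr))
}

## flatten a condensed tree into Zhang-Shasha postorder arrays:
## labels (list), lml (index of the leftmost leaf under each node)
zssFlatten <- function(tree) {
  labels <- list(); lml <- integer()
  walk <- function(node) {
    childIdx <- vapply(node$children, walk, integer(1))
    idx <- length(labels) + 1L
    labels[[idx]] <<- node$lengths
    lml[idx] <<- if (length(childIdx)) lml[childIdx[1L]] else idx
    idx
  }
  walk(tree@root)
  list(labels = labels, lml = lml, n = length(labels))
}

#' Zhang-Shasha edit distance between condensed trees
#'
#' Exact ordered-tree edit distance: the minimum total cost of node
#' insertions, removals and updates transforming `a` into `b`, via the
#' dynamic program over keyroots and leftmost-leaf decompositions.
#'
#' @param a,b \linkS4class{CondensedTree} objects (canonically ordered by
#'   construction).
#' @param costs A \linkS4class{TreeEditCosts}.
#' @return numeric edit cost.
#' @export
zssDistance <- function(a, b, costs = treeEditCosts()) {
  A <- zssFlatten(a); B <- zssFlatten(b)
  n <- A$n; m <- B$n
  ins <- costs@insert; rem <- costs@remove; upd <- costs@update
  keyroots <- function(f) {
    seen <- logical(f$n + 1L)
    kr <- integer()
    for (i in f$n:1L) {
      if (!seen[f$lml[i]]) {
        kr <- c(i, kr)
        seen[f$lml[i]] <- TRUE
      }
    }
    sort(kr)
  }
  krA <- keyroots(A); krB <- keyroots(B)
  treedist <- matrix(0, n, m)
  for (i in krA) for (j in krB) {
    li <- A$lml[i]; lj <- B$lml[j]
    ni <- i - li + 1L; nj <- j - lj + 1L
    fd <- matrix(0, ni + 1L, nj + 1L)
    for (x in seq_len(ni)) fd[x + 1L, 1L] <- fd[x, 1L] + rem
    for (y in seq_len(nj)) fd[1L, y + 1L] <- fd[1L, y] + ins
    for (x in seq_len(ni)) {
      nx <- li + x - 1L
      for (y in seq_len(nj)) {
        ny <- lj + y - 1L
        if (A$lml[nx] == li && B$lml[ny] == lj) {
          fd[x + 1L, y + 1L] <- min(
            fd[x, y + 1L] + rem,
            fd[x + 1L, y] + ins,
            fd[x, y] + upd(A$labels[[nx]], B$labels[[ny]]))
          treedist[nx, ny] <- fd[x + 1L, y + 1L]
        } else {
          px <- A$lml[nx] - li  # size of the prefix forest left of subtree nx
          py <- B$lml[ny] - lj
          fd[x + 1L, y + 1L] <- min(
            fd[x, y + 1L] + rem,
            fd[x + 1L, y] + ins,
            fd[px + 1L, py + 1L] + treedist[nx, ny])
        }
      }
    }
  }
  treedist[n, m]
}

#' Match two forests by their origins
#'
#' Optimal assignment between the trees of two forests minimizing the summed
#' spatial-plus-temporal distance of their origins:
#' ||origin_a - origin_b|| + timeWeight * |frame_a - frame_b|. Surplus trees
#' of the larger forest are reported unmatched.
#'
#' @param a,b lists of \linkS4class{CondensedTree}.
#' @param timeWeight micrometres per frame (default 1).
#' @return list(pairs = data.frame(a, b, cost), unmatchedA, unmatchedB =
#'   integer indices).
#' @export
matchForests <- function(a, b, timeWeight = 1) {
  if (!length(a) && !length(b)) stopf("both forests are empty")
  if (!length(a) || !length(b))
    return(list(pairs = data.frame(a = integer(), b = integer(), cost = numeric()),
                unmatchedA = seq_along(a), unmatchedB = seq_along(b)))
  cost <- matrix(0, length(a), length(b))
  for (i in seq_along(a)) for (j in seq_along(b)) {
    cost[i, j] <- sqrt(sum((a[[i]]@origin - b[[j]]@origin)^2)) +
      timeWeight * abs(a[[i]]@rootFrame - b[[j]]@rootFrame)
  }
  assign <- solveAssignment(cost)
  if (length(a) <= length(b)) {
    pairs <- data.frame(a = seq_along(a), b = assign,
                        cost = cost[cbind(seq_along(a), assign)])
  } else {
    rows <- which(!is.na(assign))
    pairs <- data.frame(a = rows, b = assign[rows],
                        cost = cost[cbind(rows, assign[rows])])
  }
  list(pairs = pairs,
       unmatchedA = setdiff(seq_along(a), pairs$a),
       unmatchedB = setdiff(seq_along(b), pairs$b))
}

#' Flag a spurious tree
#'
#' A tree is spurious iff its root frame differs from the expected root frame
#' (acquisitions start with all founder cells present) or its total tracked
#' timepoints fall below `minTrackLength`. Spurious trees come from bad
#' segmentation/tracking and are excluded from distance totals; they already
#' affect the distance of the tree they detached from.
#'
#' @param tree A \linkS4class{CondensedTree}.
#' @param minTrackLength frames.
#' @param expectedRootFrame frame (default 0).
#' @return logical.
#' @export
flagSpurious <- function(tree, minTrackLength, expectedRootFrame = 0L) {
  tree@rootFrame != expectedRootFrame ||
    condensedTimepoints(tree) < minTrackLength
}

#' Total edit distance between two condensed forests
#'
#' Excludes flagged spurious trees, matches the remainder by origins and sums
#' the pairwise Zhang-Shasha distances; unmatched non-spurious trees
#' contribute their full insertion/removal cost (node count times the
#' per-node cost).
#'
#' @param a,b lists of \linkS4class{CondensedTree}.
#' @param costs A \linkS4class{TreeEditCosts}.
#' @param timeWeight passed to \code{\link{matchForests}}.
#' @param spuriousA,spuriousB logical vectors flagging spurious trees
#'   (default: none).
#' @return list(total, pairs = per-pair breakdown, excludedA, excludedB,
#'   unmatchedA, unmatchedB).
#' @export
totalForestDistance <- function(a, b, costs = treeEditCosts(), timeWeight = 1,
                                spuriousA = logical(length(a)),
                                spuriousB = logical(length(b))) {
  keepA <- which(!spuriousA); keepB <- which(!spuriousB)
  if (!length(keepA) && !length(keepB))
    return(list(total = 0, pairs = data.frame(), excludedA = sum(spuriousA),
                excludedB = sum(spuriousB), unmatchedA = integer(),
                unmatchedB = integer()))
  if (!length(keepA) || !length(keepB)) {
    surplus <- if (length(keepA)) a[keepA] else b[keepB]
    perNode <- if (length(keepA)) costs@remove else costs@insert
    total <- sum(vapply(surplus, condensedSize, integer(1))) * perNode
    return(list(total = total, pairs = data.frame(),
                excludedA = sum(spuriousA), excludedB = sum(spuriousB),
                unmatchedA = keepA, unmatchedB = keepB))
  }
  mt <- matchForests(a[keepA], b[keepB], timeWeight)
  pairs <- mt$pairs
  pairs$a <- keepA[pairs$a]; pairs$b <- keepB[pairs$b]
  pairs$distance <- vapply(seq_len(nrow(pairs)), function(k)
    zssDistance(a[[pairs$a[k]]], b[[pairs$b[k]]], costs), numeric(1))
  unmatchedA <- keepA[mt$unmatchedA]; unmatchedB <- keepB[mt$unmatchedB]
  total <- sum(pairs$distance) +
    sum(vapply(a[unmatchedA], condensedSize, integer(1))) * costs@remove +
    sum(vapply(b[unmatchedB], condensedSize, integer(1))) * costs@insert
  list(total = total, pairs = pairs, excludedA = sum(spuriousA),
       excludedB = sum(spuriousB), unmatchedA = unmatchedA,
       unmatchedB = unmatchedB)
}

#' Newick string of a condensed tree
#'
#' Branch-length tuples are carried in comment blocks, e.g.
#' \code{[5,5]}; useful for quick inspection with standard tree viewers.
#'
#' @param tree A \linkS4class{CondensedTree}.
#' @return character Newick string.
#' @export
condensedToNewick <- function(tree) {
  fmt <- function(node) {
    lab <- paste0("[", paste(node$lengths, collapse = ","), "]")
    if (!length(node$children)) return(lab)
    paste0("(", paste(vapply(node$children, fmt, character(1)), collapse = ","),
           ")", lab)
  }
  paste0(fmt(tree@root), ";")
}
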