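#' @import methods
NULL

## ---------------------------------------------------------------------------
## SpotSeries
## ---------------------------------------------------------------------------

#' SpotSeries: per-frame, per-channel nucleus candidates
#'
#' The central container of the pipeline: one row per detected (or simulated)
#' nucleus candidate, with 0-based contiguous frame indices and a closed
#' channel set of \code{"green"} (global label) and \code{"red"}
#' (photoconverted sub-population). Positions are always physical micrometres,
#' never voxel indices, because the axial plane spacing (3 um by default) is
#' strongly anisotropic.
#'
#' @slot spots data.frame with columns id, frame, channel, x, y, z, radius,
#'   intensity.
#' @slot nFrames integer number of frames (frames are 0..nFrames-1).
#' @slot frameInterval acquisition interval in minutes.
#' @slot voxelSize numeric(3), micrometres per voxel in (z, y, x) order.
#' @exportClass SpotSeries
setClass("SpotSeries",
  representation(spots = "data.frame", nFrames = "integer",
                 frameInterval = "numeric", voxelSize = "numeric"))

setValidity("SpotSeries", function(object) {
  s <- object@spots
  miss <- setdiff(.SPOT_COLUMNS, names(s))
  if (length(miss)) return(paste("missing spot columns:", paste(miss, collapse = ", ")))
  if (length(object@nFrames) != 1L || is.na(object@nFrames) || object@nFrames < 0L)
    return("nFrames must be a single non-negative integer")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (z, y, x)")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  if (nrow(s)) {
    if (anyDuplicated(s$id)) return("spot ids must be unique within a SpotSeries")
    if (!all(s$channel %in% .CHANNELS))
      return(paste("unknown channel label(s):",
                   paste(unique(setdiff(s$channel, .CHANNELS)), collapse = ", ")))
    if (any(s$frame < 0L) || any(s$frame >= object@nFrames))
      return("spot frame indices must lie in [0, nFrames)")
    if (any(s$radius <= 0)) return("spot radius must be > 0")
    if (any(s$intensity < 0)) return("spot intensity must be >= 0")
  }
  TRUE
})

#' Construct a SpotSeries
#'
#' @param spots data.frame of spots (see \linkS4class{SpotSeries}); an `id`
#'   column is assigned if absent.
#' @param nFrames number of frames; defaults to `max(frame) + 1`.
#' @param frameInterval minutes between frames.
#' @param voxelSize micrometres per voxel, (z, y, x).
#' @return A \linkS4class{SpotSeries}.
#' @export
SpotSeries <- function(spots = emptySpotFrame(), nFrames = NULL,
                       frameInterval = 15, voxelSize = c(3, 2, 2)) {
  if (is.null(spots$id)) spots$id <- seq_len(nrow(spots))
  spots <- as.data.frame(spots)[, .SPOT_COLUMNS]
  spots$id <- as.integer(spots$id)
  spots$frame <- as.integer(spots$frame)
  spots$channel <- as.character(spots$channel)
  rownames(spots) <- NULL
  if (is.null(nFrames)) nFrames <- if (nrow(spots)) max(spots$frame) + 1L else 0L
  new("SpotSeries", spots = spots, nFrames = as.integer(nFrames),
      frameInterval = as.numeric(frameInterval), voxelSize = as.numeric(voxelSize))
}

#' @rdname SpotSeries
#' @param object,x A SpotSeries.
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))

#' @rdname SpotSeries
#' @export
setMethod("spots", "SpotSeries", function(x) x@spots)

#' @rdname SpotSeries
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname SpotSeries
#' @export
setMethod("nFrames", "SpotSeries", function(x) x@nFrames)

#' @rdname SpotSeries
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname SpotSeries
#' @export
setMethod("frameInterval", "SpotSeries", function(x) x@frameInterval)

#' @rdname SpotSeries
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname SpotSeries
#' @export
setMethod("voxelSize", "SpotSeries", function(x) x@voxelSize)

#' Extract the spots of one frame (optionally one channel)
#'
#' @param x A SpotSeries.
#' @param frame 0-based frame index.
#' @param channel optional \code{"green"} or \code{"red"}.
#' @return data.frame of spots.
#' @export
frameSpots <- function(x, frame, channel = NULL) {
  s <- x@spots[x@spots$frame == frame, , drop = FALSE]
  if (!is.null(channel)) s <- s[s$channel == channel, , drop = FALSE]
  rownames(s) <- NULL
  s
}

setMethod("show", "SpotSeries", function(object) {
  s <- object@spots
  cat("SpotSeries with", object@nFrames, "frame(s),", nrow(s), "spot(s)\n")
  cat("  frame interval:", object@frameInterval, "min; voxel size (z,y,x):",
      paste(object@voxelSize, collapse = " x "), "um\n")
  if (nrow(s))
    cat("  per channel:", paste(sprintf("%s=%d", .CHANNELS,
        vapply(.CHANNELS, function(ch) sum(s$channel == ch), integer(1))),
        collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ImageVolume
## ---------------------------------------------------------------------------

#' ImageVolume: a single-channel 3D stack at one timepoint
#'
#' Voxels are stored (z, y, x); the physical centre of voxel (k, j, i)
#' (0-based) is ((i + 0.5) dx, (j + 0.5) dy, (k + 0.5) dz), which keeps spot
#' detection and the synthetic renderer mutually consistent.
#'
#' @slot voxels 3D numeric array indexed (z, y, x), all values >= 0.
#' @slot voxelSize numeric(3) micrometres per axis (z, y, x).
#' @slot frame integer 0-based time index.
#' @slot channel \code{"green"} or \code{"red"}.
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(voxels = "array", voxelSize = "numeric",
                 frame = "integer", channel = "character"))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array (z, y, x)")
  if (any(object@voxels < 0)) return("voxel values must be >= 0")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values (z, y, x)")
  if (!object@channel %in% .CHANNELS) return("unknown channel")
  if (object@frame < 0L) return("frame must be >= 0")
  TRUE
})

#' @rdname ImageVolume-class
#' @param voxels 3D array (z, y, x).
#' @param voxelSize micrometres per axis (z, y, x).
#' @param frame 0-based frame index.
#' @param channel channel label.
#' @export
ImageVolume <- function(voxels, voxelSize = c(3, 2, 2), frame = 0L,
                        channel = "green") {
  new("ImageVolume", voxels = voxels, voxelSize = as.numeric(voxelSize),
      frame = as.integer(frame), channel = channel)
}

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume frame %d channel %s: %d x %d x %d voxels (z,y,x), %s um\n",
              object@frame, object@channel, d[1], d[2], d[3],
              paste(object@voxelSize, collapse = " x ")))
})

## physical coordinates (x, y, z, in um) of all voxel centres along each axis
voxelAxes <- function(volume) {
  d <- dim(volume@voxels)
  vs <- volume@voxelSize
  list(z = (seq_len(d[1]) - 0.5) * vs[1],
       y = (seq_len(d[2]) - 0.5) * vs[2],
       x = (seq_len(d[3]) - 0.5) * vs[3])
}

## ---------------------------------------------------------------------------
## RigidTransform / ReferenceFrame
## ---------------------------------------------------------------------------

#' RigidTransform: rotation about an origin
#'
#' Maps a world position x to the aligned position R (x - o), where o is the
#' frame origin stored in \code{translation}.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1 (tol 1e-9).
#' @slot translation numeric(3): the origin o, micrometres.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  if (!isRotationMatrix(object@rotation))
    return("rotation must be orthonormal with determinant +1 (tol 1e-9)")
  if (length(object@translation) != 3L) return("translation must be numeric(3)")
  TRUE
})

#' @rdname RigidTransform-class
#' @param rotation 3x3 rotation matrix.
#' @param translation origin o (numeric(3), um).
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' Apply or invert a rigid transform
#'
#' \code{applyTransform} maps world coordinates (rows of an n x 3 matrix, or a
#' spot data.frame) into the aligned frame; \code{invertTransform} returns the
#' transform mapping aligned coordinates back to world coordinates.
#'
#' @param transform A \linkS4class{RigidTransform}.
#' @param x n x 3 coordinate matrix (x, y, z) or a spot data.frame.
#' @return Transformed coordinates of the same shape/class as `x`.
#' @export
applyTransform <- function(transform, x) {
  if (is.data.frame(x)) {
    m <- applyTransform(transform, spotCoords(x))
    x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
    return(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(x, 2, transform@translation) %*% t(transform@rotation)
}

#' @rdname applyTransform
#' @export
invertTransform <- function(transform) {
  ## inverse of x -> R (x - o) is y -> R^T y + o = R^T (y - (-R o))
  RigidTransform(rotation = t(transform@rotation),
                 translation = -as.vector(transform@rotation %*% transform@translation))
}

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform: origin", paste(signif(object@translation, 6), collapse = ", "), "um\n")
  print(signif(object@rotation, 6))
})

#' ReferenceFrame: per-timepoint embryo frame from the two channels
#'
#' The origin sits at the centre of mass (COM) of the green spots; the axis is
#' the unit vector along delta-COM = COM_red - COM_green; roll is the residual
#' rotation (degrees) about that axis fixed by the drift search.
#'
#' @slot origin numeric(3) um.
#' @slot axis unit numeric(3).
#' @slot roll degrees in [0, 360).
#' @exportClass ReferenceFrame
setClass("ReferenceFrame",
  representation(origin = "numeric", axis = "numeric", roll = "numeric"))

setValidity("ReferenceFrame", function(object) {
  if (length(object@origin) != 3L) return("origin must be numeric(3)")
  if (length(object@axis) != 3L || abs(sqrt(sum(object@axis^2)) - 1) > 1e-9)
    return("axis must be a unit 3-vector (tol 1e-9)")
  if (object@roll < 0 || object@roll >= 360) return("roll must lie in [0, 360)")
  TRUE
})

ReferenceFrame <- function(origin, axis, roll = 0) {
  new("ReferenceFrame", origin = as.numeric(origin), axis = as.numeric(axis),
      roll = as.numeric(roll))
}

setMethod("show", "ReferenceFrame", function(object) {
  cat(sprintf("ReferenceFrame: origin (%s) um, axis (%s), roll %g deg\n",
              paste(signif(object@origin, 5), collapse = ", "),
              paste(signif(object@axis, 4), collapse = ", "), object@roll))
})

## ---------------------------------------------------------------------------
## AlignmentResult / CropBox
## ---------------------------------------------------------------------------

#' AlignmentResult: per-frame reference frames, transforms and drift scores
#'
#' @slot referenceFrames list of \linkS4class{ReferenceFrame}, one per frame.
#' @slot transforms list of \linkS4class{RigidTransform}, one per frame.
#' @slot roll chosen roll angle per frame, degrees in [0, 360); frame 0 is 0
#'   by convention.
#' @slot drift per-frame mean nearest-neighbour displacement (um) of the
#'   aligned green spots relative to the previous aligned frame; 0 at frame 0.
#' @slot axisReused logical per frame: TRUE where the red channel gave no
#'   usable orientation and the previous frame's axis was reused.
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(referenceFrames = "list", transforms = "list",
                 roll = "numeric", drift = "numeric", axisReused = "logical"))

setValidity("AlignmentResult", function(object) {
  n <- length(object@transforms)
  if (length(object@referenceFrames) != n || length(object@roll) != n ||
      length(object@drift) != n || length(object@axisReused) != n)
    return("per-frame slots must have equal length")
  if (n && (object@roll[1] != 0)) return("frame 0 roll must be 0 by convention")
  if (any(object@roll < 0 | object@roll >= 360)) return("roll must lie in [0, 360)")
  if (any(object@drift < 0)) return("drift scores must be >= 0")
  TRUE
})

setMethod("show", "AlignmentResult", function(object) {
  n <- length(object@transforms)
  cat("AlignmentResult over", n, "frame(s)\n")
  if (n > 1)
    cat(sprintf("  mean drift (frames 1..%d): %.4g um; rolls: %s%s\n", n - 1,
                mean(object@drift[-1]),
                paste(head(object@roll, 8), collapse = ", "),
                if (n > 8) ", ..." else ""))
  if (any(object@axisReused))
    cat("  axis reused (no red orientation) at frames:",
        paste(which(object@axisReused) - 1L, collapse = ", "), "\n")
})

#' CropBox: axis-aligned bounding box in aligned coordinates
#'
#' @slot min,max numeric(3) corners (x, y, z) um, min < max per axis.
#' @slot margin numeric margin (um) already included in the corners.
#' @exportClass CropBox
setClass("CropBox",
  representation(min = "numeric", max = "numeric", margin = "numeric"))

setValidity("CropBox", function(object) {
  if (length(object@min) != 3L || length(object@max) != 3L)
    return("min and max must be numeric(3)")
  if (!all(object@min < object@max)) return("min must be < max on every axis")
  TRUE
})

CropBox <- function(min, max, margin = 0) {
  new("CropBox", min = as.numeric(min), max = as.numeric(max),
      margin = as.numeric(margin))
}

setMethod("show", "CropBox", function(object) {
  cat(sprintf("CropBox [%s] -> [%s] um (margin %g)\n",
              paste(signif(object@min, 5), collapse = ", "),
              paste(signif(object@max, 5), collapse = ", "), object@margin))
})

## ---------------------------------------------------------------------------
## TrackGraph / LineageForest
## ---------------------------------------------------------------------------

#' TrackGraph: frame-to-frame links over spots
#'
#' Directed edges run mother -> daughter and span exactly one frame step.
#' Every node has in-degree <= 1 and out-degree <= 2 (a division creates
#' exactly two daughters).
#'
#' @slot nodes data.frame: id, frame, x, y, z, synthetic (gap-closed nodes).
#' @slot edges data.frame: from, to (node ids).
#' @exportClass TrackGraph
setClass("TrackGraph", representation(nodes = "data.frame", edges = "data.frame"))

setValidity("TrackGraph", function(object) {
  n <- object@nodes; e <- object@edges
  if (!all(c("id", "frame", "x", "y", "z", "synthetic") %in% names(n)))
    return("nodes need columns id, frame, x, y, z, synthetic")
  if (!all(c("from", "to") %in% names(e))) return("edges need columns from, to")
  if (nrow(e)) {
    if (!all(e$from %in% n$id) || !all(e$to %in% n$id))
      return("edges reference unknown node ids")
    fr <- n$frame[match(e$from, n$id)]; to <- n$frame[match(e$to, n$id)]
    if (!all(to == fr + 1L)) return("edges must connect frame t to frame t+1")
    if (any(table(e$to) > 1L)) return("in-degree must be <= 1")
    if (any(table(e$from) > 2L)) return("out-degree must be <= 2")
  }
  TRUE
})

TrackGraph <- function(nodes, edges) {
  new("TrackGraph", nodes = as.data.frame(nodes), edges = as.data.frame(edges))
}

setMethod("show", "TrackGraph", function(object) {
  ndiv <- if (nrow(object@edges)) sum(table(object@edges$from) == 2L) else 0L
  cat("TrackGraph:", nrow(object@nodes), "node(s),", nrow(object@edges),
      "edge(s),", ndiv, "division(s)\n")
})

#' LineageForest: rooted lineage trees over tracked spots
#'
#' @slot nodes data.frame: id, tree, frame, x, y, z, channel, synthetic.
#' @slot edges data.frame: from, to (mother -> daughter node ids).
#' @slot trees data.frame: tree, channel, rootFrame, rootX, rootY, rootZ.
#' @exportClass LineageForest
setClass("LineageForest",
  representation(nodes = "data.frame", edges = "data.frame", trees = "data.frame"))

setValidity("LineageForest", function(object) {
  n <- object@nodes; e <- object@edges; tr <- object@trees
  if (!all(c("id", "tree", "frame", "x", "y", "z", "channel", "synthetic") %in% names(n)))
    return("nodes need columns id, tree, frame, x, y, z, channel, synthetic")
  if (!all(c("tree", "channel", "rootFrame", "rootX", "rootY", "rootZ") %in% names(tr)))
    return("trees need columns tree, channel, rootFrame, rootX, rootY, rootZ")
  if (nrow(e)) {
    if (any(table(e$to) > 1L)) return("in-degree must be <= 1 (trees)")
    if (any(table(e$from) > 2L)) return("out-degree must be <= 2 (binary divisions)")
  }
  TRUE
})

LineageForest <- function(nodes, edges, trees) {
  new("LineageForest", nodes = as.data.frame(nodes),
      edges = as.data.frame(edges), trees = as.data.frame(trees))
}

#' @rdname LineageForest-class
#' @param x A LineageForest.
#' @export
nTrees <- function(x) nrow(x@trees)

setMethod("show", "LineageForest", function(object) {
  cat("LineageForest:", nrow(object@trees), "tree(s),", nrow(object@nodes),
      "node(s)\n")
  if (nrow(object@trees))
    cat("  channels:", paste(sprintf("%s=%d", .CHANNELS,
        vapply(.CHANNELS, function(ch) sum(object@trees$channel == ch), integer(1))),
        collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## CondensedTree / TreeEditCosts
## ---------------------------------------------------------------------------

#' CondensedTree: division events only, with branch lengths
#'
#' A lineage tree reduced to its division events. The root node represents the
#' tree origin and stores the number of timepoints tracked until the first
#' division (or track end); every other node is one division and stores, per
#' daughter branch, the number of timepoints that daughter was tracked until
#' its next division or track end. Children are held in a canonical order so
#' that the ordered-tree edit distance is well defined on the intrinsically
#' unordered daughters. Node count = number of divisions + 1.
#'
#' @slot root recursive list; each node is list(lengths = numeric, children = list).
#' @slot rootFrame 0-based frame of the tree origin.
#' @slot origin numeric(3): position (um) of the tree origin.
#' @exportClass CondensedTree
setClass("CondensedTree",
  representation(root = "list", rootFrame = "integer", origin = "numeric"))

setValidity("CondensedTree", function(object) {
  ok <- TRUE
  walk <- function(node) {
    if (any(node$lengths < 1)) ok <<- FALSE
    for (ch in node$children) walk(ch)
  }
  walk(object@root)
  if (!ok) return("all stored branch lengths must be >= 1")
  if (length(object@origin) != 3L) return("origin must be numeric(3)")
  TRUE
})

CondensedTree <- function(root, rootFrame = 0L, origin = c(0, 0, 0)) {
  new("CondensedTree", root = root, rootFrame = as.integer(rootFrame),
      origin = as.numeric(origin))
}

#' Number of nodes (divisions + 1) of a condensed tree
#' @param tree A \linkS4class{CondensedTree}.
#' @return integer node count.
#' @export
condensedSize <- function(tree) {
  count <- function(node) 1L + sum(vapply(node$children, count, integer(1)))
  count(tree@root)
}

#' Total tracked timepoints of a condensed tree (sum of all branch lengths)
#' @param tree A \linkS4class{CondensedTree}.
#' @return integer.
#' @export
condensedTimepoints <- function(tree) {
  total <- function(node) sum(node$lengths) + sum(vapply(node$children, total, numeric(1)))
  as.integer(total(tree@root))
}

setMethod("show", "CondensedTree", function(object) {
  cat(sprintf("CondensedTree: %d node(s) (%d division(s)), %d timepoints, origin frame %d\n",
              condensedSize(object), condensedSize(object) - 1L,
              condensedTimepoints(object), object@rootFrame))
})

#' TreeEditCosts: edit-operation costs for the tree distance
#'
#' @slot insert,remove non-negative per-node costs.
#' @slot update function(lengthsA, lengthsB) -> non-negative cost with
#'   update(x, x) = 0.
#' @exportClass TreeEditCosts
setClass("TreeEditCosts",
  representation(insert = "numeric", remove = "numeric", update = "function"))

setValidity("TreeEditCosts", function(object) {
  if (object@insert < 0 || object@remove < 0) return("costs must be non-negative")
  TRUE
})

#' Construct tree edit costs
#'
#' @param insert,remove per-node insertion/removal costs (default 1).
#' @param update either \code{"binary"} (0 if the branch-length tuples are
#'   equal, else 1), \code{"length"} (sum of absolute differences of the
#'   canonical tuples, padded with zeros), or a function(a, b) -> cost.
#' @return A \linkS4class{TreeEditCosts}.
#' @export
treeEditCosts <- function(insert = 1, remove = 1, update = "binary") {
  if (is.character(update)) {
    update <- switch(match.arg(update, c("binary", "length")),
      binary = function(a, b) {
        if (length(a) == length(b) && all(a == b)) 0 else 1
      },
      length = function(a, b) {
        n <- max(length(a), length(b))
        sum(abs(c(a, rep(0, n - length(a))) - c(b, rep(0, n - length(b)))))
      })
  }
  new("TreeEditCosts", insert = as.numeric(insert), remove = as.numeric(remove),
      update = update)
}
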