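## Readers and writers for every format the pipeline touches:
## CSV spot tables, multi-page TIFF volume sequences, lineage forest JSON,
## and the Cell-Tracking-Challenge man_track-style text export.

#' Read a spot table from CSV
#'
#' Expected header columns: frame, channel, x, y, z, radius, intensity; an
#' `id` column is optional and assigned from row order when absent. Channel
#' labels other than "green"/"red" are rejected.
#'
#' @param path CSV file path.
#' @param frameInterval minutes between frames (not stored in the CSV).
#' @param voxelSize voxel size in um, (z, y, x).
#' @return A \linkS4class{SpotSeries} with contiguous frame indexing.
#' @export
readSpotTable <- function(path, frameInterval = 15, voxelSize = c(3, 2, 2)) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("frame", "channel", "x", "y", "z", "radius", "intensity")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stopf("spot table '%s' is missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  for (col in c("frame", "x", "y", "z", "radius", "intensity")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v))
      if (length(bad))
        stopf("non-numeric value in column '%s' at data row %d of '%s'",
              col, bad[1], path)
      tab[[col]] <- suppress
    }
  }
  bad <- setdiff(unique(tab$channel), .CHANNELS)
  if (length(bad))
    stopf("unknown channel label(s) in '%s': %s", path, paste(bad, collapse = ", "))
  if (is.null(tab$id)) tab$id <- seq_len(nrow(tab))
  SpotSeries(tab, frameInterval = frameInterval, voxelSize = voxelSize)
}

#' Write a spot table to CSV
#'
#' Rows are sorted by (frame, channel, id); floating-point values keep full
#' precision (>= 6 significant digits) so that a read/write round trip
#' reproduces the series.
#'
#' @param series A \linkS4class{SpotSeries}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeSpotTable <- function(series, path) {
  s <- spots(series)
  s <- s[order(s$frame, match(s$channel, .CHANNELS), s$id), , drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(.SPOT_COLUMNS, collapse = ","), con)
  if (nrow(s)) {
    fmt <- function(v) vapply(v, function(x) format(x, digits = 15, trim = TRUE),
                              character(1))
    lines <- paste(s$id, s$frame, s$channel, fmt(s$x), fmt(s$y), fmt(s$z),
                   fmt(s$radius), fmt(s$intensity), sep = ",")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a TIFF volume sequence
#'
#' One multi-page TIFF per (frame, channel), named \code{t<frame>_c<channel>.tif}
#' under `dir`. Volumes are returned ordered by frame then channel; all frames
#' must be present (a gap raises an error listing the missing indices) and all
#' volumes must share one shape.
#'
#' @param dir directory containing the TIFF files.
#' @param voxelSize um per axis (z, y, x); TIFFs carry no trusted metadata here.
#' @param channels channels to read (default both).
#' @return List of \linkS4class{ImageVolume}, ordered by frame then channel.
#' @export
readVolumeSequence <- function(dir, voxelSize = c(3, 2, 2),
                               channels = .CHANNELS) {
  files <- list.files(dir, pattern = "^t[0-9]+_c(green|red)\\.tif$")
  if (!length(files)) stopf("no volume files (t<frame>_c<channel>.tif) in '%s'", dir)
  info <- regmatches(files, regexec("^t([0-9]+)_c(green|red)\\.tif$", files))
  tab <- data.frame(file = files,
                    frame = as.integer(vapply(info, `[`, character(1), 2)),
                    channel = vapply(info, `[`, character(1), 3),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$channel %in% channels, , drop = FALSE]
  frames <- sort(unique(tab$frame))
  wanted <- seq(0L, max(frames))
  gaps <- setdiff(wanted, frames)
  if (length(gaps))
    stopf("missing frame(s) in volume sequence: %s", paste(gaps, collapse = ", "))
  for (fr in frames) for (ch in channels) {
    if (!any(tab$frame == fr & tab$channel == ch))
      stopf("missing channel '%s' at frame %d", ch, fr)
  }
  tab <- tab[order(tab$frame, match(tab$channel, .CHANNELS)), , drop = FALSE]
  shape <- NULL
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pages <- tiff::readTIFF(file.path(dir, tab$file[i]), all = TRUE,
                            as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(length(pages), dim(pages[[1]])[1:2])
    if (is.null(shape)) shape <- d
    else if (!all(d == shape))
      stopf("inconsistent volume shape at frame %d channel %s: %s vs %s",
            tab$frame[i], tab$channel[i], paste(d, collapse = "x"),
            paste(shape, collapse = "x"))
    vox <- array(0, dim = shape)
    for (k in seq_along(pages)) vox[k, , ] <- pages[[k]]
    out[[i]] <- ImageVolume(vox, voxelSize = voxelSize,
                            frame = tab$frame[i], channel = tab$channel[i])
  }
  out
}

#' Write a TIFF volume sequence
#'
#' The TIFF container stores values in [0, 1]; voxel values are divided by
#' `scale` (default: the global maximum) on write, so intensities are only
#' preserved up to that factor. Spot detection is unaffected up to a matching
#' threshold rescaling.
#'
#' @param volumes list of \linkS4class{ImageVolume}.
#' @param dir output directory (created if needed).
#' @param scale divisor applied before writing; NULL = global max.
#' @return Invisibly, the scale used.
#' @export
writeVolumeSequence <- function(volumes, dir, scale = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scale)) {
    scale <- max(1e-12, max(vapply(volumes, function(v) max(v@voxels), numeric(1))))
  }
  for (v in volumes) {
    pages <- lapply(seq_len(dim(v@voxels)[1]),
                    function(k) pmin(v@voxels[k, , ] / scale, 1))
    tiff::writeTIFF(pages, file.path(dir, sprintf("t%d_c%s.tif", v@frame, v@channel)),
                    bits.per.sample = 32L)
  }
  invisible(scale)
}

#' Write a lineage forest to JSON
#'
#' Schema (artifact-defined): top-level `trees` (tree, channel, rootFrame,
#' rootPosition), `nodes` (id, tree, frame, position, channel, synthetic) and
#' `edges` (from, to).
#'
#' @param forest A \linkS4class{LineageForest}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeLineageForest <- function(forest, path) {
  n <- forest@nodes; tr <- forest@trees
  obj <- list(
    trees = lapply(seq_len(nrow(tr)), function(i) list(
      tree = tr$tree[i], channel = tr$channel[i], rootFrame = tr$rootFrame[i],
      rootPosition = c(tr$rootX[i], tr$rootY[i], tr$rootZ[i]))),
    nodes = lapply(seq_len(nrow(n)), function(i) list(
      id = n$id[i], tree = n$tree[i], frame = n$frame[i],
      position = c(n$x[i], n$y[i], n$z[i]), channel = n$channel[i],
      synthetic = n$synthetic[i])),
    edges = lapply(seq_len(nrow(forest@edges)), function(i) list(
      from = forest@edges$from[i], to = forest@edges$to[i])))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read a lineage forest from JSON
#'
#' @param path JSON path written by \code{\link{writeLineageForest}}.
#' @return A \linkS4class{LineageForest}.
#' @export
readLineageForest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  trees <- obj$trees
  if (is.null(trees) || !NROW(trees)) {
    treedf <- data.frame(tree = integer(), channel = character(),
                         rootFrame = integer(), rootX = numeric(),
                         rootY = numeric(), rootZ = numeric())
  } else {
    rp <- do.call(rbind, trees$rootPosition)
    treedf <- data.frame(tree = as.integer(trees$tree), channel = trees$channel,
                         rootFrame = as.integer(trees$rootFrame),
                         rootX = rp[, 1], rootY = rp[, 2], rootZ = rp[, 3])
  }
  nodes <- obj$nodes
  if (is.null(nodes) || !NROW(nodes)) {
    nodedf <- data.frame(id = integer(), tree = integer(), frame = integer(),
                         x = numeric(), y = numeric(), z = numeric(),
                         channel = character(), synthetic = logical())
  } else {
    pos <- do.call(rbind, nodes$position)
    nodedf <- data.frame(id = as.integer(nodes$id), tree = as.integer(nodes$tree),
                         frame = as.integer(nodes$frame),
                         x = pos[, 1], y = pos[, 2], z = pos[, 3],
                         channel = nodes$channel,
                         synthetic = as.logical(nodes$synthetic))
  }
  edges <- obj$edges
  edgedf <- if (is.null(edges) || !NROW(edges)) {
    data.frame(from = integer(), to = integer())
  } else {
    data.frame(from = as.integer(edges$from), to = as.integer(edges$to))
  }
  LineageForest(nodedf, edgedf, treedf)
}

## Decompose a forest into track segments: maximal chains broken at divisions.
## Returns data.frame(label, begin, end, parent, tree, channel).
forestSegments <- function(forest) {
  n <- forest@nodes; e <- forest@edges
  if (!nrow(n))
    return(data.frame(label = integer(), begin = integer(), end = integer(),
                      parent = integer(), tree = integer(), channel = character()))
  outdeg <- table(factor(e$from, levels = n$id))
  indeg <- table(factor(e$to, levels = n$id))
  childOf <- split(e$to, factor(e$from, levels = n$id))
  parentOf <- setNames(e$from, e$to)
  frameOf <- setNames(n$frame, n$id)
  treeOf <- setNames(n$tree, n$id)
  ## segment starts: roots, or daughters of a division (mother out-degree 2)
  starts <- n$id[indeg[as.character(n$id)] == 0L]
  if (nrow(e)) {
    mothers <- as.integer(names(outdeg)[outdeg == 2L])
    starts <- c(starts, e$to[e$from %in% mothers])
  }
  starts <- sort(unique(starts))
  segs <- list(); segOfEnd <- list()
  for (s in starts) {
    cur <- s
    repeat {
      ch <- childOf[[as.character(cur)]]
      if (is.null(ch) || length(ch) != 1L) break
      ## a single child continues the segment unless that child starts its own
      if (ch %in% starts) break
      cur <- ch
    }
    segs[[length(segs) + 1L]] <- c(start = s, end = cur)
  }
  segdf <- do.call(rbind, lapply(segs, function(x)
    data.frame(startNode = x[["start"]], endNode = x[["end"]])))
  segdf$label <- seq_len(nrow(segdf))
  segdf$begin <- as.integer(frameOf[as.character(segdf$startNode)])
  segdf$end <- as.integer(frameOf[as.character(segdf$endNode)])
  segdf$tree <- as.integer(treeOf[as.character(segdf$startNode)])
  segdf$channel <- n$channel[match(segdf$startNode, n$id)]
  endToLabel <- setNames(segdf$label, segdf$endNode)
  segdf$parent <- vapply(seq_len(nrow(segdf)), function(i) {
    p <- parentOf[as.character(segdf$startNode[i])]
    if (is.na(p)) 0L else as.integer(endToLabel[as.character(p)])
  }, integer(1))
  segdf[, c("label", "begin", "end", "parent", "tree", "channel",
            "startNode", "endNode")]
}

#' Export lineage tracks in Cell-Tracking-Challenge text format
#'
#' One line per track segment: "L B E P" (label, begin frame, end frame,
#' parent label; 0 for roots). Segments break at divisions.
#'
#' @param forest A \linkS4class{LineageForest}.
#' @param path output text file.
#' @return Invisibly, the segment table.
#' @export
exportCTCTracks <- function(forest, path) {
  if (nrow(forest@edges)) {
    outdeg <- table(forest@edges$from)
    if (any(outdeg > 2L))
      stopf("invariant violation: node(s) with > 2 children: %s",
            paste(names(outdeg)[outdeg > 2L], collapse = ", "))
  }
  segs <- forestSegments(forest)
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(segs))
    writeLines(paste(segs$label, segs$begin, segs$end, segs$parent), con)
  invisible(segs)
}

#' Read a Cell-Tracking-Challenge track file
#'
#' @param path text file with "L B E P" lines.
#' @return data.frame(label, begin, end, parent).
#' @export
readCTCTracks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(label = integer(), begin = integer(), end = integer(),
                      parent = integer()))
  parts <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"), as.integer))
  data.frame(label = parts[, 1], begin = parts[, 2], end = parts[, 3],
             parent = parts[, 4])
}
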