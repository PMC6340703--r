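## The first/second validation: embryo-extent outlier removal, double-spot
## merging, red/green colocalization filtering and temporal recovery of
## discarded red spots. All distance comparisons use closed balls (<=) for
## determinism at boundaries, and surviving unmerged spots are never moved.

#' Estimate the embryo extent from green spots
#'
#' Returns the median over spots i of max_j ||x_i - x_j||, i.e. the median of
#' all maximal inter-spot distances. This approximates a diameter when
#' roughly antipodal spots exist; the radius filter scales it by a
#' user-defined factor (see \code{\link{validationParams}}).
#'
#' @param greenSpots data.frame of green spots (>= 2 rows).
#' @return Extent in micrometres.
#' @export
estimateEmbryoExtent <- function(greenSpots) {
  if (nrow(greenSpots) < 2L)
    stopf("insufficient data: need >= 2 green spots to estimate the embryo extent (got %d)",
          nrow(greenSpots))
  p <- spotCoords(greenSpots)
  d <- crossDist(p, p)
  median(apply(d, 1, max))
}

#' Remove spots outside the embryo
#'
#' Keeps spots within distance T = radiusFactor * extent of the green centre
#' of mass (closed ball); the partition into kept/discarded is exhaustive
#' and disjoint. Contaminated frames inflate both the extent estimate and
#' (slightly) the centre, which is why \code{\link{validateSeries}} applies
#' this filter iteratively.
#'
#' @param spotsDf data.frame of spots (one frame, any channel) to filter.
#' @param greenSpots data.frame of the frame's green spots (defines extent and
#'   centre).
#' @param params A \linkS4class{ValidationParams}.
#' @return list(kept, discarded) data.frames.
#' @export
filterOutsideEmbryo <- function(spotsDf, greenSpots, params) {
  extent <- estimateEmbryoExtent(greenSpots)
  threshold <- params@radiusFactor * extent
  center <- colMeans(spotCoords(greenSpots))
  d <- sqrt(colSums((t(spotCoords(spotsDf)) - center)^2))
  keep <- d <= threshold
  list(kept = spotsDf[keep, , drop = FALSE],
       discarded = spotsDf[!keep, , drop = FALSE])
}

#' Merge double detections of one nucleus
#'
#' Connected components under the relation "pairwise distance <=
#' mergeDistance" are each replaced by one spot at the intensity-weighted
#' centroid (plain mean if total intensity is 0), with radius = max member
#' radius and intensity = summed intensity. Singletons pass through
#' unchanged; merged spots get fresh ids.
#'
#' @param spotsDf data.frame of spots from one frame and one channel.
#' @param mergeDistance micrometres (> 0).
#' @param idStart first id for newly created merged spots (default: one past
#'   the maximum input id).
#' @return data.frame of spots after merging.
#' @export
mergeDoubleSpots <- function(spotsDf, mergeDistance, idStart = NULL) {
  if (mergeDistance < 0) stopf("mergeDistance must be >= 0 (got %g)", mergeDistance)
  if (nrow(spotsDf) <= 1L) return(spotsDf)
  stopifnot(length(unique(spotsDf$frame)) == 1L,
            length(unique(spotsDf$channel)) == 1L)
  p <- spotCoords(spotsDf)
  d <- crossDist(p, p)
  pairs <- which(d <= mergeDistance & upper.tri(d), arr.ind = TRUE)
  comp <- connectedComponents(nrow(spotsDf), pairs)
  if (is.null(idStart)) idStart <- max(spotsDf$id) + 1L
  nextId <- as.integer(idStart)
  out <- lapply(split(seq_len(nrow(spotsDf)), comp), function(idx) {
    if (length(idx) == 1L) return(spotsDf[idx, , drop = FALSE])
    sub <- spotsDf[idx, , drop = FALSE]
    w <- sub$intensity
    if (sum(w) <= 0) w <- rep(1, nrow(sub))
    merged <- sub[1, , drop = FALSE]
    merged$id <- nextId
    nextId <<- nextId + 1L
    merged$x <- sum(sub$x * w) / sum(w)
    merged$y <- sum(sub$y * w) / sum(w)
    merged$z <- sum(sub$z * w) / sum(w)
    merged$radius <- max(sub$radius)
    merged$intensity <- sum(sub$intensity)
    merged
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keep only red spots that colocalize with a green spot
#'
#' A red spot is kept iff some green spot lies within `colocDistance` (closed
#' ball). Photoconversion is never exhaustive, so every true red nucleus
#' retains a green partner; red detections without one are background.
#'
#' @param redSpots,greenSpots same-frame spot data.frames.
#' @param colocDistance micrometres.
#' @return list(kept, discarded).
#' @export
filterNoncolocalizedRed <- function(redSpots, greenSpots, colocDistance) {
  if (!nrow(redSpots)) return(list(kept = redSpots, discarded = redSpots))
  if (!nrow(greenSpots))
    return(list(kept = redSpots[0, , drop = FALSE], discarded = redSpots))
  d <- crossDist(spotCoords(redSpots), spotCoords(greenSpots))
  keep <- apply(d, 1, min) <= colocDistance
  list(kept = redSpots[keep, , drop = FALSE],
       discarded = redSpots[!keep, , drop = FALSE])
}

#' Recover discarded red spots using the previous frame
#'
#' Returns the subset of this frame's discarded red spots that have a valid
#' red spot in the previous frame within `recoveryRadius`, compensating for
#' residual green-channel mis-segmentations. Nothing is recovered at frame 0.
#'
#' @param discardedRed discarded red spots of frame t.
#' @param validRedPrev validated red spots of frame t - 1.
#' @param recoveryRadius micrometres.
#' @return data.frame of recovered spots (possibly empty).
#' @export
recoverRedSpots <- function(discardedRed, validRedPrev, recoveryRadius) {
  if (!nrow(discardedRed) || !nrow(validRedPrev))
    return(discardedRed[0, , drop = FALSE])
  if (any(discardedRed$frame == 0L)) return(discardedRed[0, , drop = FALSE])
  d <- crossDist(spotCoords(discardedRed), spotCoords(validRedPrev))
  keep <- apply(d, 1, min) <= recoveryRadius
  discardedRed[keep, , drop = FALSE]
}

#' Run the full validation over a series
#'
#' Applies, per frame and in order: the outside-embryo filter (both channels,
#' threshold from the green spots), per-channel double-spot merging, the red
#' colocalization filter, and (if enabled) sequential-in-time red recovery
#' against the previous frame's validated red spots.
#'
#' @param series A \linkS4class{SpotSeries} with >= 2 green spots per frame.
#' @param params A \linkS4class{ValidationParams}.
#' @return list(series = validated \linkS4class{SpotSeries}, report =
#'   data.frame with one row per frame and channel: nIn, nOut, outside,
#'   merged (spots removed by merging), noncoloc, recovered; conservation
#'   nIn = nOut + outside + merged + noncoloc - recovered holds exactly).
#' @export
validateSeries <- function(series, params = validationParams()) {
  validObject(params)
  allSpots <- spots(series)
  nextId <- if (nrow(allSpots)) max(allSpots$id) + 1L else 1L
  outFrames <- list()
  report <- list()
  prevRed <- NULL
  for (fr in seq_len(nFrames(series)) - 1L) {
    green <- frameSpots(series, fr, "green")
    red <- frameSpots(series, fr, "red")
    if (nrow(green) < 2L)
      stopf("insufficient data at frame %d: %d green spot(s), need >= 2",
            fr, nrow(green))
    ## 1. outside-embryo filter (threshold from the green spots), iterated to
    ## a fixed point: discarded outliers inflate the extent estimate, so the
    ## filter is re-applied on the survivors until nothing more is discarded
    ## (this is what makes the whole validation idempotent)
    greenKept <- green
    nOutsideG <- 0L
    repeat {
      fg <- filterOutsideEmbryo(greenKept, greenKept, params)
      nOutsideG <- nOutsideG + nrow(fg$discarded)
      if (!nrow(fg$discarded) || nrow(fg$kept) < 2L) break
      greenKept <- fg$kept
    }
    frr <- filterOutsideEmbryo(red, greenKept, params)
    nOutsideR <- nrow(frr$discarded)
    ## 2. per-channel double-spot merge
    mg <- mergeDoubleSpots(fg$kept, params@mergeDistance, idStart = nextId)
    if (nrow(mg)) nextId <- max(nextId, max(mg$id) + 1L)
    mr <- mergeDoubleSpots(frr$kept, params@mergeDistance, idStart = nextId)
    if (nrow(mr)) nextId <- max(nextId, max(mr$id) + 1L)
    nMergedG <- nrow(fg$kept) - nrow(mg)
    nMergedR <- nrow(frr$kept) - nrow(mr)
    ## 3. red colocalization filter
    fc <- filterNoncolocalizedRed(mr, mg, params@colocDistance)
    nNoncoloc <- nrow(fc$discarded)
    redKept <- fc$kept
    ## 4. sequential red recovery from the previous validated frame
    nRecovered <- 0L
    if (params@recoveryEnabled && fr > 0L && !is.null(prevRed)) {
      discardedRed <- rbind(frr$discarded, fc$discarded)
      rec <- recoverRedSpots(discardedRed, prevRed, params@recoveryRadius)
      nRecovered <- nrow(rec)
      if (nRecovered) redKept <- rbind(redKept, rec)
    }
    prevRed <- redKept
    outFrames[[length(outFrames) + 1L]] <- rbind(mg, redKept)
    report[[length(report) + 1L]] <- data.frame(
      frame = fr,
      channel = c("green", "red"),
      nIn = c(nrow(green), nrow(red)),
      nOut = c(nrow(mg), nrow(redKept)),
      outside = c(nOutsideG, nOutsideR),
      merged = c(nMergedG, nMergedR),
      noncoloc = c(0L, nNoncoloc),
      recovered = c(0L, nRecovered))
  }
  out <- do.call(rbind, c(outFrames, list(emptySpotFrame())))
  rownames(out) <- NULL
  validated <- SpotSeries(out, nFrames = nFrames(series),
                          frameInterval = frameInterval(series),
                          voxelSize = voxelSize(series))
  list(series = validated, report = do.call(rbind, report))
}
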