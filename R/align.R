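## Embryo alignment: per-frame reference frames from the green/red centres of
## mass, exhaustive 1-degree roll search against the previous aligned frame,
## application to spots and volumes, and cropping.

#' Compute a per-frame reference frame from the two channels
#'
#' Origin = fluorescence centre of mass of the green spots; axis = unit
#' vector along delta-COM = COM_red - COM_green; roll = 0 (fixed later by
#' the drift search). Both COMs are intensity-weighted: histone-fusion
#' signal is partitioned between the daughters at division, so the weighted
#' COM of either channel is invariant across divisions, whereas a
#' count-based COM jumps by (c - COM)/(n+1) whenever one of n cells
#' divides, abruptly translating the origin and tilting the orientation
#' axis mid-series (a jolt the 1-degree roll search cannot correct). Spots
#' without usable intensities fall back to equal weights.
#'
#' @param greenSpots,redSpots same-frame spot data.frames.
#' @return A \linkS4class{ReferenceFrame}.
#' @export
computeReferenceFrame <- function(greenSpots, redSpots) {
  if (!nrow(greenSpots)) stopf("need >= 1 green spot")
  if (!nrow(redSpots))
    stop(errorCondition("no red spots: orientation undefined",
                        class = "noOrientationError"))
  comG <- intensityCOM(greenSpots)
  comR <- intensityCOM(redSpots)
  delta <- comR - comG
  len <- sqrt(sum(delta^2))
  if (len < 1e-6)
    stop(errorCondition(
      sprintf("degenerate orientation: |deltaCOM| = %g um < 1e-6", len),
      class = "degenerateOrientationError"))
  ReferenceFrame(origin = comG, axis = delta / len, roll = 0)
}

## fluorescence centre of mass of a spot set
intensityCOM <- function(spotsDf) {
  w <- spotsDf$intensity
  if (is.null(w) || !all(is.finite(w)) || sum(w) <= 0) w <- rep(1, nrow(spotsDf))
  colSums(spotCoords(spotsDf) * w) / sum(w)
}

#' Build a right-handed orthonormal basis from a unit axis
#'
#' Returns a 3x3 rotation matrix whose first row is the axis; the second row
#' is the world axis least parallel to the input (ties broken toward world
#' x), projected orthogonal to it and normalized; the third row completes the
#' right-handed system by cross product. Multiplying a coordinate vector by
#' the matrix expresses it in the frame whose +x direction is the axis.
#'
#' @param axis unit numeric(3).
#' @return 3x3 rotation matrix B with B[1, ] = axis, det(B) = 1.
#' @export
buildBasis <- function(axis) {
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6)
    stopf("axis must be a unit vector (norm %g)", sqrt(sum(axis^2)))
  ## world axis least parallel to the input; near-ties (within 1e-6) break
  ## toward world-x so the basis varies continuously around exact ties
  a <- abs(axis)
  cand <- which(a - min(a) < 1e-6)
  w <- c(0, 0, 0); w[cand[1]] <- 1
  v <- w - sum(w * axis) * axis
  v <- v / sqrt(sum(v^2))
  u <- c(axis[2] * v[3] - axis[3] * v[2],
         axis[3] * v[1] - axis[1] * v[3],
         axis[1] * v[2] - axis[2] * v[1])
  B <- rbind(axis, v, u, deparse.level = 0)
  dimnames(B) <- NULL
  B
}

#' Exhaustive roll search minimizing inter-frame cell drift
#'
#' Evaluates candidate roll angles theta in 0, 1, ..., 359 degrees about the
#' frame axis (+x of the pre-rotated coordinates). The drift of an angle is
#' the mean over current spots of the nearest-neighbour distance to the
#' previous aligned spots; the argmin is returned, ties broken by the
#' smallest angle. The mean (rather than a trimmed statistic) keeps the
#' search stiff: a partial statistic can be lowered by rotations that chase
#' a subset of the cloud after a small orientation-axis tilt, visibly
#' mis-rotating the rest.
#'
#' @param current green spots of frame t, pre-rotated into the frame's basis
#'   (n x 3 matrix or spot data.frame).
#' @param previousAligned fully aligned green spots of frame t - 1.
#' @return list(angle = degrees, drift = um).
#' @export
optimizeRoll <- function(current, previousAligned) {
  p <- if (is.data.frame(current)) spotCoords(current) else current
  q <- if (is.data.frame(previousAligned)) spotCoords(previousAligned) else previousAligned
  if (!nrow(p) || !nrow(q)) stopf("optimizeRoll needs non-empty spot sets")
  ## squared distance between Rx(theta) p_i and q_j decomposes as
  ## S_ij - 2 cos(theta) P_ij - 2 sin(theta) Q_ij
  S <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * outer(p[, 1], q[, 1])
  P <- outer(p[, 2], q[, 2]) + outer(p[, 3], q[, 3])
  Q <- outer(p[, 2], q[, 3]) - outer(p[, 3], q[, 2])
  angles <- 0:359
  th <- angles * pi / 180
  best <- Inf; bestAngle <- 0
  for (i in seq_along(angles)) {
    d2 <- S - 2 * (cos(th[i]) * P + sin(th[i]) * Q)
    drift <- mean(sqrt(pmax(apply(d2, 1, min), 0)))
    if (drift < best - 1e-12) {
      best <- drift; bestAngle <- angles[i]
    }
  }
  list(angle = bestAngle, drift = best)
}

## rotation matrix of the full per-frame alignment: roll about +x after the
## basis rotation
frameRotation <- function(axis, roll) rotationAboutX(roll) %*% buildBasis(axis)

#' Align a series across time
#'
#' Frame 0 is aligned with roll 0; every subsequent frame gets a reference
#' frame from its green/red centres of mass, is expressed in that frame, and
#' its roll is chosen by \code{\link{optimizeRoll}} against the previous
#' aligned frame (green spots only; red spots are transformed passively).
#' Frames without a usable red orientation reuse the previous frame's axis
#' (recorded in the result). After alignment every frame's green COM sits at
#' the origin and its red COM on the +x ray.
#'
#' @param series validated \linkS4class{SpotSeries}; frame 0 must have >= 1
#'   red spot.
#' @return list(series = aligned SpotSeries, result =
#'   \linkS4class{AlignmentResult}).
#' @export
alignSeries <- function(series) {
  n <- nFrames(series)
  if (n < 1L) stopf("cannot align an empty series")
  refs <- vector("list", n); trs <- vector("list", n)
  rolls <- numeric(n); drifts <- numeric(n); reused <- logical(n)
  outFrames <- vector("list", n)
  prevAlignedGreen <- NULL
  prevAxis <- NULL
  for (fr in seq_len(n) - 1L) {
    green <- frameSpots(series, fr, "green")
    red <- frameSpots(series, fr, "red")
    ref <- tryCatch(computeReferenceFrame(green, red), error = function(e) e)
    if (inherits(ref, "error")) {
      if (fr == 0L)
        stopf("frame 0 has no usable red orientation (%s): anchor orientation undefined",
              conditionMessage(ref))
      ref <- ReferenceFrame(origin = intensityCOM(green), axis = prevAxis)
      reused[fr + 1L] <- TRUE
    }
    prevAxis <- ref@axis
    B <- buildBasis(ref@axis)
    pre <- sweep(spotCoords(green), 2, ref@origin) %*% t(B)
    if (fr == 0L) {
      roll <- 0; drift <- 0
    } else {
      opt <- optimizeRoll(pre, prevAlignedGreen)
      roll <- opt$angle; drift <- opt$drift
    }
    refs[[fr + 1L]] <- ReferenceFrame(ref@origin, ref@axis, roll)
    R <- frameRotation(ref@axis, roll)
    tr <- RigidTransform(rotation = R, translation = ref@origin)
    trs[[fr + 1L]] <- tr
    rolls[fr + 1L] <- roll; drifts[fr + 1L] <- drift
    frameAll <- frameSpots(series, fr)
    aligned <- applyTransform(tr, frameAll)
    outFrames[[fr + 1L]] <- aligned
    prevAlignedGreen <- spotCoords(aligned[aligned$channel == "green", , drop = FALSE])
  }
  out <- do.call(rbind, c(outFrames, list(emptySpotFrame())))
  rownames(out) <- NULL
  alignedSeries <- SpotSeries(out, nFrames = n,
                              frameInterval = frameInterval(series),
                              voxelSize = voxelSize(series))
  result <- new("AlignmentResult", referenceFrames = refs, transforms = trs,
                roll = rolls, drift = drifts, axisReused = reused)
  list(series = alignedSeries, result = result)
}

#' Apply a previously computed alignment to another series
#'
#' Transforms every frame of `series` with the per-frame rigid transforms of
#' `result` (e.g. to re-align the raw, unvalidated spots for the second
#' validation pass).
#'
#' @param series A \linkS4class{SpotSeries}.
#' @param result An \linkS4class{AlignmentResult} covering at least as many
#'   frames.
#' @return The aligned \linkS4class{SpotSeries}.
#' @export
applyAlignment <- function(series, result) {
  if (length(result@transforms) < nFrames(series))
    stopf("alignment covers %d frame(s) but the series has %d",
          length(result@transforms), nFrames(series))
  s <- spots(series)
  if (nrow(s)) {
    for (fr in unique(s$frame)) {
      sel <- s$frame == fr
      s[sel, ] <- applyTransform(result@transforms[[fr + 1L]], s[sel, , drop = FALSE])
    }
  }
  SpotSeries(s, nFrames = nFrames(series), frameInterval = frameInterval(series),
             voxelSize = voxelSize(series))
}

#' Bounding crop box of an aligned series
#'
#' Axis-aligned box covering every spot centre across all frames and
#' channels, expanded by `margin` on each face.
#'
#' @param aligned non-empty aligned \linkS4class{SpotSeries}.
#' @param margin micrometres.
#' @return A \linkS4class{CropBox}.
#' @export
cropBounds <- function(aligned, margin = 0) {
  s <- spots(aligned)
  if (!nrow(s)) stopf("cannot compute crop bounds of an empty series")
  p <- spotCoords(s)
  CropBox(min = apply(p, 2, min) - margin, max = apply(p, 2, max) + margin,
          margin = margin)
}

#' Resample a volume into aligned, cropped coordinates
#'
#' The output voxel grid spans the crop box at the input voxel size; values
#' are pulled through the inverse transform with trilinear interpolation and
#' out-of-bounds samples are 0.
#'
#' @param volume An \linkS4class{ImageVolume} (world coordinates).
#' @param transform the frame's \linkS4class{RigidTransform}.
#' @param box A \linkS4class{CropBox} in aligned coordinates.
#' @return The resampled \linkS4class{ImageVolume}.
#' @export
resampleVolume <- function(volume, transform, box) {
  ext <- box@max - box@min
  if (any(ext <= 0)) stopf("crop box has zero extent")
  vs <- volume@voxelSize  # (z, y, x)
  dims <- c(max(1L, ceiling(ext[3] / vs[1])),
            max(1L, ceiling(ext[2] / vs[2])),
            max(1L, ceiling(ext[1] / vs[3])))
  zc <- box@min[3] + (seq_len(dims[1]) - 0.5) * vs[1]
  yc <- box@min[2] + (seq_len(dims[2]) - 0.5) * vs[2]
  xc <- box@min[1] + (seq_len(dims[3]) - 0.5) * vs[3]
  grid <- cbind(x = rep(xc, each = dims[1] * dims[2]),
                y = rep(rep(yc, each = dims[1]), times = dims[3]),
                z = rep(zc, times = dims[2] * dims[3]))
  inv <- invertTransform(transform)
  world <- applyTransform(inv, grid)
  out <- array(trilinearSample(volume, world), dim = dims)
  ImageVolume(out, voxelSize = vs, frame = volume@frame, channel = volume@channel)
}

## trilinear interpolation of a volume at world positions (n x 3, x/y/z um);
## samples outside the volume return 0
trilinearSample <- function(volume, pos) {
  d <- dim(volume@voxels)
  vs <- volume@voxelSize
  ## continuous voxel coordinates (1-based voxel centres at i)
  cz <- pos[, 3] / vs[1] + 0.5
  cy <- pos[, 2] / vs[2] + 0.5
  cx <- pos[, 1] / vs[3] + 0.5
  k0 <- floor(cz); j0 <- floor(cy); i0 <- floor(cx)
  fz <- cz - k0; fy <- cy - j0; fx <- cx - i0
  val <- numeric(nrow(pos))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    kk <- k0 + dz; jj <- j0 + dy; ii <- i0 + dx
    w <- (if (dz) fz else 1 - fz) * (if (dy) fy else 1 - fy) *
      (if (dx) fx else 1 - fx)
    ok <- kk >= 1 & kk <= d[1] & jj >= 1 & jj <= d[2] & ii >= 1 & ii <= d[3] & w > 0
    if (any(ok))
      val[ok] <- val[ok] + w[ok] *
        volume@voxels[cbind(kk[ok], jj[ok], ii[ok])]
  }
  val
}
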