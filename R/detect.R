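## Multiscale Laplacian-of-Gaussian spot detection for nuclei in 3D volumes.
## Scales are expressed in micrometres and converted per axis by the voxel
## size, so the strongly anisotropic axial spacing is handled correctly.

gaussKernel1D <- function(sigmaVox) {
  h <- max(1L, ceiling(3 * sigmaVox))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigmaVox^2))
  k / sum(k)
}

## separable 1D convolution along one axis of a 3D array, replicate padding
convolveAxis <- function(a, k, axis) {
  h <- (length(k) - 1L) / 2L
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  clamp <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
  for (j in seq_along(k)) {
    sl <- clamp(j - h - 1L)
    out <- out + k[j] * switch(axis,
      a[sl, , , drop = FALSE],
      a[, sl, , drop = FALSE],
      a[, , sl, drop = FALSE])
  }
  out
}

gaussianSmooth3D <- function(a, sigmaVox) {
  for (axis in 1:3) {
    if (sigmaVox[axis] > 1e-6) a <- convolveAxis(a, gaussKernel1D(sigmaVox[axis]), axis)
  }
  a
}

## second difference along one axis divided by the squared physical spacing
secondDiff <- function(a, axis, spacing) {
  d <- dim(a)
  n <- d[axis]
  clamp <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
  plus <- switch(axis, a[clamp(1L), , , drop = FALSE],
                 a[, clamp(1L), , drop = FALSE], a[, , clamp(1L), drop = FALSE])
  minus <- switch(axis, a[clamp(-1L), , , drop = FALSE],
                  a[, clamp(-1L), , drop = FALSE], a[, , clamp(-1L), drop = FALSE])
  (plus - 2 * a + minus) / spacing^2
}

## scale-normalized negated LoG response (positive for bright blobs)
logResponse <- function(voxels, voxelSize, sigma) {
  sm <- gaussianSmooth3D(voxels, sigma / voxelSize)
  lap <- secondDiff(sm, 1L, voxelSize[1]) + secondDiff(sm, 2L, voxelSize[2]) +
    secondDiff(sm, 3L, voxelSize[3])
  -sigma^2 * lap
}

## maximum over the 26 spatial neighbours of every voxel
neighborhoodMax <- function(a) {
  d <- dim(a)
  out <- array(-Inf, d)
  clamp <- function(shift, n) pmin(pmax(seq_len(n) + shift, 1L), n)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    out <- pmax(out, a[clamp(dz, d[1]), clamp(dy, d[2]), clamp(dx, d[3])])
  }
  out
}

#' Detect candidate nuclei as spots in a 3D volume
#'
#' Finds local maxima of a multiscale scale-normalized Laplacian-of-Gaussian
#' response above `threshold`. Scales are logarithmically spaced between
#' `sigmaMin` and `sigmaMax` (micrometres) and converted per axis into voxel
#' units, correcting for anisotropy. Each spot's radius adapts to its best
#' scale s as sqrt(3) * s; positions are voxel centres in micrometres.
#' Detection is deliberately permissive: spurious extras are expected and are
#' removed by the validation filters.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param params A \linkS4class{DetectionParams}.
#' @return data.frame of spots (id, frame, channel, x, y, z, radius, intensity);
#'   intensity is the raw voxel value at the maximum.
#' @export
detectSpots <- function(volume, params) {
  validObject(params)
  vs <- volume@voxelSize
  if (params@sigmaMax < max(vs))
    stopf("sigmaMax (%g um) is smaller than one voxel along some axis (voxel %s um)",
          params@sigmaMax, paste(vs, collapse = " x "))
  vox <- volume@voxels
  if (all(vox == 0)) return(emptySpotFrame())
  sigmas <- exp(seq(log(params@sigmaMin), log(params@sigmaMax),
                    length.out = params@nScales))
  d <- dim(vox)
  resp <- array(0, c(d, params@nScales))
  for (s in seq_along(sigmas))
    resp[, , , s] <- logResponse(vox, vs, sigmas[s])

  cand <- NULL
  for (s in seq_along(sigmas)) {
    r <- resp[, , , s]
    nb <- neighborhoodMax(r)
    if (s > 1L) nb <- pmax(nb, resp[, , , s - 1L])
    if (s < params@nScales) nb <- pmax(nb, resp[, , , s + 1L])
    hit <- which(r > params@threshold & r >= nb, arr.ind = TRUE)
    if (nrow(hit)) {
      cand <- rbind(cand, cbind(hit, scale = s,
                                value = r[cbind(hit[, 1], hit[, 2], hit[, 3])]))
    }
  }
  if (is.null(cand) || !nrow(cand)) return(emptySpotFrame())
  cand <- as.data.frame(cand)
  names(cand)[1:3] <- c("k", "j", "i")
  ## deterministic cluster/plateau handling: candidates that touch in voxel
  ## space (Chebyshev distance <= 1, any scale) describe one blob; keep the
  ## strongest response, breaking exact ties by lowest (z, y, x) index.
  cand <- cand[order(-cand$value, cand$k, cand$j, cand$i), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) for (j in (i + 1L):nrow(cand)) {
      if (!keep[j]) next
      if (max(abs(c(cand$k[i] - cand$k[j], cand$j[i] - cand$j[j],
                    cand$i[i] - cand$i[j]))) <= 1L)
        keep[j] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$k, cand$j, cand$i), , drop = FALSE]
  data.frame(id = seq_len(nrow(cand)),
             frame = volume@frame,
             channel = volume@channel,
             x = (cand$i - 0.5) * vs[3],
             y = (cand$j - 0.5) * vs[2],
             z = (cand$k - 0.5) * vs[1],
             radius = sqrt(3) * sigmas[cand$scale],
             intensity = vox[cbind(cand$k, cand$j, cand$i)],
             stringsAsFactors = FALSE)
}

#' Refine a spot to the intensity-weighted centroid of a local window
#'
#' The spot position is replaced by the intensity-weighted centroid of the
#' voxels whose centres fall within +/- `window` um of the current position,
#' and the intensity by the summed window intensity. A zero-intensity window
#' leaves the position unchanged (documented fallback) with intensity 0.
#'
#' @param volume An \linkS4class{ImageVolume}.
#' @param spot single-row spot data.frame.
#' @param window half-width of the cubic window, um.
#' @return The refined spot (same id/frame/channel).
#' @export
refineSpot <- function(volume, spot, window) {
  vs <- volume@voxelSize
  d <- dim(volume@voxels)
  ax <- voxelAxes(volume)
  sel <- list(z = which(abs(ax$z - spot$z) <= window),
              y = which(abs(ax$y - spot$y) <= window),
              x = which(abs(ax$x - spot$x) <= window))
  if (!length(sel$z) || !length(sel$y) || !length(sel$x))
    stopf("refinement window around (%g, %g, %g) lies entirely outside the volume",
          spot$x, spot$y, spot$z)
  w <- volume@voxels[sel$z, sel$y, sel$x, drop = FALSE]
  total <- sum(w)
  if (total <= 0) {
    spot$intensity <- 0
    return(spot)
  }
  gz <- apply(w, 1, sum); gy <- apply(w, 2, sum); gx <- apply(w, 3, sum)
  spot$z <- sum(ax$z[sel$z] * gz) / total
  spot$y <- sum(ax$y[sel$y] * gy) / total
  spot$x <- sum(ax$x[sel$x] * gx) / total
  spot$intensity <- total
  spot
}
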