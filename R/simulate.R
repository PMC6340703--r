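## Synthetic embryo acquisitions with full ground truth: a dividing embryo
## from the 4-cell stage, photoconversion of one cell, geometric red-signal
## dilution, rigid drift and rotation, spurious detections, and (optionally)
## rendered image volumes with rising background and Poisson noise.

#' SimulationParams: synthetic-acquisition settings
#'
#' Defaults emulate a mouse pre-implantation acquisition: four founder cells,
#' one photoconverted, three synchronous-ish division rounds, a z-stack of 80
#' planes 3 um apart, and per-nucleus intensity halving per division in both
#' channels (histone partitioning). Per-cell motion magnitudes are
#' assumptions, not measurements.
#'
#' @slot nStartCells founder cells (default 4).
#' @slot nDivisionRounds completed division rounds to simulate.
#' @slot cellCycleMean,cellCycleJitter minutes; per-cell division times are
#'   jittered around the mean.
#' @slot frameInterval minutes between frames (5, 7.5 or 15 are typical).
#' @slot nFrames number of acquired frames.
#' @slot embryoRadius um.
#' @slot nucleusSigma um: Gaussian scale of a rendered nucleus.
#' @slot motionSd um per frame: Brownian per-cell jitter.
#' @slot driftVelocity numeric(3) um per frame: rigid translational drift.
#' @slot rotationDegPerFrame,rotationAxis rigid rotation about an axis
#'   through the embryo centre.
#' @slot convertedCellIndex 0-based index of the photoconverted founder.
#' @slot redDilutionPerDivision multiplicative red-intensity factor per
#'   completed division (default 0.5).
#' @slot backgroundBase,backgroundRamp rendered background: base + ramp *
#'   frame (laser power is raised over time to follow the diluting red
#'   signal, which raises background).
#' @slot noiseModel "poisson" or "none".
#' @slot spuriousRate expected spurious detections per frame per channel at
#'   the final division round; the effective rate ramps with the red-signal
#'   dilution (zero before the first division round, when illumination is
#'   still at base power).
#' @slot spuriousClearance um: minimum distance of an interior spurious spot
#'   from any true nucleus.
#' @slot volumeShape voxels (z, y, x); default 80 planes.
#' @slot voxelSize um (z, y, x); default 3 um plane spacing.
#' @slot seed RNG seed; fixed seed gives bitwise-identical output.
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(nStartCells = "integer", nDivisionRounds = "integer",
                 cellCycleMean = "numeric", cellCycleJitter = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 embryoRadius = "numeric", nucleusSigma = "numeric",
                 motionSd = "numeric", driftVelocity = "numeric",
                 rotationDegPerFrame = "numeric", rotationAxis = "numeric",
                 convertedCellIndex = "integer",
                 redDilutionPerDivision = "numeric",
                 backgroundBase = "numeric", backgroundRamp = "numeric",
                 noiseModel = "character", spuriousRate = "numeric",
                 spuriousClearance = "numeric", volumeShape = "integer",
                 voxelSize = "numeric", seed = "integer"))

setValidity("SimulationParams", function(object) {
  if (object@nStartCells < 1L) return("nStartCells must be >= 1")
  if (object@convertedCellIndex < 0L ||
      object@convertedCellIndex >= object@nStartCells)
    return("convertedCellIndex must lie in [0, nStartCells)")
  if (object@cellCycleMean <= 0 || object@frameInterval <= 0 ||
      object@embryoRadius <= 0 || object@nucleusSigma <= 0)
    return("scales and rates must be positive")
  if (object@redDilutionPerDivision <= 0 || object@redDilutionPerDivision > 1)
    return("redDilutionPerDivision must lie in (0, 1]")
  if (!object@noiseModel %in% c("poisson", "none"))
    return("noiseModel must be 'poisson' or 'none'")
  if (length(object@driftVelocity) != 3L || length(object@rotationAxis) != 3L)
    return("driftVelocity and rotationAxis must be numeric(3)")
  if (length(object@volumeShape) != 3L || length(object@voxelSize) != 3L)
    return("volumeShape and voxelSize must have 3 entries (z, y, x)")
  TRUE
})

#' @rdname SimulationParams-class
#' @param nStartCells,nDivisionRounds,cellCycleMean,cellCycleJitter,frameInterval,nFrames,embryoRadius,nucleusSigma,motionSd,driftVelocity,rotationDegPerFrame,rotationAxis,convertedCellIndex,redDilutionPerDivision,backgroundBase,backgroundRamp,noiseModel,spuriousRate,spuriousClearance,volumeShape,voxelSize,seed
#'   see the class slots.
#' @export
simulationParams <- function(nStartCells = 4L, nDivisionRounds = 3L,
                             cellCycleMean = 200, cellCycleJitter = 35,
                             frameInterval = 15, nFrames = 60L,
                             embryoRadius = 45, nucleusSigma = 4,
                             motionSd = 0.35, driftVelocity = c(0, 0, 0),
                             rotationDegPerFrame = 0,
                             rotationAxis = c(0, 0, 1),
                             convertedCellIndex = 0L,
                             redDilutionPerDivision = 0.5,
                             backgroundBase = 10, backgroundRamp = 0.2,
                             noiseModel = "poisson", spuriousRate = 1.5,
                             spuriousClearance = 12,
                             volumeShape = c(80L, 96L, 96L),
                             voxelSize = c(3, 2, 2), seed = 1L) {
  new("SimulationParams", nStartCells = as.integer(nStartCells),
      nDivisionRounds = as.integer(nDivisionRounds),
      cellCycleMean = cellCycleMean, cellCycleJitter = cellCycleJitter,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      embryoRadius = embryoRadius, nucleusSigma = nucleusSigma,
      motionSd = motionSd, driftVelocity = as.numeric(driftVelocity),
      rotationDegPerFrame = rotationDegPerFrame,
      rotationAxis = as.numeric(rotationAxis),
      convertedCellIndex = as.integer(convertedCellIndex),
      redDilutionPerDivision = redDilutionPerDivision,
      backgroundBase = backgroundBase, backgroundRamp = backgroundRamp,
      noiseModel = noiseModel, spuriousRate = spuriousRate,
      spuriousClearance = spuriousClearance,
      volumeShape = as.integer(volumeShape), voxelSize = as.numeric(voxelSize),
      seed = as.integer(seed))
}

#' Simulation presets
#'
#' Two acquisition archetypes mirroring the rotating/non-rotating embryo
#' dichotomy, plus a crowded variant used to study channel separation:
#' \describe{
#'   \item{rotating}{15-min frames, 60 frames, strong rigid drift
#'     ((5, 4, 3) um/frame) plus 5 degrees/frame rotation about a tilted
#'     axis.}
#'   \item{stationary}{5-min frames, 160 frames, per-cell jitter only.}
#'   \item{crowded}{two division rounds squeezed into a smaller embryo with
#'     larger per-cell motion, bringing red and green nuclei into close
#'     contact.}
#' }
#' All presets are clean acquisitions (spuriousRate 0); enable background
#' injection explicitly via \code{spuriousRate}.
#'
#' @param preset one of "rotating", "stationary", "crowded".
#' @param ... overrides passed to \code{\link{simulationParams}}.
#' @return A \linkS4class{SimulationParams}.
#' @export
simulationPreset <- function(preset = c("rotating", "stationary", "crowded"),
                             ...) {
  preset <- match.arg(preset)
  ## presets are clean acquisitions (no background/spurious spots): they
  ## carry the motion regimes; background injection is a separate,
  ## explicitly-enabled ingredient (spuriousRate > 0)
  base <- switch(preset,
    rotating = list(frameInterval = 15, nFrames = 60L, cellCycleMean = 200,
                    motionSd = 0.35, driftVelocity = c(5, 4, 3),
                    rotationDegPerFrame = 5, spuriousRate = 0,
                    rotationAxis = unitVector(c(0.3, 0.2, 1))),
    stationary = list(frameInterval = 5, nFrames = 160L, cellCycleMean = 200,
                      motionSd = 0.3, driftVelocity = c(0, 0, 0),
                      rotationDegPerFrame = 0, spuriousRate = 0),
    crowded = list(frameInterval = 5, nFrames = 110L, cellCycleMean = 200,
                   nDivisionRounds = 2L, embryoRadius = 26, motionSd = 1.2,
                   driftVelocity = c(0, 0, 0), rotationDegPerFrame = 0,
                   spuriousRate = 0))
  args <- utils::modifyList(base, list(...))
  do.call(simulationParams, args)
}

#' GroundTruth: everything the simulator knows
#'
#' @slot cells data.frame: frame, cell, x, y, z (world um), red, generation,
#'   intensityGreen, intensityRed.
#' @slot pedigree data.frame: cell, parent (NA for founders), birthFrame,
#'   lastFrame, founder (ancestral founder cell id).
#' @slot transforms list of per-frame \linkS4class{RigidTransform} mapping
#'   world coordinates into the drift/rotation-free embryo frame.
#' @slot spurious data.frame of injected spurious spots (frame, channel,
#'   x, y, z).
#' @slot params the generating \linkS4class{SimulationParams}.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(cells = "data.frame", pedigree = "data.frame",
                 transforms = "list", spurious = "data.frame",
                 params = "SimulationParams"))

setMethod("show", "GroundTruth", function(object) {
  nf <- length(object@transforms)
  final <- sum(object@cells$frame == nf - 1L)
  cat("GroundTruth:", nf, "frame(s),", nrow(object@pedigree), "cell(s) total,",
      final, "at the last frame,", nrow(object@spurious), "spurious spot(s)\n")
})

## place n founders on a shell, enforcing a minimum separation
placeFounders <- function(n, radius, minSep, maxTries = 2000L) {
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (tries in seq_len(maxTries)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    r <- radius * runif(1, .SHELL_FRAC[1], 0.8)
    cand <- u * r
    if (placed == 0L ||
        min(sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2))) >= minSep) {
      placed <- placed + 1L
      pos[placed, ] <- cand
      if (placed == n) return(pos)
    }
  }
  stopf("could not place %d founder cells with separation %g um inside radius %g um",
        n, minSep, radius)
}

## a few repulsion iterations resolving pairs closer than minSep; nuclei are
## kept in a peripheral shell (blastomeres appose the zona pellucida as the
## embryo compacts and cavitates, so nuclei sit near the periphery).
## `mobility` weights split each pairwise correction: freshly placed
## daughters (mobility 1) squeeze into the free space while established
## nuclei (small mobility) hold their positions, so a division does not
## shove the rest of the embryo - and with it the red centre of mass -
## around.
.SHELL_FRAC <- c(0.6, 0.85)

relaxOverlaps <- function(pos, minSep, embryoRadius, iterations = 12L,
                          mobility = rep(1, nrow(pos)), maxStep = Inf) {
  shell <- .SHELL_FRAC * embryoRadius
  start <- pos
  for (it in seq_len(iterations)) {
    d <- crossDist(pos, pos)
    diag(d) <- Inf
    close <- which(d < minSep & upper.tri(d), arr.ind = TRUE)
    if (!nrow(close)) break
    for (k in seq_len(nrow(close))) {
      i <- close[k, 1]; j <- close[k, 2]
      dir <- pos[j, ] - pos[i, ]
      len <- sqrt(sum(dir^2))
      dir <- if (len < 1e-9) c(1, 0, 0) else dir / len
      push <- minSep - len + 2e-3
      wi <- mobility[i] / (mobility[i] + mobility[j])
      pos[i, ] <- pos[i, ] - dir * push * wi
      pos[j, ] <- pos[j, ] + dir * push * (1 - wi)
    }
    pos <- clampShell(pos, shell)
  }
  pos <- clampShell(pos, shell)
  if (is.finite(maxStep)) {
    ## cells rearrange at a bounded speed: cap the per-frame displacement
    ## that the tiling relaxation may add, letting crowded configurations
    ## (e.g. a fresh daughter pair) spread over several frames
    disp <- pos - start
    len <- sqrt(rowSums(disp^2))
    over <- len > maxStep
    if (any(over)) pos[over, ] <- start[over, ] +
        disp[over, , drop = FALSE] * (maxStep / len[over])
  }
  pos
}

clampShell <- function(pos, shell) {
  r <- sqrt(rowSums(pos^2))
  r[r < 1e-9] <- 1e-9
  rc <- pmin(pmax(r, shell[1]), shell[2])
  pos * (rc / r)
}

#' Simulate a dividing, drifting, photoconverted embryo
#'
#' Founder cells are placed without overlap inside the embryo sphere; per
#' frame, cells get Brownian jitter, the whole embryo gets rigid drift and
#' rotation, and cells divide at jittered cell-cycle times (daughters placed
#' at +/- nucleusSigma along a random direction, then relaxed). Every cell
#' emits a green spot; descendants of the converted founder also emit a red
#' spot whose intensity is diluted per completed division. Spurious spots are
#' injected per frame and channel: green ones outside the spot cloud (where
#' rising illumination produces false detections), red ones anywhere at
#' least `spuriousClearance` from any true nucleus (background that fails
#' colocalization). Deterministic under a fixed seed.
#'
#' @param params A \linkS4class{SimulationParams}.
#' @return list(series = \linkS4class{SpotSeries}, truth =
#'   \linkS4class{GroundTruth}).
#' @export
simulateEmbryo <- function(params) {
  validObject(params)
  set.seed(params@seed)
  sigma <- params@nucleusSigma
  ## blastomeres tile the embryo: the centre-to-centre spacing is set by the
  ## cell size (shell area / cell count), not by the nuclear size, until the
  ## cells become small enough that nuclear exclusion takes over
  shellMid <- mean(.SHELL_FRAC) * params@embryoRadius
  cellSep <- function(n) max(2.2 * sigma,
                             0.65 * sqrt(4 * pi * shellMid^2 / n))
  minSep <- cellSep(params@nStartCells)
  ## histone-fusion signal is partitioned between daughters at division, so
  ## per-nucleus intensity halves per generation in BOTH channels (fresh
  ## synthesis is neglected on these timescales); this is what makes the
  ## fluorescence centre of mass of each channel stable across divisions
  greenIntensity <- 100
  ## embryo-frame state
  pos <- placeFounders(params@nStartCells, params@embryoRadius,
                       0.85 * minSep)
  nCells <- params@nStartCells
  cellIds <- seq_len(nCells)
  generation <- rep(0L, nCells)
  founder <- cellIds
  redFlag <- founder == params@convertedCellIndex + 1L
  pedigree <- data.frame(cell = cellIds, parent = NA_integer_,
                         birthFrame = 0L, lastFrame = NA_integer_,
                         founder = founder)
  divTime <- params@cellCycleMean +
    rnorm(nCells, 0, params@cellCycleJitter)
  nextCell <- nCells + 1L
  center0 <- c(sum(params@voxelSize[3] * params@volumeShape[3]) / 2,
               sum(params@voxelSize[2] * params@volumeShape[2]) / 2,
               sum(params@voxelSize[1] * params@volumeShape[1]) / 2)
  cellRows <- list(); spuriousRows <- list(); spotRows <- list()
  transforms <- vector("list", params@nFrames)
  nextSpot <- 1L
  for (fr in seq_len(params@nFrames) - 1L) {
    tMin <- fr * params@frameInterval
    if (fr > 0L) {
      ## Brownian per-cell jitter in the embryo frame
      pos <- pos + matrix(rnorm(3 * nCells, 0, params@motionSd), nCells, 3)
      ## divisions due by this frame
      due <- which(divTime <= tMin & generation < params@nDivisionRounds)
      fresh <- integer()
      for (i in due) {
        ## division orientation follows the free space around the mother
        ## (Hertwig-style): pick, among random candidate axes, the one whose
        ## daughter positions stay farthest from the neighbouring nuclei, so
        ## divisions do not shove neighbours (and with them the red centre
        ## of mass) around
        half <- 1.1 * sigma
        others <- pos[-i, , drop = FALSE]
        best <- NULL; bestScore <- -Inf
        for (cand in 1:12) {
          uu <- rnorm(3); uu <- uu / sqrt(sum(uu^2))
          p1 <- pos[i, ] + half * uu; p2 <- pos[i, ] - half * uu
          score <- if (nrow(others)) {
            min(crossDist(rbind(p1, p2), others))
          } else 1
          if (score > bestScore) { bestScore <- score; best <- uu }
        }
        u <- best
        mother <- cellIds[i]
        pedigree$lastFrame[pedigree$cell == mother] <- fr - 1L
        d1 <- pos[i, ] + half * u
        d2 <- pos[i, ] - half * u
        pos[i, ] <- d1
        pos <- rbind(pos, d2)
        newIds <- c(nextCell, nextCell + 1L)
        ## daughter 1 replaces the mother's row; daughter 2 appended
        cellIds[i] <- newIds[1]
        cellIds <- c(cellIds, newIds[2])
        generation[i] <- generation[i] + 1L
        generation <- c(generation, generation[i])
        founder <- c(founder, founder[i])
        redFlag <- c(redFlag, redFlag[i])
        pedigree <- rbind(pedigree, data.frame(
          cell = newIds, parent = mother, birthFrame = fr,
          lastFrame = NA_integer_,
          founder = rep(founder[i], 2)))
        newDiv <- tMin + params@cellCycleMean +
          rnorm(2, 0, params@cellCycleJitter)
        divTime[i] <- newDiv[1]
        divTime <- c(divTime, newDiv[2])
        nextCell <- nextCell + 2L
        nCells <- nCells + 1L
        fresh <- c(fresh, i, nCells)
      }
      mobility <- rep(0.05, nCells)
      mobility[fresh] <- 1
      pos <- relaxOverlaps(pos, cellSep(nCells), params@embryoRadius,
                           mobility = mobility, maxStep = 2.5)
      ## the zona pellucida confines the blastomere mass: collective motion
      ## of the whole cloud is rigid drift (modeled explicitly), so the
      ## embryo-frame cloud stays centred
      pos <- sweep(pos, 2, colMeans(pos))
    }
    ## rigid world placement
    R <- rotationAboutAxis(params@rotationAxis, fr * params@rotationDegPerFrame)
    center <- center0 + fr * params@driftVelocity
    world <- sweep(pos %*% t(R), 2, -center)
    transforms[[fr + 1L]] <- RigidTransform(rotation = t(R), translation = center)
    redIntensity <- ifelse(redFlag,
                           greenIntensity * params@redDilutionPerDivision^generation,
                           0)
    greenCell <- greenIntensity * 0.5^generation
    cellRows[[fr + 1L]] <- data.frame(
      frame = fr, cell = cellIds, x = world[, 1], y = world[, 2], z = world[, 3],
      red = redFlag, generation = generation,
      intensityGreen = greenCell, intensityRed = redIntensity)
    ## true spots
    mkSpots <- function(sel, channel, intensity) {
      k <- sum(sel)
      if (!k) return(NULL)
      df <- data.frame(id = seq.int(nextSpot, length.out = k), frame = fr,
                       channel = channel, x = world[sel, 1], y = world[sel, 2],
                       z = world[sel, 3], radius = sqrt(3) * sigma,
                       intensity = intensity[sel])
      nextSpot <<- nextSpot + k
      df
    }
    spotRows[[length(spotRows) + 1L]] <-
      mkSpots(rep(TRUE, nCells), "green", greenCell)
    spotRows[[length(spotRows) + 1L]] <- mkSpots(redFlag, "red", redIntensity)
    ## spurious spots
    cloudCom <- colMeans(world)
    cloudMax <- max(sqrt(colSums((t(world) - cloudCom)^2)))
    ## background false detections track the illumination ramp: laser power
    ## is raised to follow the red signal as it dilutes with division, so
    ## background is absent before the first division round and grows
    ## geometrically with the generation afterwards, reaching spuriousRate
    ## per channel per frame at the final round
    ## quadratic response: a false detection needs a background fluctuation
    ## to cross the (fixed) detection threshold, so the rate grows faster
    ## than the background itself
    rampRate <- params@spuriousRate *
      ((2^mean(generation) - 1) / max(1, 2^params@nDivisionRounds - 1))^2
    for (channel in .CHANNELS) {
      nSp <- rpois(1, rampRate)
      if (!nSp) next
      sp <- matrix(NA_real_, 0, 3)
      for (k in seq_len(nSp)) {
        if (channel == "green") {
          ## tight distance band: the extent estimator is self-referential
          ## (spurious spots inflate it), and a narrow band keeps every
          ## spurious spot beyond the inflated keep radius
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- cloudCom + u * cloudMax * runif(1, 2.9, 3.0)
        } else {
          cand <- NULL
          for (try in 1:50) {
            u <- rnorm(3); u <- u / sqrt(sum(u^2))
            p <- cloudCom + u * cloudMax * 1.6 * runif(1)^(1 / 3)
            if (min(sqrt(colSums((t(world) - p)^2))) >= params@spuriousClearance) {
              cand <- p
              break
            }
          }
          if (is.null(cand)) next
        }
        sp <- rbind(sp, cand)
      }
      if (!nrow(sp)) next
      spuriousRows[[length(spuriousRows) + 1L]] <- data.frame(
        frame = fr, channel = channel, x = sp[, 1], y = sp[, 2], z = sp[, 3])
      df <- data.frame(id = seq.int(nextSpot, length.out = nrow(sp)), frame = fr,
                       channel = channel, x = sp[, 1], y = sp[, 2], z = sp[, 3],
                       radius = sqrt(3) * sigma,
                       intensity = params@backgroundBase * 2)
      nextSpot <- nextSpot + nrow(sp)
      spotRows[[length(spotRows) + 1L]] <- df
    }
  }
  pedigree$lastFrame[is.na(pedigree$lastFrame)] <- params@nFrames - 1L
  cells <- do.call(rbind, cellRows)
  spurious <- if (length(spuriousRows)) do.call(rbind, spuriousRows) else
    data.frame(frame = integer(), channel = character(), x = numeric(),
               y = numeric(), z = numeric())
  rownames(cells) <- rownames(spurious) <- NULL
  spotsDf <- do.call(rbind, c(spotRows, list(emptySpotFrame())))
  rownames(spotsDf) <- NULL
  series <- SpotSeries(spotsDf, nFrames = params@nFrames,
                       frameInterval = params@frameInterval,
                       voxelSize = params@voxelSize)
  truth <- new("GroundTruth", cells = cells, pedigree = pedigree,
               transforms = transforms, spurious = spurious, params = params)
  list(series = series, truth = truth)
}

## which cell of the pedigree was the ancestor of `cell` alive at `frame`?
ancestorAt <- function(pedigree, cell, frame) {
  cur <- cell
  repeat {
    row <- pedigree[pedigree$cell == cur, ]
    if (row$birthFrame <= frame) return(cur)
    if (is.na(row$parent)) return(cur)
    cur <- row$parent
  }
}

#' Ground-truth lineage forest
#'
#' Builds the true \linkS4class{LineageForest} over the simulated cells, one
#' tree per founder, optionally retaining only every k-th frame (frames are
#' then renumbered contiguously, matching \code{\link{subsampleTime}}).
#'
#' @param truth A \linkS4class{GroundTruth}.
#' @param keepEvery integer k >= 1.
#' @return A \linkS4class{LineageForest}; the converted founder's tree is
#'   tagged "red", the rest "green".
#' @export
truthForest <- function(truth, keepEvery = 1L) {
  if (keepEvery < 1L) stopf("keepEvery must be >= 1")
  cells <- truth@cells
  keptFrames <- seq(0L, max(cells$frame), by = keepEvery)
  cells <- cells[cells$frame %in% keptFrames, , drop = FALSE]
  cells$newFrame <- match(cells$frame, keptFrames) - 1L
  cells$nodeId <- seq_len(nrow(cells))
  key <- function(frame, cell) paste(frame, cell)
  lookup <- setNames(cells$nodeId, key(cells$frame, cells$cell))
  edges <- list()
  ped <- truth@pedigree
  for (m in seq_along(keptFrames)[-1]) {
    f0 <- keptFrames[m - 1L]; f1 <- keptFrames[m]
    now <- cells[cells$frame == f1, , drop = FALSE]
    for (i in seq_len(nrow(now))) {
      anc <- ancestorAt(ped, now$cell[i], f0)
      from <- lookup[key(f0, anc)]
      if (!is.na(from))
        edges[[length(edges) + 1L]] <- data.frame(from = unname(from),
                                                  to = now$nodeId[i])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(), to = integer())
  converted <- truth@params@convertedCellIndex + 1L
  founderOf <- setNames(ped$founder, ped$cell)
  cells$tree <- as.integer(founderOf[as.character(cells$cell)])
  cells$channel <- ifelse(cells$tree == converted, "red", "green")
  roots <- cells[cells$frame == 0L, , drop = FALSE]
  roots <- roots[order(roots$tree), , drop = FALSE]
  trees <- data.frame(tree = roots$tree, channel = roots$channel,
                      rootFrame = 0L, rootX = roots$x, rootY = roots$y,
                      rootZ = roots$z)
  nodes <- data.frame(id = cells$nodeId, tree = cells$tree,
                      frame = cells$newFrame, x = cells$x, y = cells$y,
                      z = cells$z, channel = cells$channel, synthetic = FALSE)
  LineageForest(nodes, edges, trees)
}

#' Render ground truth into image volumes
#'
#' Each cell becomes an anisotropy-aware Gaussian blob of scale nucleusSigma
#' and its channel intensity; a constant-plus-ramp background is added and
#' Poisson noise applied per the params. Cells outside the field of view are
#' clipped silently.
#'
#' @param truth A \linkS4class{GroundTruth}.
#' @param params A \linkS4class{SimulationParams} (defaults to the
#'   generating ones).
#' @param frames 0-based frames to render (default all).
#' @param channels channels to render (default both).
#' @return list of \linkS4class{ImageVolume}, ordered frame-major.
#' @export
renderVolumes <- function(truth, params = truth@params, frames = NULL,
                          channels = .CHANNELS) {
  if (is.null(frames)) frames <- sort(unique(truth@cells$frame))
  d <- params@volumeShape
  vs <- params@voxelSize
  out <- list()
  for (fr in frames) {
    cells <- truth@cells[truth@cells$frame == fr, , drop = FALSE]
    bg <- params@backgroundBase + params@backgroundRamp * fr
    for (channel in channels) {
      vox <- array(bg, dim = d)
      amp <- if (channel == "green") cells$intensityGreen else cells$intensityRed
      sel <- amp > 0
      if (any(sel))
        vox <- addGaussianBlobs(vox, vs,
                                cbind(cells$x[sel], cells$y[sel], cells$z[sel]),
                                amp[sel], params@nucleusSigma)
      if (params@noiseModel == "poisson") {
        vox <- array(rpois(length(vox), vox), dim = d)
      }
      out[[length(out) + 1L]] <- ImageVolume(vox, voxelSize = vs, frame = fr,
                                             channel = channel)
    }
  }
  out
}

## add isotropic (in um) Gaussian blobs to a (z, y, x) voxel array
addGaussianBlobs <- function(vox, vs, centers, amplitudes, sigma) {
  d <- dim(vox)
  zc <- (seq_len(d[1]) - 0.5) * vs[1]
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  xc <- (seq_len(d[3]) - 0.5) * vs[3]
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; cz <- centers[i, 3]
    kz <- which(abs(zc - cz) <= 4 * sigma)
    ky <- which(abs(yc - cy) <= 4 * sigma)
    kx <- which(abs(xc - cx) <= 4 * sigma)
    if (!length(kz) || !length(ky) || !length(kx)) next
    gz <- exp(-(zc[kz] - cz)^2 / (2 * sigma^2))
    gy <- exp(-(yc[ky] - cy)^2 / (2 * sigma^2))
    gx <- exp(-(xc[kx] - cx)^2 / (2 * sigma^2))
    blob <- amplitudes[i] * outer(outer(gz, gy), gx)
    vox[kz, ky, kx] <- vox[kz, ky, kx] + blob
  }
  vox
}

#' Subsample a series in time
#'
#' Retains frames 0, k, 2k, ...; frame indices are renumbered contiguously
#' and the frame interval multiplied by k.
#'
#' @param series A \linkS4class{SpotSeries}.
#' @param keepEvery integer k >= 1.
#' @return The subsampled \linkS4class{SpotSeries}.
#' @export
subsampleTime <- function(series, keepEvery) {
  if (keepEvery < 1L) stopf("keepEvery must be >= 1 (got %s)", keepEvery)
  keepEvery <- as.integer(keepEvery)
  if (keepEvery == 1L) return(series)
  kept <- seq(0L, nFrames(series) - 1L, by = keepEvery)
  s <- spots(series)
  s <- s[s$frame %in% kept, , drop = FALSE]
  s$frame <- match(s$frame, kept) - 1L
  SpotSeries(s, nFrames = length(kept),
             frameInterval = frameInterval(series) * keepEvery,
             voxelSize = voxelSize(series))
}
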