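## End-to-end orchestration: detect (if volumes) -> first validation ->
## alignment -> second validation on the re-aligned embryo -> channel
## subsetting -> two-channel tracing -> export, plus evaluation against a
## known ground truth.

.CONFIG_KEYS <- list(
  input = c("spots", "volumes", "frame_interval", "voxel_size"),
  detection = c("sigma_min", "sigma_max", "n_scales", "threshold"),
  validation = c("radius_factor", "merge_distance", "coloc_distance",
                 "recovery_radius", "recovery"),
  alignment = c("enabled", "margin"),
  tracking = c("max_link_distance", "division_distance", "gap_closing",
               "two_channel", "coloc_distance"),
  output = c("dir"),
  top = c("input", "detection", "validation", "alignment", "tracking",
          "output", "seed", "log_level"))

#' Validate and normalize a pipeline configuration
#'
#' Accepts a nested list or a YAML file path; unknown keys are rejected and
#' referenced input paths must exist.
#'
#' @param config nested list or YAML path.
#' @return The normalized config list.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), setdiff(.CONFIG_KEYS$top, "top"))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (section in intersect(names(config), names(.CONFIG_KEYS))) {
    bad <- setdiff(names(config[[section]]), .CONFIG_KEYS[[section]])
    if (length(bad))
      stopf("unknown key(s) in config section '%s': %s", section,
            paste(bad, collapse = ", "))
  }
  if (is.null(config$input) ||
      (is.null(config$input$spots) && is.null(config$input$volumes)))
    stopf("config must provide input$spots (CSV) or input$volumes (TIFF dir)")
  path <- config$input$spots %||% config$input$volumes
  if (!file.exists(path)) stopf("input path does not exist: %s", path)
  if (is.null(config$output$dir)) stopf("config must provide output$dir")
  config
}

#' Validate, align and trace a spot series in memory
#'
#' The compute core of the pipeline: first validation, alignment (optional),
#' second validation on the re-aligned raw spots, channel subsetting and
#' two-channel (or single-channel) tracing. \code{\link{runPipeline}} wraps
#' this with file I/O and logging.
#'
#' @param series raw \linkS4class{SpotSeries}.
#' @param vparams A \linkS4class{ValidationParams}.
#' @param lparams A \linkS4class{LinkingParams}.
#' @param align logical: apply drift/rotation correction.
#' @param twoChannel logical: trace red and green-minus-red separately
#'   (otherwise the whole green channel at once).
#' @param colocDistance um used for the green-minus-red subsetting.
#' @return list(forest, alignment (\linkS4class{AlignmentResult} or NULL),
#'   validated (the post-alignment validated series), reports).
#' @export
traceSeries <- function(series, vparams = validationParams(),
                        lparams = linkingParams(), align = TRUE,
                        twoChannel = TRUE,
                        colocDistance = vparams@colocDistance) {
  v1 <- validateSeries(series, vparams)
  if (align) {
    al <- alignSeries(v1$series)
    aligned <- applyAlignment(series, al$result)
  } else {
    al <- NULL
    aligned <- series
  }
  v2 <- validateSeries(aligned, vparams)
  s <- spots(v2$series)
  nf <- nFrames(v2$series)
  fi <- frameInterval(v2$series)
  vs <- voxelSize(v2$series)
  if (twoChannel) {
    redSeries <- SpotSeries(s[s$channel == "red", , drop = FALSE],
                            nFrames = nf, frameInterval = fi, voxelSize = vs)
    gmr <- do.call(rbind, c(lapply(seq_len(nf) - 1L, function(fr)
      subsetGreenMinusRed(frameSpots(v2$series, fr, "green"),
                          frameSpots(v2$series, fr, "red"), colocDistance)),
      list(emptySpotFrame())))
    gmrSeries <- SpotSeries(gmr, nFrames = nf, frameInterval = fi,
                            voxelSize = vs)
    forest <- traceTwoChannel(redSeries, gmrSeries, lparams)
  } else {
    greenSeries <- SpotSeries(s[s$channel == "green", , drop = FALSE],
                              nFrames = nf, frameInterval = fi, voxelSize = vs)
    forest <- graphToForest(buildTrackGraph(greenSeries, lparams), "green")
  }
  list(forest = forest, alignment = if (align) al$result else NULL,
       validated = v2$series,
       reports = list(first = v1$report, second = v2$report))
}

pipelineLog <- function(con, level, stage, msg) {
  line <- sprintf("[%s] %s: %s", level, stage, msg)
  writeLines(line, con)
  invisible(line)
}

#' Run the full pipeline
#'
#' Stages: detect (when the input is a volume directory) -> first validation
#' -> alignment -> second validation on the re-aligned raw spots -> channel
#' subsetting -> two-channel tracing -> export. All intermediates, the
#' per-frame transforms, the validation reports, a structured log and a
#' frozen copy of the resolved configuration are written into the run
#' directory. Deterministic given config and inputs.
#'
#' @param config nested list or YAML path (see \code{\link{pipelineConfig}}).
#' @return Invisibly, a list with the run directory, the lineage forest, the
#'   alignment result and the validation reports.
#' @export
runPipeline <- function(config) {
  config <- pipelineConfig(config)
  dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
  logCon <- file(file.path(config$output$dir, "run.log"), "w")
  on.exit(close(logCon))
  yaml::write_yaml(config, file.path(config$output$dir, "config.yaml"))
  stage <- "startup"
  result <- tryCatch({
    vs <- as.numeric(config$input$voxel_size %||% c(3, 2, 2))
    fi <- as.numeric(config$input$frame_interval %||% 15)
    ## --- input / detection -------------------------------------------------
    if (!is.null(config$input$spots)) {
      stage <- "input"
      raw <- readSpotTable(config$input$spots, frameInterval = fi, voxelSize = vs)
      pipelineLog(logCon, "INFO", stage,
                  sprintf("read %d spot(s) over %d frame(s) from %s",
                          nrow(spots(raw)), nFrames(raw), config$input$spots))
    } else {
      stage <- "detect"
      det <- config$detection %||% list()
      volumes <- readVolumeSequence(config$input$volumes, voxelSize = vs)
      rows <- list()
      nextId <- 1L
      for (v in volumes) {
        p <- detectionParams(sigmaMin = det$sigma_min %||% 2.5,
                             sigmaMax = det$sigma_max %||% 8,
                             nScales = det$n_scales %||% 5L,
                             threshold = det$threshold %||% 2,
                             channel = v@channel)
        sp <- detectSpots(v, p)
        if (nrow(sp)) {
          sp$id <- seq.int(nextId, length.out = nrow(sp))
          nextId <- nextId + nrow(sp)
          rows[[length(rows) + 1L]] <- sp
        }
      }
      raw <- SpotSeries(do.call(rbind, c(rows, list(emptySpotFrame()))),
                        frameInterval = fi, voxelSize = vs)
      pipelineLog(logCon, "INFO", stage,
                  sprintf("detected %d spot(s) over %d volume(s)",
                          nrow(spots(raw)), length(volumes)))
    }
    writeSpotTable(raw, file.path(config$output$dir, "spots_raw.csv"))
    ## --- first validation --------------------------------------------------
    stage <- "validate"
    val <- config$validation %||% list()
    vparams <- validationParams(
      radiusFactor = val$radius_factor %||% 0.78,
      mergeDistance = val$merge_distance %||% 4,
      colocDistance = val$coloc_distance %||% 4,
      recoveryRadius = val$recovery_radius %||% 6,
      recoveryEnabled = val$recovery %||% TRUE)
    v1 <- validateSeries(raw, vparams)
    pipelineLog(logCon, "INFO", stage, sprintf(
      "first validation: %d -> %d spot(s)", nrow(spots(raw)), nrow(spots(v1$series))))
    writeSpotTable(v1$series, file.path(config$output$dir, "spots_valid.csv"))
    ## --- alignment ---------------------------------------------------------
    alignmentEnabled <- config$alignment$enabled %||% TRUE
    if (alignmentEnabled) {
      stage <- "align"
      al <- alignSeries(v1$series)
      alignedRaw <- applyAlignment(raw, al$result)
      pipelineLog(logCon, "INFO", stage, sprintf(
        "aligned %d frame(s); mean drift %.3f um; rolls %s",
        nFrames(v1$series), mean(al$result@drift[-1]),
        paste(al$result@roll, collapse = ",")))
      writeTransforms(al$result, file.path(config$output$dir, "transforms.json"))
    } else {
      al <- NULL
      alignedRaw <- raw
      pipelineLog(logCon, "INFO", "align", "alignment disabled")
    }
    ## --- second validation on the re-aligned embryo ------------------------
    stage <- "validate2"
    v2 <- validateSeries(alignedRaw, vparams)
    pipelineLog(logCon, "INFO", stage, sprintf(
      "second validation: %d -> %d spot(s)", nrow(spots(alignedRaw)),
      nrow(spots(v2$series))))
    writeSpotTable(v2$series, file.path(config$output$dir, "spots_aligned.csv"))
    ## --- subsetting and tracing --------------------------------------------
    stage <- "trace"
    trk <- config$tracking %||% list()
    lparams <- linkingParams(
      maxLinkDistance = trk$max_link_distance %||% 15,
      divisionDistance = trk$division_distance %||% 15,
      allowGap = trk$gap_closing %||% FALSE)
    colocD <- trk$coloc_distance %||% (val$coloc_distance %||% 4)
    twoChannel <- trk$two_channel %||% TRUE
    s <- spots(v2$series)
    if (twoChannel) {
      redSeries <- SpotSeries(s[s$channel == "red", , drop = FALSE],
                              nFrames = nFrames(v2$series),
                              frameInterval = frameInterval(v2$series),
                              voxelSize = vs)
      gmr <- do.call(rbind, c(lapply(seq_len(nFrames(v2$series)) - 1L, function(fr)
        subsetGreenMinusRed(frameSpots(v2$series, fr, "green"),
                            frameSpots(v2$series, fr, "red"), colocD)),
        list(emptySpotFrame())))
      gmrSeries <- SpotSeries(gmr, nFrames = nFrames(v2$series),
                              frameInterval = frameInterval(v2$series),
                              voxelSize = vs)
      forest <- traceTwoChannel(redSeries, gmrSeries, lparams)
    } else {
      greenSeries <- SpotSeries(s[s$channel == "green", , drop = FALSE],
                                nFrames = nFrames(v2$series),
                                frameInterval = frameInterval(v2$series),
                                voxelSize = vs)
      forest <- graphToForest(buildTrackGraph(greenSeries, lparams), "green")
    }
    ndiv <- if (nrow(forest@edges)) sum(table(forest@edges$from) == 2L) else 0L
    pipelineLog(logCon, "INFO", stage, sprintf(
      "traced %d tree(s) (%d red), %d division(s)", nrow(forest@trees),
      sum(forest@trees$channel == "red"), ndiv))
    ## --- export -------------------------------------------------------------
    stage <- "export"
    writeLineageForest(forest, file.path(config$output$dir, "forest.json"))
    exportCTCTracks(forest, file.path(config$output$dir, "tracks.txt"))
    box <- cropBounds(v2$series, margin = config$alignment$margin %||% 10)
    jsonlite::write_json(list(min = box@min, max = box@max, margin = box@margin),
                         file.path(config$output$dir, "cropbox.json"),
                         auto_unbox = FALSE, digits = NA)
    report <- list(firstValidation = v1$report, secondValidation = v2$report)
    jsonlite::write_json(report, file.path(config$output$dir, "report.json"),
                         dataframe = "rows", digits = NA)
    pipelineLog(logCon, "INFO", stage, "run complete")
    list(dir = config$output$dir, forest = forest,
         alignment = if (is.null(al)) NULL else al$result,
         validation = report, cropBox = box)
  }, error = function(e) {
    pipelineLog(logCon, "ERROR", stage, conditionMessage(e))
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(result)
}

#' Write per-frame alignment transforms to JSON
#'
#' Records, per frame: origin, axis, roll and the full rotation matrix.
#'
#' @param result An \linkS4class{AlignmentResult}.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
writeTransforms <- function(result, path) {
  obj <- lapply(seq_along(result@transforms), function(i) {
    rf <- result@referenceFrames[[i]]
    list(frame = i - 1L, origin = rf@origin, axis = rf@axis, roll = rf@roll,
         drift = result@drift[i], axisReused = result@axisReused[i],
         rotation = result@transforms[[i]]@rotation)
  })
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read alignment transforms written by \code{\link{writeTransforms}}
#'
#' @param path JSON path.
#' @return An \linkS4class{AlignmentResult}.
#' @export
readTransforms <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  refs <- lapply(obj, function(o)
    ReferenceFrame(unlist(o$origin), unlist(o$axis), o$roll))
  trs <- lapply(obj, function(o) {
    R <- if (is.matrix(o$rotation)) o$rotation else
      do.call(rbind, lapply(o$rotation, unlist))
    RigidTransform(rotation = R, translation = unlist(o$origin))
  })
  new("AlignmentResult", referenceFrames = refs, transforms = trs,
      roll = vapply(obj, `[[`, numeric(1), "roll"),
      drift = vapply(obj, `[[`, numeric(1), "drift"),
      axisReused = vapply(obj, `[[`, logical(1), "axisReused"))
}

#' Evaluate a computed forest against ground truth
#'
#' Reports the total condensed-tree edit distance (spurious computed trees
#' excluded), a per-tree breakdown, and link-level precision/recall against
#' the truth edges. Computed spots are matched to truth cells frame-wise by
#' nearest neighbour within `matchRadius` before edges are compared. If the
#' computed forest lives in aligned coordinates, pass the alignment's
#' per-frame transforms so the truth is expressed in the same frame.
#'
#' @param computed A \linkS4class{LineageForest} (from the pipeline).
#' @param truth A \linkS4class{LineageForest} (e.g. \code{\link{truthForest}}).
#' @param transforms optional list of per-frame \linkS4class{RigidTransform}
#'   applied to the truth positions (an \linkS4class{AlignmentResult} is
#'   also accepted).
#' @param costs A \linkS4class{TreeEditCosts}.
#' @param timeWeight um per frame for origin matching.
#' @param minTrackLength,expectedRootFrame spurious-tree rule for the
#'   computed forest.
#' @param matchRadius um: one nuclear radius.
#' @return list(totalDistance, pairs, excludedSpurious, linkPrecision,
#'   linkRecall, warning flag for an empty computed forest).
#' @export
evaluateAgainstTruth <- function(computed, truth, transforms = NULL,
                                 costs = treeEditCosts(), timeWeight = 1,
                                 minTrackLength = 10L, expectedRootFrame = 0L,
                                 matchRadius = 7) {
  if (is(transforms, "AlignmentResult")) transforms <- transforms@transforms
  truthNodes <- truth@nodes
  truthTrees <- truth@trees
  if (!is.null(transforms)) {
    for (fr in unique(truthNodes$frame)) {
      tr <- transforms[[fr + 1L]]
      sel <- truthNodes$frame == fr
      m <- applyTransform(tr, as.matrix(truthNodes[sel, c("x", "y", "z")]))
      truthNodes$x[sel] <- m[, 1]; truthNodes$y[sel] <- m[, 2]
      truthNodes$z[sel] <- m[, 3]
    }
    sel0 <- truthTrees$rootFrame + 1L
    for (i in seq_len(nrow(truthTrees))) {
      m <- applyTransform(transforms[[sel0[i]]],
                          c(truthTrees$rootX[i], truthTrees$rootY[i],
                            truthTrees$rootZ[i]))
      truthTrees$rootX[i] <- m[1]; truthTrees$rootY[i] <- m[2]
      truthTrees$rootZ[i] <- m[3]
    }
  }
  truthAligned <- LineageForest(truthNodes, truth@edges, truthTrees)
  condTruth <- condenseForest(truthAligned)
  condComputed <- condenseForest(computed)
  emptyComputed <- length(condComputed) == 0L
  if (emptyComputed) {
    total <- sum(vapply(condTruth, condensedSize, integer(1))) * costs@insert
    warning("computed forest is empty; reporting the maximal distance")
    return(list(totalDistance = total, pairs = data.frame(),
                excludedSpurious = 0L, linkPrecision = 0, linkRecall = 0,
                emptyComputed = TRUE))
  }
  spurious <- vapply(condComputed, flagSpurious, logical(1),
                     minTrackLength = minTrackLength,
                     expectedRootFrame = expectedRootFrame)
  dist <- totalForestDistance(condComputed, condTruth, costs = costs,
                              timeWeight = timeWeight, spuriousA = spurious,
                              spuriousB = logical(length(condTruth)))
  ## ---- link-level precision/recall ---------------------------------------
  compNodes <- computed@nodes
  mapToTruth <- rep(NA_integer_, nrow(compNodes))
  for (fr in unique(compNodes$frame)) {
    cSel <- which(compNodes$frame == fr)
    tSel <- which(truthNodes$frame == fr)
    if (!length(tSel)) next
    d <- crossDist(as.matrix(compNodes[cSel, c("x", "y", "z")]),
                   as.matrix(truthNodes[tSel, c("x", "y", "z")]))
    nn <- apply(d, 1, which.min)
    ok <- d[cbind(seq_along(cSel), nn)] <= matchRadius
    mapToTruth[cSel[ok]] <- truthNodes$id[tSel[nn[ok]]]
  }
  mapOf <- setNames(mapToTruth, compNodes$id)
  truthEdgeKey <- paste(truth@edges$from, truth@edges$to)
  compKeys <- paste(mapOf[as.character(computed@edges$from)],
                    mapOf[as.character(computed@edges$to)])
  correct <- compKeys %in% truthEdgeKey
  precision <- if (nrow(computed@edges)) mean(correct) else 0
  recall <- if (length(truthEdgeKey)) {
    sum(unique(compKeys[correct]) %in% truthEdgeKey) / length(truthEdgeKey)
  } else 1
  list(totalDistance = dist$total, pairs = dist$pairs,
       excludedSpurious = dist$excludedA, linkPrecision = precision,
       linkRecall = recall, emptyComputed = FALSE)
}
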