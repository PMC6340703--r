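## Parameter containers for the individual pipeline stages.

#' DetectionParams: multiscale LoG blob-detection settings
#'
#' @slot sigmaMin,sigmaMax blob scale range in micrometres (0 < min < max).
#' @slot nScales number of logarithmically spaced scales (>= 1).
#' @slot threshold minimum scale-normalized filter response (a.u., >= 0).
#'   Deliberately permissive by default: the downstream validation filters are
#'   designed to remove spurious detections, so it is better to over-detect
#'   dim nuclei at late timepoints than to miss them.
#' @slot channel channel the parameters apply to.
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(sigmaMin = "numeric", sigmaMax = "numeric", nScales = "integer",
                 threshold = "numeric", channel = "character"))

setValidity("DetectionParams", function(object) {
  if (!(object@sigmaMin > 0 && object@sigmaMin < object@sigmaMax))
    return("need 0 < sigmaMin < sigmaMax")
  if (object@nScales < 1L) return("nScales must be >= 1")
  if (object@threshold < 0) return("threshold must be >= 0")
  if (!object@channel %in% .CHANNELS) return("unknown channel")
  TRUE
})

#' @rdname DetectionParams-class
#' @param sigmaMin,sigmaMax,nScales,threshold,channel see slots.
#' @export
detectionParams <- function(sigmaMin = 2.5, sigmaMax = 8, nScales = 5L,
                            threshold = 2, channel = "green") {
  new("DetectionParams", sigmaMin = as.numeric(sigmaMin),
      sigmaMax = as.numeric(sigmaMax), nScales = as.integer(nScales),
      threshold = as.numeric(threshold), channel = channel)
}

#' ValidationParams: first/second validation settings
#'
#' @slot radiusFactor multiplier applied to the estimated embryo extent to get
#'   the keep radius around the green centre of mass. The extent estimator
#'   (median of per-spot maximal inter-spot distances) approximates a
#'   diameter only when roughly antipodal spots exist: a 4-cell tetrahedron
#'   has its blastomeres at 0.61 x extent from the centre, and in dense
#'   shell-like clouds the outermost genuine nuclei reach ~0.73 x extent.
#'   The default 0.78 keeps genuine boundary nuclei - and keeps the iterated
#'   filter at a fixed point on clean data - while still rejecting
#'   background well outside the cloud. Fully user-tunable, exactly the
#'   compensation knob the method prescribes.
#' @slot mergeDistance um: spots of one channel closer than this are treated
#'   as double detections of one nucleus and merged.
#' @slot colocDistance um: a red spot must have a green spot within this
#'   distance (photoconversion always retains a residual green population).
#' @slot recoveryRadius um: search radius into the previous frame's valid red
#'   spots when recovering discarded red spots.
#' @slot recoveryEnabled logical.
#' @exportClass ValidationParams
setClass("ValidationParams",
  representation(radiusFactor = "numeric", mergeDistance = "numeric",
                 colocDistance = "numeric", recoveryRadius = "numeric",
                 recoveryEnabled = "logical"))

setValidity("ValidationParams", function(object) {
  if (object@radiusFactor <= 0) return("radiusFactor must be > 0")
  if (object@mergeDistance <= 0 || object@colocDistance <= 0 ||
      object@recoveryRadius <= 0)
    return("all distances must be > 0")
  TRUE
})

#' @rdname ValidationParams-class
#' @param radiusFactor,mergeDistance,colocDistance,recoveryRadius,recoveryEnabled
#'   see slots.
#' @export
validationParams <- function(radiusFactor = 0.78, mergeDistance = 4,
                             colocDistance = 4, recoveryRadius = 6,
                             recoveryEnabled = TRUE) {
  new("ValidationParams", radiusFactor = as.numeric(radiusFactor),
      mergeDistance = as.numeric(mergeDistance),
      colocDistance = as.numeric(colocDistance),
      recoveryRadius = as.numeric(recoveryRadius),
      recoveryEnabled = isTRUE(recoveryEnabled))
}

#' LinkingParams: frame-to-frame tracking settings
#'
#' @slot maxLinkDistance um: maximum displacement for a one-to-one link.
#' @slot divisionDistance um: maximum mother-daughter distance when attaching
#'   a second daughter.
#' @slot allowGap logical: close single-frame gaps with a flagged synthetic
#'   midpoint node (off by default).
#' @exportClass LinkingParams
setClass("LinkingParams",
  representation(maxLinkDistance = "numeric", divisionDistance = "numeric",
                 allowGap = "logical"))

setValidity("LinkingParams", function(object) {
  if (object@maxLinkDistance <= 0 || object@divisionDistance <= 0)
    return("distances must be > 0")
  TRUE
})

#' @rdname LinkingParams-class
#' @param maxLinkDistance,divisionDistance,allowGap see slots.
#' @export
linkingParams <- function(maxLinkDistance = 15, divisionDistance = 15,
                          allowGap = FALSE) {
  new("LinkingParams", maxLinkDistance = as.numeric(maxLinkDistance),
      divisionDistance = as.numeric(divisionDistance), allowGap = isTRUE(allowGap))
}
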