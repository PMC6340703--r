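#' @importFrom stats rnorm rpois runif median setNames
#' @importFrom utils read.csv write.csv head tail
NULL

.CHANNELS <- c("green", "red")

.SPOT_COLUMNS <- c("id", "frame", "channel", "x", "y", "z", "radius", "intensity")

emptySpotFrame <- function() {
  data.frame(id = integer(), frame = integer(), channel = character(),
             x = numeric(), y = numeric(), z = numeric(),
             radius = numeric(), intensity = numeric(),
             stringsAsFactors = FALSE)
}

spotCoords <- function(spots) {
  m <- as.matrix(spots[, c("x", "y", "z"), drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

## pairwise Euclidean distances between rows of a (n x 3) and b (m x 3)
crossDist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(numeric(0), nrow = nrow(a), ncol = nrow(b)))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

unitVector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

## Rodrigues rotation matrix: rotate by `deg` degrees about unit `axis`
rotationAboutAxis <- function(axis, deg) {
  u <- unitVector(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotationAboutX <- function(deg) {
  th <- deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  matrix(c(1, 0, 0,
           0, c_, s_,
           0, -s_, c_), 3, 3)
}

isRotationMatrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

## simple disjoint-set for connected components over a pairwise relation
connectedComponents <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
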