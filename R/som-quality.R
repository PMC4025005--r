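#' Best matching unit(s)
#'
#' Finds the codebook unit nearest to each case (Euclidean distance on
#' the normalized scale) and the runner-up. Ties are broken toward the
#' lowest unit index (units are numbered row-major from the lattice
#' top-left).
#'
#' @param model a [SOMModel-class].
#' @param x a case vector (original units) or a cases x variables matrix.
#' @return for a single case, integer \code{c(best, second)}; for a
#'   matrix, an n x 2 integer matrix with columns \code{best},
#'   \code{second}.
#' @export
bmu <- function(model, x) {
  stopifnot(is(model, "SOMModel"))
  single <- is.null(dim(x))
  if (single) x <- matrix(x, nrow = 1L)
  z <- .normalizeWith(model, x)
  d2 <- .caseUnitDist2(z, model@codebook)
  best <- max.col(-d2, ties.method = "first")
  d2[cbind(seq_len(nrow(d2)), best)] <- Inf
  second <- max.col(-d2, ties.method = "first")
  if (single) c(best = best[1L], second = second[1L])
  else cbind(best = best, second = second)
}

#' Quantization error
#'
#' Mean Euclidean distance (normalized scale) between each case and its
#' best matching unit: the map-resolution measure used for map-size
#' selection.
#'
#' @param model a [SOMModel-class].
#' @param data cases x variables matrix or data.frame, original units.
#' @return nonnegative scalar QE.
#' @export
quantizationError <- function(model, data) {
  stopifnot(is(model, "SOMModel"))
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("empty data")
  z <- .normalizeWith(model, data)
  d2 <- .caseUnitDist2(z, model@codebook)
  best <- max.col(-d2, ties.method = "first")
  # recompute the winning distance directly: the expanded |x|^2 + |m|^2
  # - 2xm form used for the argmin cancels catastrophically near zero
  mean(sqrt(rowSums((z - model@codebook[best, , drop = FALSE])^2)))
}

# adjacency on the lattice: units at (unit) distance 1
.latticeAdjacency <- function(model) {
  L <- .latticeDist(model@unitXY)
  L > 0 & L <= 1 + 1e-9
}

#' Topographic error
#'
#' Proportion of cases whose first and second best matching units are not
#' adjacent on the lattice: the topology-preservation measure used for
#' map-size selection. A two-unit map always scores 0.
#'
#' @param model a [SOMModel-class].
#' @param data cases x variables matrix or data.frame, original units.
#' @return TE in \eqn{[0, 1]}.
#' @export
topographicError <- function(model, data) {
  stopifnot(is(model, "SOMModel"))
  data <- as.matrix(data)
  if (nrow(data) < 1L) stop("empty data")
  b <- bmu(model, data)
  adj <- .latticeAdjacency(model)
  mean(!adj[cbind(b[, "best"], b[, "second"])])
}

#' U-matrix of a trained SOM
#'
#' For every pair of lattice-adjacent units, the Euclidean distance
#' between their codebook vectors; each unit's summary value is the mean
#' of its incident edge distances. Large values mark cluster boundaries
#' on the map.
#'
#' @param model a [SOMModel-class].
#' @return list with \code{edges} (data.frame \code{from}, \code{to},
#'   \code{distance}) and \code{unit} (an nRows x nCols matrix of per-unit
#'   mean edge distances).
#' @export
uMatrix <- function(model) {
  stopifnot(is(model, "SOMModel"))
  adj <- .latticeAdjacency(model)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  d <- sqrt(rowSums((model@codebook[idx[, 1L], , drop = FALSE] -
                     model@codebook[idx[, 2L], , drop = FALSE])^2))
  nu <- nrow(model@codebook)
  unitVal <- vapply(seq_len(nu), function(u)
    mean(d[idx[, 1L] == u | idx[, 2L] == u]), numeric(1))
  list(edges = data.frame(from = idx[, 1L], to = idx[, 2L], distance = d),
       unit = matrix(unitVal, model@nRows, model@nCols, byrow = TRUE))
}

#' Component planes
#'
#' One lattice-shaped matrix per input variable containing the
#' denormalized codebook values: the per-variable view of the trained
#' map.
#'
#' @param model a [SOMModel-class].
#' @return named list of nRows x nCols matrices, one per variable.
#' @export
componentPlanes <- function(model) {
  stopifnot(is(model, "SOMModel"))
  M <- codebookDenormalized(model)
  planes <- lapply(seq_len(ncol(M)), function(j)
    matrix(M[, j], model@nRows, model@nCols, byrow = TRUE))
  stats::setNames(planes, model@varNames)
}

#' Candidate map sizes for the size scan
#'
#' The nine lattice sizes conventionally scanned for surveys of a few
#' hundred units, from 8 x 5 = 40 to 18 x 11 = 198 map units.
#'
#' @return a two-column matrix (nRows, nCols).
#' @export
defaultMapSizes <- function() {
  cbind(nRows = c(8L, 9L, 10L, 12L, 12L, 13L, 14L, 16L, 18L),
        nCols = c(5L, 6L, 7L, 7L, 8L, 9L, 10L, 11L, 11L))
}

#' Scan candidate map sizes by quantization and topographic error
#'
#' Trains one SOM per candidate size under a shared seed and identical
#' settings, records QE and TE for each, and selects the size with the
#' smallest QE, breaking ties by the smaller TE.
#'
#' @param data cases x variables matrix or data.frame.
#' @param sizes two-column matrix of candidate (nRows, nCols); defaults
#'   to [defaultMapSizes()].
#' @param ... passed to [trainSOM()] (lattice, init, epochs, ...).
#' @param seed shared seed for all candidates.
#' @return list with \code{scan} (data.frame \code{nRows}, \code{nCols},
#'   \code{units}, \code{qe}, \code{te}), \code{selected} (row index into
#'   the scan), and \code{model} (the trained SOM of the selected size).
#' @export
mapSizeScan <- function(data, sizes = defaultMapSizes(), ...,
                        seed = NULL) {
  sizes <- matrix(as.integer(sizes), ncol = 2L,
                  dimnames = list(NULL, c("nRows", "nCols")))
  if (nrow(sizes) < 1L) stop("at least one candidate size is required")
  bad <- sizes[, 1L] * sizes[, 2L] < 2L
  if (any(bad))
    stop(sprintf("candidate size(s) with fewer than 2 units rejected: %s",
                 paste(sprintf("%dx%d", sizes[bad, 1L], sizes[bad, 2L]),
                       collapse = ", ")))
  models <- vector("list", nrow(sizes))
  qe <- te <- numeric(nrow(sizes))
  for (i in seq_len(nrow(sizes))) {
    m <- trainSOM(data, sizes[i, 1L], sizes[i, 2L], ..., seed = seed)
    models[[i]] <- m
    qe[i] <- quantizationError(m, data)
    te[i] <- topographicError(m, data)
  }
  scan <- data.frame(nRows = sizes[, 1L], nCols = sizes[, 2L],
                     units = sizes[, 1L] * sizes[, 2L], qe = qe, te = te)
  sel <- order(qe, te)[1L]
  list(scan = scan, selected = sel, model = models[[sel]])
}
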