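#' Construct a GridField
#'
#' @param xOrigin,yOrigin south-west corner of the grid.
#' @param cellSize cell edge length.
#' @param nRows,nCols grid dimensions.
#' @param values optional row-major value vector (row 1 southernmost);
#'   defaults to \code{NA}.
#' @return a [GridField-class].
#' @export
GridField <- function(xOrigin, yOrigin, cellSize, nRows, nCols,
                      values = rep(NA_real_, nRows * nCols)) {
  new("GridField", xOrigin = xOrigin, yOrigin = yOrigin,
      cellSize = cellSize, nRows = as.integer(nRows),
      nCols = as.integer(nCols), values = as.numeric(values))
}

#' @rdname GridField-class
#' @export
setMethod("gridValues", "GridField", function(object) object@values)

setMethod("show", "GridField", function(object) {
  cat(sprintf("GridField %d x %d, cell %.4g, origin (%.4f, %.4f)\n",
              object@nRows, object@nCols, object@cellSize,
              object@xOrigin, object@yOrigin))
  v <- object@values[is.finite(object@values)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], %d of %d cells set\n",
                min(v), max(v), length(v), length(object@values)))
})

#' Grid-cell center coordinates
#'
#' @param grid a [GridField-class].
#' @return data.frame with \code{x}, \code{y} for every cell, in storage
#'   (row-major, southernmost row first) order.
#' @export
gridCenters <- function(grid) {
  stopifnot(is(grid, "GridField"))
  cx <- grid@xOrigin + (seq_len(grid@nCols) - 0.5) * grid@cellSize
  cy <- grid@yOrigin + (seq_len(grid@nRows) - 0.5) * grid@cellSize
  data.frame(x = rep(cx, times = grid@nRows),
             y = rep(cy, each = grid@nCols))
}

#' Export a grid as (x, y, value) CSV
#'
#' @param grid a [GridField-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGridCSV <- function(grid, path) {
  df <- gridCenters(grid)
  df$value <- gridValues(grid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# average values at exactly coincident coordinates; warns when collapsing
.dedupPoints <- function(x, y, values) {
  key <- paste(x, y, sep = "\r")
  if (!anyDuplicated(key))
    return(list(x = x, y = y,
                values = if (is.matrix(values)) values else
                  matrix(values, ncol = 1L)))
  warning("duplicate sample coordinates averaged before kriging")
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  ukey <- unique(key)
  idx <- match(key, ukey)
  vOut <- apply(values, 2L, function(col)
    as.vector(tapply(col, idx, mean)))
  first <- match(ukey, key)
  list(x = x[first], y = y[first],
       values = matrix(vOut, ncol = ncol(values)))
}

# ordinary kriging system: factorize once, predict for many targets.
# Returns a function mapping prediction coords to an (n+1) x m weight
# matrix (kriging weights rows 1..n, Lagrange multiplier last).
.okSolver <- function(x, y, model) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  G <- matrix(variogramValue(model, D), n, n)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  qrA <- qr(A, LAPACK = TRUE)
  function(px, py) {
    d0 <- sqrt(outer(x, px, "-")^2 + outer(y, py, "-")^2)
    B <- rbind(matrix(variogramValue(model, d0), n, length(px)), 1)
    qr.coef(qrA, B)
  }
}

#' Ordinary kriging weights at prediction points
#'
#' Solves the ordinary kriging system (semivariogram form with the
#' unbiasedness constraint, so weights sum to 1) for explicit prediction
#' locations. Mainly useful for diagnostics and testing; use
#' [krigeGrid()] for surfaces.
#'
#' @param x,y sample coordinates.
#' @param model a [VariogramModel-class].
#' @param px,py prediction coordinates.
#' @return an \code{m x n} matrix of weights (one row per prediction
#'   point).
#' @export
krigingWeights <- function(x, y, model, px, py) {
  dd <- .dedupPoints(x, y, rep(0, length(x)))
  solver <- .okSolver(dd$x, dd$y, model)
  W <- solver(px, py)
  t(W[seq_along(dd$x), , drop = FALSE])
}

#' Krige point observations onto a regular grid
#'
#' Ordinary kriging of one or more fields observed at common point
#' locations. Exactly coincident points are averaged first (with a
#' warning). With a zero nugget the prediction at a sample location
#' reproduces the observation. All fields share the sample geometry, so
#' the kriging system is factorized once per variogram model; pass a
#' matrix of \code{values} with one column per field to interpolate many
#' fields at once with a common model.
#'
#' @param x,y sample coordinates (WGS84 degrees, treated as planar).
#' @param values numeric vector, or matrix with one column per field.
#' @param model a [VariogramModel-class].
#' @param grid a [GridField-class] defining the target geometry, or
#'   \code{NULL} to build one from the sample bounding box.
#' @param cellSize cell size used when \code{grid} is \code{NULL}
#'   (default 0.01 degrees).
#' @param chunk number of grid nodes solved per block (memory control).
#' @return a [GridField-class], or a list of them for matrix input.
#' @export
krigeGrid <- function(x, y, values, model, grid = NULL, cellSize = 0.01,
                      chunk = 4096L) {
  stopifnot(is(model, "VariogramModel"))
  dd <- .dedupPoints(x, y, values)
  if (length(dd$x) < 2L) stop("need at least 2 non-coincident points")
  if (is.null(grid)) {
    pad <- cellSize / 2
    x0 <- min(x) - pad; y0 <- min(y) - pad
    nc <- max(1L, ceiling((max(x) + pad - x0) / cellSize))
    nr <- max(1L, ceiling((max(y) + pad - y0) / cellSize))
    grid <- GridField(x0, y0, cellSize, nr, nc)
  }
  ctr <- gridCenters(grid)
  solver <- .okSolver(dd$x, dd$y, model)
  nF <- ncol(dd$values)
  out <- matrix(NA_real_, nrow(ctr), nF)
  n <- length(dd$x)
  starts <- seq(1L, nrow(ctr), by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, nrow(ctr))
    W <- solver(ctr$x[s:e], ctr$y[s:e])[seq_len(n), , drop = FALSE]
    out[s:e, ] <- crossprod(W, dd$values)
  }
  fields <- lapply(seq_len(nF), function(j)
    GridField(grid@xOrigin, grid@yOrigin, grid@cellSize, grid@nRows,
              grid@nCols, out[, j]))
  if (is.matrix(values)) {
    names(fields) <- colnames(values)
    fields
  } else fields[[1L]]
}

#' Zonal mean of a grid over unit polygons
#'
#' Averages grid values whose cell centers fall inside each unit polygon
#' (cell-center rule, no partial-area weighting). Units covering no cell
#' center get \code{NA}; the cell count per unit is attached as the
#' \code{"ncells"} attribute, so a tessellation's cell-count-weighted mean
#' of unit means reproduces the overall grid mean exactly.
#'
#' @param grid a [GridField-class].
#' @param units a [UnitPolygonSet-class] in the same coordinate system.
#' @return named numeric vector of unit means with attribute
#'   \code{ncells}.
#' @export
zonalMean <- function(grid, units) {
  stopifnot(is(grid, "GridField"), is(units, "UnitPolygonSet"))
  ctr <- gridCenters(grid)
  v <- gridValues(grid)
  means <- stats::setNames(rep(NA_real_, length(units@unitId)),
                           units@unitId)
  ncells <- stats::setNames(integer(length(units@unitId)), units@unitId)
  for (i in seq_along(units@unitId)) {
    bb <- .unitBBox(units@geometry[[i]])
    cand <- which(ctr$x >= bb["xmin"] & ctr$x <= bb["xmax"] &
                  ctr$y >= bb["ymin"] & ctr$y <= bb["ymax"])
    if (!length(cand)) next
    inside <- cand[.pointsInUnit(ctr$x[cand], ctr$y[cand],
                                 units@geometry[[i]])]
    vals <- v[inside]
    vals <- vals[is.finite(vals)]
    ncells[i] <- length(vals)
    if (length(vals)) means[i] <- mean(vals)
  }
  attr(means, "ncells") <- ncells
  means
}
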