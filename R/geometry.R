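# Planar geometry helpers for unit polygons. Coordinates are WGS84
# lon/lat treated as planar (documented limitation; study areas are
# assumed small enough that degree-space areas rank correctly).

.ringArea <- function(ring) {
  # shoelace; ring is a closed or open n x 2 matrix
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  if (n < 3L) return(0)
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

.unitArea <- function(geom) {
  # geom: list of parts, each a list of rings (outer first, holes after)
  tot <- 0
  for (part in geom) {
    tot <- tot + .ringArea(part[[1L]])
    if (length(part) > 1L)
      for (h in part[-1L]) tot <- tot - .ringArea(h)
  }
  tot
}

.pointsInUnit <- function(px, py, geom) {
  # logical vector: is each point inside the unit (any part, outside holes)
  inside <- rep(FALSE, length(px))
  for (part in geom) {
    ring <- part[[1L]]
    inPart <- pracma::inpolygon(px, py, ring[, 1L], ring[, 2L],
                                boundary = TRUE)
    if (length(part) > 1L) {
      for (h in part[-1L]) {
        inHole <- pracma::inpolygon(px, py, h[, 1L], h[, 2L],
                                    boundary = FALSE)
        inPart <- inPart & !inHole
      }
    }
    inside <- inside | inPart
  }
  inside
}

.unitBBox <- function(geom) {
  xs <- unlist(lapply(geom, function(part) part[[1L]][, 1L]))
  ys <- unlist(lapply(geom, function(part) part[[1L]][, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Construct a UnitPolygonSet
#'
#' @param unitId character vector of unique unit identifiers.
#' @param geometry list of per-unit geometries: each a list of parts, each
#'   part a list of closed n x 2 rings (outer ring first).
#' @param unitData optional data.frame of attributes, one row per unit.
#' @return a validated [UnitPolygonSet-class].
#' @export
UnitPolygonSet <- function(unitId, geometry,
                           unitData = data.frame()) {
  new("UnitPolygonSet", unitId = as.character(unitId), geometry = geometry,
      unitData = unitData)
}

#' @rdname UnitPolygonSet-class
#' @export
setMethod("unitIds", "UnitPolygonSet", function(object) object@unitId)

setMethod("show", "UnitPolygonSet", function(object) {
  bb <- do.call(rbind, lapply(object@geometry, .unitBBox))
  cat("UnitPolygonSet with", length(object@unitId), "units\n")
  cat(sprintf("  bbox: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              min(bb[, "xmin"]), max(bb[, "xmax"]),
              min(bb[, "ymin"]), max(bb[, "ymax"])))
})

#' Areas of unit polygons
#'
#' Planar (degree-space) polygon areas via the shoelace formula, holes
#' subtracted.
#'
#' @param units a [UnitPolygonSet-class].
#' @return named numeric vector of areas (square degrees).
#' @export
unitAreas <- function(units) {
  stopifnot(is(units, "UnitPolygonSet"))
  stats::setNames(vapply(units@geometry, .unitArea, numeric(1)),
                  units@unitId)
}
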