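# GeoJSON (RFC 7946) I/O for unit polygons. Only Polygon and MultiPolygon
# features are supported; coordinates are WGS84 lon-lat.

.closeRing <- function(m) {
  if (!all(m[1L, ] == m[nrow(m), ])) m <- rbind(m, m[1L, ])
  m
}

.coordsToRing <- function(cc) {
  # cc: list of [lon, lat] pairs (jsonlite simplifies to matrix or list)
  if (is.matrix(cc)) return(.closeRing(cc[, 1:2, drop = FALSE]))
  .closeRing(do.call(rbind, lapply(cc, function(p) as.numeric(p[1:2]))))
}

#' Read administrative-unit polygons from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection of Polygon/MultiPolygon features.
#' The unit identifier is taken from the property named by \code{idField};
#' all other properties become columns of the attribute table.
#'
#' @param path GeoJSON file path.
#' @param idField property holding the unit id (default "unit_id").
#' @return a [UnitPolygonSet-class].
#' @export
readUnitsGeoJSON <- function(path, idField = "unit_id") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  feats <- gj$features
  ids <- character(length(feats))
  geoms <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (is.null(f$properties[[idField]]))
      stop(sprintf("feature %d lacks property '%s'", i, idField))
    ids[i] <- as.character(f$properties[[idField]])
    props[[i]] <- f$properties[names(f$properties) != idField]
    g <- f$geometry
    geoms[[i]] <- switch(g$type,
      Polygon = list(lapply(g$coordinates, .coordsToRing)),
      MultiPolygon = lapply(g$coordinates,
                            function(part) lapply(part, .coordsToRing)),
      stop(sprintf("unsupported geometry type '%s' for unit '%s'",
                   g$type, ids[i])))
  }
  keys <- unique(unlist(lapply(props, names)))
  ud <- if (length(keys)) {
    as.data.frame(lapply(stats::setNames(keys, keys), function(k)
      unlist(lapply(props, function(p)
        if (is.null(p[[k]])) NA else p[[k]]))),
      stringsAsFactors = FALSE)
  } else data.frame()
  UnitPolygonSet(ids, geoms, ud)
}

#' Write unit polygons to GeoJSON
#'
#' @param units a [UnitPolygonSet-class].
#' @param path output path.
#' @param idField property name for the unit id.
#' @return \code{path}, invisibly.
#' @export
writeUnitsGeoJSON <- function(units, path, idField = "unit_id") {
  stopifnot(is(units, "UnitPolygonSet"))
  feats <- lapply(seq_along(units@unitId), function(i) {
    geom <- units@geometry[[i]]
    ringsOf <- function(part) lapply(part, function(r)
      lapply(seq_len(nrow(r)), function(j) as.numeric(r[j, ])))
    g <- if (length(geom) == 1L)
      list(type = "Polygon", coordinates = ringsOf(geom[[1L]]))
    else
      list(type = "MultiPolygon", coordinates = lapply(geom, ringsOf))
    pr <- stats::setNames(list(units@unitId[i]), idField)
    if (nrow(units@unitData))
      pr <- c(pr, as.list(units@unitData[i, , drop = FALSE]))
    list(type = "Feature", properties = pr, geometry = g)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
  invisible(path)
}
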