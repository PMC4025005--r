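#' @import methods
NULL

#' MetalPanel: the eight screened metals with toxicity weights and references
#'
#' A \code{MetalPanel} couples the eight heavy metals screened in regional
#' soil surveys (Cr, Ni, Zn, Hg, Cu, As, Cd, Pb) with their dimensionless
#' toxic-response factors \eqn{T_r} and the regulatory reference
#' concentrations (mg/kg) that the contamination factor divides by.
#'
#' The default toxic-response factors follow the Hakanson weighting
#' commonly used for these metals:
#' Hg 40, Cd 30, As 10, Cu 5, Pb 5, Ni 5, Cr 2, Zn 1.
#' Reference concentrations carry no universal default: they are a property
#' of the regulatory standard in force and must be supplied (the synthetic
#' scene generator provides its own, clearly synthetic, panel).
#'
#' @slot metals character vector of the eight metal symbols, fixed order.
#' @slot toxicResponse named numeric, strictly positive, one per metal.
#' @slot reference named numeric reference concentrations (mg/kg),
#'   strictly positive, one per metal.
#' @seealso [MetalPanel()], [ecologicalRisk()], [scoreSamples()]
#' @export
setClass("MetalPanel",
  representation(metals = "character",
                 toxicResponse = "numeric",
                 reference = "numeric"))

.PANEL_METALS <- c("Cr", "Ni", "Zn", "Hg", "Cu", "As", "Cd", "Pb")

.DEFAULT_TR <- c(Hg = 40, Cd = 30, As = 10, Cu = 5, Pb = 5, Ni = 5,
                 Cr = 2, Zn = 1)

setValidity("MetalPanel", function(object) {
  msg <- character()
  if (!identical(sort(object@metals), sort(.PANEL_METALS)) ||
      anyDuplicated(object@metals))
    msg <- c(msg, "panel must contain each of the 8 metals exactly once")
  for (s in c("toxicResponse", "reference")) {
    v <- slot(object, s)
    if (!setequal(names(v), object@metals))
      msg <- c(msg, sprintf("%s must be named by the panel metals", s))
    else if (any(!is.finite(v)) || any(v <= 0))
      msg <- c(msg, sprintf("%s must be strictly positive and finite", s))
  }
  if (length(msg)) msg else TRUE
})

#' VariogramModel: a fitted isotropic semivariogram
#'
#' Parameters of the spherical or exponential semivariogram used to drive
#' ordinary kriging. Distances are in the same units as the point
#' coordinates (decimal degrees for the WGS84 workflows in this package).
#' For the exponential family \code{rangeParam} is the practical range
#' (semivariance reaches 95\% of the sill).
#'
#' @slot family "spherical" or "exponential".
#' @slot nugget nonnegative nugget variance.
#' @slot partialSill nonnegative partial sill.
#' @slot rangeParam positive range parameter.
#' @seealso [fitVariogram()], [krigeGrid()]
#' @export
setClass("VariogramModel",
  representation(family = "character", nugget = "numeric",
                 partialSill = "numeric", rangeParam = "numeric"))

setValidity("VariogramModel", function(object) {
  msg <- character()
  if (!object@family %in% c("spherical", "exponential"))
    msg <- c(msg, "family must be 'spherical' or 'exponential'")
  if (object@nugget < 0) msg <- c(msg, "nugget must be >= 0")
  if (object@partialSill < 0) msg <- c(msg, "partialSill must be >= 0")
  if (object@rangeParam <= 0) msg <- c(msg, "rangeParam must be > 0")
  if (length(msg)) msg else TRUE
})

#' GridField: a regular raster of interpolated values
#'
#' Lightweight raster container used for kriged surfaces. Values are stored
#' row-major with row 1 the southernmost row; cell (r, c) has center
#' \code{(xOrigin + (c - 0.5) * cellSize, yOrigin + (r - 0.5) * cellSize)}.
#' \code{NA} marks cells outside the interpolation domain.
#'
#' @slot xOrigin,yOrigin coordinates of the grid's south-west corner.
#' @slot cellSize cell edge length (degrees).
#' @slot nRows,nCols grid dimensions.
#' @slot values numeric vector of length \code{nRows * nCols}, row-major.
#' @seealso [krigeGrid()], [zonalMean()], [gridCenters()]
#' @export
setClass("GridField",
  representation(xOrigin = "numeric", yOrigin = "numeric",
                 cellSize = "numeric", nRows = "integer", nCols = "integer",
                 values = "numeric"))

setValidity("GridField", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid must have at least one row and column")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be > 0")
  if (length(object@values) != object@nRows * object@nCols)
    msg <- c(msg, "values length must equal nRows * nCols")
  if (length(msg)) msg else TRUE
})

#' UnitPolygonSet: administrative-unit polygons
#'
#' Polygons (WGS84 lon/lat) for the administrative units ("towns") that
#' risk surfaces are aggregated to. Each unit's geometry is a list of
#' parts; each part is a list of rings (closed n x 2 coordinate matrices),
#' the first ring the outer boundary, any further rings holes.
#'
#' @slot unitId character identifiers, unique.
#' @slot geometry list of per-unit geometries (see Description).
#' @slot unitData data.frame of unit attributes, one row per unit.
#' @seealso [readUnitsGeoJSON()], [zonalMean()]
#' @export
setClass("UnitPolygonSet",
  representation(unitId = "character", geometry = "list",
                 unitData = "data.frame"))

setValidity("UnitPolygonSet", function(object) {
  msg <- character()
  n <- length(object@unitId)
  if (anyDuplicated(object@unitId)) msg <- c(msg, "unit ids must be unique")
  if (length(object@geometry) != n)
    msg <- c(msg, "one geometry per unit id required")
  if (nrow(object@unitData) && nrow(object@unitData) != n)
    msg <- c(msg, "unitData must have one row per unit")
  areas <- vapply(object@geometry, .unitArea, numeric(1))
  if (any(!is.finite(areas)) || any(areas <= 0))
    msg <- c(msg, sprintf("zero or invalid area for unit(s): %s",
                          paste(object@unitId[!is.finite(areas) | areas <= 0],
                                collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SOMModel: a trained self-organizing map
#'
#' Holds the lattice geometry, the codebook (on the normalized scale), and
#' the per-variable normalization parameters of a batch-trained SOM.
#' Units are indexed row-major from the top-left of the lattice.
#'
#' @slot nRows,nCols lattice dimensions.
#' @slot lattice "hexagonal" or "rectangular".
#' @slot codebook units x variables matrix of weight vectors (z-scored
#'   scale).
#' @slot unitXY units x 2 matrix of lattice coordinates used for
#'   neighborhood and adjacency computations.
#' @slot normCenter,normScale per-variable normalization parameters.
#' @slot constantVars logical flags for variables constant in training data
#'   (kept in the codebook as zeros; they carry no distance information).
#' @slot varNames variable names, in codebook column order.
#' @slot config list of training settings (init, epochs, radii, seed).
#' @seealso [trainSOM()], [bmu()], [quantizationError()], [uMatrix()]
#' @export
setClass("SOMModel",
  representation(nRows = "integer", nCols = "integer", lattice = "character",
                 codebook = "matrix", unitXY = "matrix",
                 normCenter = "numeric", normScale = "numeric",
                 constantVars = "logical", varNames = "character",
                 config = "list"))

setValidity("SOMModel", function(object) {
  msg <- character()
  nu <- object@nRows * object@nCols
  if (nu < 2L) msg <- c(msg, "lattice must have at least 2 units")
  if (!object@lattice %in% c("hexagonal", "rectangular"))
    msg <- c(msg, "lattice must be 'hexagonal' or 'rectangular'")
  if (nrow(object@codebook) != nu)
    msg <- c(msg, "codebook must have nRows * nCols rows")
  if (any(!is.finite(object@codebook)))
    msg <- c(msg, "codebook must be finite")
  if (length(object@varNames) != ncol(object@codebook))
    msg <- c(msg, "varNames length must match codebook columns")
  if (length(msg)) msg else TRUE
})

#' SyntheticScene: a fully synthetic survey scene with planted structure
#'
#' A self-contained stand-in for a regional heavy-metal survey: town
#' polygons tiled over a rectangular study area, town-level covariates
#' drawn from planted archetypes, point soil samples with lognormal metal
#' concentrations, and a synthetic reference panel calibrated so town RI
#' spans the range typical of an urbanizing region. The planted archetype
#' labels are the ground truth for cluster-recovery validation.
#'
#' @slot towns [UnitPolygonSet-class] of town polygons.
#' @slot covariates data.frame: unit_id plus the 19 social-ecological
#'   covariates.
#' @slot archetype named integer vector: planted archetype per town.
#' @slot samples data.frame: sample_id, town_id, lon, lat and the 8 metal
#'   concentration columns (mg/kg).
#' @slot panel [MetalPanel-class] with synthetic reference values.
#' @slot archetypes the archetype specification list used to generate the
#'   scene (see [defaultArchetypes()]).
#' @slot seed integer seed the scene was generated from.
#' @seealso [simulateScene()], [sceneToFiles()]
#' @export
setClass("SyntheticScene",
  representation(towns = "UnitPolygonSet", covariates = "data.frame",
                 archetype = "integer", samples = "data.frame",
                 panel = "MetalPanel", archetypes = "list", seed = "integer"))

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (length(object@archetype) != length(object@towns@unitId))
    msg <- c(msg, "planted labels must cover all towns")
  if (!all(c("sample_id", "town_id", "lon", "lat") %in%
           names(object@samples)))
    msg <- c(msg, "samples must have sample_id, town_id, lon, lat")
  if (length(msg)) msg else TRUE
})
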