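#' Construct a metal panel
#'
#' Builds the [MetalPanel-class] describing the eight screened heavy metals.
#' Toxic-response factors default to the standard Hakanson weighting
#' (Hg 40, Cd 30, As 10, Cu 5, Pb 5, Ni 5, Cr 2, Zn 1); reference
#' concentrations have no default and must be supplied in mg/kg, one per
#' metal, e.g. from the soil quality standard applicable to the study area.
#'
#' @param reference named numeric vector of reference concentrations
#'   (mg/kg) covering all eight metals.
#' @param toxicResponse named numeric vector of toxic-response factors;
#'   defaults to the Hakanson values.
#' @return a validated [MetalPanel-class] object.
#' @examples
#' ref <- c(Cr = 250, Ni = 60, Zn = 300, Hg = 1, Cu = 100, As = 30,
#'          Cd = 0.6, Pb = 350)
#' MetalPanel(reference = ref)
#' @export
MetalPanel <- function(reference, toxicResponse = defaultToxicResponse()) {
  if (is.null(names(reference)) || is.null(names(toxicResponse)))
    stop("reference and toxicResponse must be named by metal symbol")
  new("MetalPanel", metals = .PANEL_METALS,
      toxicResponse = toxicResponse[.PANEL_METALS],
      reference = reference[.PANEL_METALS])
}

#' Default Hakanson toxic-response factors
#'
#' @return named numeric vector of the eight factors, in panel metal order.
#' @export
defaultToxicResponse <- function() .DEFAULT_TR[.PANEL_METALS]

#' @rdname MetalPanel-class
#' @export
setMethod("metals", "MetalPanel", function(object) object@metals)

#' @rdname MetalPanel-class
#' @export
setMethod("toxicResponse", "MetalPanel",
          function(object) object@toxicResponse)

#' @rdname MetalPanel-class
#' @export
setMethod("referenceValues", "MetalPanel",
          function(object) object@reference)

setMethod("show", "MetalPanel", function(object) {
  cat("MetalPanel with", length(object@metals), "metals\n")
  df <- data.frame(metal = object@metals,
                   T_r = unname(object@toxicResponse),
                   reference = unname(object@reference))
  print(df, row.names = FALSE)
})

#' Read a metal panel from a YAML config
#'
#' Expects top-level mappings \code{toxic_response:} and \code{reference:},
#' each keyed by metal symbol. \code{toxic_response} may be omitted, in
#' which case the Hakanson defaults are used.
#'
#' @param path path to a YAML file.
#' @return a [MetalPanel-class].
#' @export
readPanel <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$reference))
    stop("panel config must provide 'reference' values")
  tr <- if (is.null(cfg$toxic_response)) defaultToxicResponse()
        else unlist(cfg$toxic_response)
  MetalPanel(reference = unlist(cfg$reference), toxicResponse = tr)
}

#' Write a metal panel to a YAML config
#'
#' @param panel a [MetalPanel-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "MetalPanel"))
  yaml::write_yaml(list(toxic_response = as.list(toxicResponse(panel)),
                        reference = as.list(referenceValues(panel))),
                   path, precision = 17L)
  invisible(path)
}
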