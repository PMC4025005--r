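#' @rdname MetalPanel-class
#' @param object a \code{MetalPanel}
#' @export
setGeneric("metals", function(object) standardGeneric("metals"))

#' @rdname MetalPanel-class
#' @export
setGeneric("toxicResponse",
           function(object) standardGeneric("toxicResponse"))

#' @rdname MetalPanel-class
#' @export
setGeneric("referenceValues",
           function(object) standardGeneric("referenceValues"))

#' @rdname SOMModel-class
#' @param object a \code{SOMModel}
#' @export
setGeneric("codebook", function(object) standardGeneric("codebook"))

#' @rdname UnitPolygonSet-class
#' @param object a \code{UnitPolygonSet}
#' @export
setGeneric("unitIds", function(object) standardGeneric("unitIds"))

#' @rdname GridField-class
#' @param object a \code{GridField}
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
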