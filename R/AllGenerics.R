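#' @title Accessor generics
#' @description Slot access for the package's S4 classes goes through these
#'   accessors; user code should never reach into slots directly.
#' @param x an object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname accessors
#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))

#' @rdname accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname accessors
#' @export
setGeneric("habitat", function(x) standardGeneric("habitat"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("taxonomyData", function(x) standardGeneric("taxonomyData"))

#' @rdname accessors
#' @export
setGeneric("communities", function(x) standardGeneric("communities"))

#' @rdname accessors
#' @export
setGeneric("taxonomies", function(x) standardGeneric("taxonomies"))

#' @rdname accessors
#' @export
setGeneric("teValues", function(x) standardGeneric("teValues"))

#' @rdname accessors
#' @export
setGeneric("mandalaPoints", function(x) standardGeneric("mandalaPoints"))

#' @rdname accessors
#' @export
setGeneric("axisMaxima", function(x) standardGeneric("axisMaxima"))
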