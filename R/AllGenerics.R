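#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return See the individual methods.
#' @name taskFC-generics
NULL

#' @rdname taskFC-generics
#' @export
setGeneric("roiTable", function(x, ...) standardGeneric("roiTable"))

#' @rdname taskFC-generics
#' @export
setGeneric("survivingRois", function(x, ...) standardGeneric("survivingRois"))

#' @rdname taskFC-generics
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))

#' @rdname taskFC-generics
#' @export
setGeneric("excludedIds", function(x) standardGeneric("excludedIds"))

#' @rdname taskFC-generics
#' @export
setGeneric("networkCounts", function(x, ...) standardGeneric("networkCounts"))

#' @rdname taskFC-generics
#' @export
setGeneric("cmValues", function(x) standardGeneric("cmValues"))

#' @rdname taskFC-generics
#' @export
setGeneric("diagonalMode", function(x) standardGeneric("diagonalMode"))

#' @rdname taskFC-generics
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname taskFC-generics
#' @export
setGeneric("domainLabel", function(x) standardGeneric("domainLabel"))

#' @rdname taskFC-generics
#' @export
setGeneric("domainSeries", function(x, domain) standardGeneric("domainSeries"))
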