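#' @name BraceMorph-generics
#' @title Generics for mesh and result accessors
#' @description Accessor generics for the package's S4 classes.
#' @param x an object.
#' @keywords internal
NULL

#' @rdname BraceMorph-generics
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname BraceMorph-generics
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname BraceMorph-generics
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname BraceMorph-generics
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname BraceMorph-generics
#' @export
setGeneric("meshMetadata", function(x) standardGeneric("meshMetadata"))

#' @rdname BraceMorph-generics
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname BraceMorph-generics
#' @export
setGeneric("peaksTable", function(x) standardGeneric("peaksTable"))

#' @rdname BraceMorph-generics
#' @export
setGeneric("asymmetryPercent", function(x) standardGeneric("asymmetryPercent"))
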