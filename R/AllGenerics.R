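#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics for the S4 classes in this package. Accessors are
#' the supported way to read object contents; slots are internal.
#'
#' @param x An object.
#' @param i An index (for [eventSamples()]).
#' @return The corresponding component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spacer", function(x) standardGeneric("spacer"))

#' @rdname accessors
#' @export
setGeneric("protospacer", function(x) standardGeneric("protospacer"))

#' @rdname accessors
#' @export
setGeneric("pam", function(x) standardGeneric("pam"))

#' @rdname accessors
#' @export
setGeneric("hasValidPam", function(x) standardGeneric("hasValidPam"))

#' @rdname accessors
#' @export
setGeneric("barcode", function(x) standardGeneric("barcode"))

#' @rdname accessors
#' @export
setGeneric("slotPositions", function(x) standardGeneric("slotPositions"))

#' @rdname accessors
#' @export
setGeneric("overhangSites", function(x) standardGeneric("overhangSites"))

#' @rdname accessors
#' @export
setGeneric("concentrationWeight", function(x) standardGeneric("concentrationWeight"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("traceCurrent", function(x) standardGeneric("traceCurrent"))

#' @rdname accessors
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("eventSamples", function(x, i) standardGeneric("eventSamples"))

#' @rdname accessors
#' @export
setGeneric("mismatchEntries", function(x) standardGeneric("mismatchEntries"))
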