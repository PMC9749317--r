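#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers. Prefer these to
#' direct slot access (`@`); slot layout is not part of the API.
#'
#' @param x An object.
#' @return The corresponding slot value; see the class documentation.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("leadSignals", function(x) standardGeneric("leadSignals"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("leadNames", function(x) standardGeneric("leadNames"))

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' @rdname accessors
#' @export
setGeneric("cropOffset", function(x) standardGeneric("cropOffset"))

#' @rdname accessors
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("recordLabel", function(x) standardGeneric("recordLabel"))

#' @rdname accessors
#' @export
setGeneric("truthSignals", function(x) standardGeneric("truthSignals"))

#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' @rdname accessors
#' @export
setGeneric("truthRows", function(x) standardGeneric("truthRows"))

#' @rdname accessors
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))

#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname accessors
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))
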