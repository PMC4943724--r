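#' @rdname GenotypeData-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("markerMAF", function(x) standardGeneric("markerMAF"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("markerCallRate", function(x) standardGeneric("markerCallRate"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("sampleCallRate", function(x) standardGeneric("sampleCallRate"))

#' @rdname TraitData-accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname TraitData-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname TraitData-accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname Grm-accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))

#' @rdname Grm-accessors
#' @export
setGeneric("excludedChrom", function(x) standardGeneric("excludedChrom"))

#' @rdname NullModelFit-accessors
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
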