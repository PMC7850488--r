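#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes. `mutations()`
#' returns the mutation table of a [MissenseSet-class]; `census()` its
#' [SubstitutionCensus-class]; `mappingTable()` the per-column table of a
#' [CrossSpeciesMap-class]; `identityFraction()` its identity fraction;
#' `unmappedPositions()` the source positions that face a gap;
#' `parameterNames()` and `parameterSigns()` describe a
#' [ParameterRegistry-class]; `weights()` and `intercept()` a
#' [WeightSet-class]; `wmmsThreshold()` the attenuated/severe WMMS cutoff
#' of an [OutcomeModel-class]; `nTotal()` the total progeny of a
#' [ColonyCounts-class].
#'
#' @param x an object of the matching class.
#' @return See each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname accessors
#' @export
setGeneric("census", function(x) standardGeneric("census"))

#' @rdname accessors
#' @export
setGeneric("mappingTable", function(x) standardGeneric("mappingTable"))

#' @rdname accessors
#' @export
setGeneric("identityFraction", function(x) standardGeneric("identityFraction"))

#' @rdname accessors
#' @export
setGeneric("unmappedPositions", function(x) standardGeneric("unmappedPositions"))

#' @rdname accessors
#' @export
setGeneric("parameterNames", function(x) standardGeneric("parameterNames"))

#' @rdname accessors
#' @export
setGeneric("parameterSigns", function(x) standardGeneric("parameterSigns"))

#' @rdname accessors
#' @param object a [WeightSet-class] (for `weights()`).
#' @param ... ignored.
#' @export
setGeneric("weights", function(object, ...) standardGeneric("weights"))

#' @rdname accessors
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @rdname accessors
#' @export
setGeneric("wmmsThreshold", function(x) standardGeneric("wmmsThreshold"))

#' @rdname accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))
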