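#' @rdname MarkerMap
#' @param x a MarkerMap or TetradSet
#' @param chromosome optional chromosome to restrict to
#' @export
setGeneric("markerNames", function(x, chromosome = NULL) standardGeneric("markerNames"))

#' @rdname MarkerMap
#' @export
setGeneric("mapIntervals", function(x, chromosome = NULL) standardGeneric("mapIntervals"))

#' @rdname MarkerMap
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname TetradSet
#' @export
setGeneric("nTetrads", function(x) standardGeneric("nTetrads"))

#' @rdname TetradSet
#' @export
setGeneric("tetradIds", function(x) standardGeneric("tetradIds"))

#' @rdname TetradSet
#' @export
setGeneric("nViable", function(x) standardGeneric("nViable"))

#' @rdname TetradSet
#' @export
setGeneric("spores", function(x) standardGeneric("spores"))

#' @rdname TetradSet
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname ViabilityProfile
#' @param x object to extract from
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname ViabilityProfile
#' @export
setGeneric("percentViable", function(x) standardGeneric("percentViable"))

#' @rdname FluctuationExperiment
#' @param x a FluctuationExperiment
#' @export
setGeneric("cultureCounts", function(x) standardGeneric("cultureCounts"))

#' @rdname FluctuationExperiment
#' @export
setGeneric("cellsAtRisk", function(x) standardGeneric("cellsAtRisk"))
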