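#' @rdname MissionGrid-class
#' @param x a \linkS4class{MissionGrid} or an object carrying one.
#' @export
setGeneric("gridDays", function(x) standardGeneric("gridDays"))

#' @rdname MissionGrid-class
#' @export
setGeneric("gridBoundaries", function(x) standardGeneric("gridBoundaries"))

#' @rdname MissionGrid-class
#' @export
setGeneric("baselineIndex", function(x) standardGeneric("baselineIndex"))

#' @rdname MissionExperiment-class
#' @param x a \linkS4class{MissionExperiment}.
#' @export
setGeneric("binnedMatrix", function(x) standardGeneric("binnedMatrix"))

#' @rdname MissionExperiment-class
#' @export
setGeneric("normalizedMatrix", function(x) standardGeneric("normalizedMatrix"))

#' @rdname MissionExperiment-class
#' @export
setGeneric("keptSeries", function(x) standardGeneric("keptSeries"))

#' @rdname MissionExperiment-class
#' @export
setGeneric("trendClasses", function(x) standardGeneric("trendClasses"))

#' @rdname SpectralNull-class
#' @param x a \linkS4class{SpectralNull}.
#' @export
setGeneric("rhoThresholds", function(x) standardGeneric("rhoThresholds"))

#' @rdname SpectralNull-class
#' @export
setGeneric("spikeThresholds", function(x) standardGeneric("spikeThresholds"))

#' @rdname CohortGraph-class
#' @param x a \linkS4class{CohortGraph} (or \linkS4class{VisibilityGraph}).
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname CohortGraph-class
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' @rdname CohortGraph-class
#' @export
setGeneric("membershipFrequencies",
           function(x) standardGeneric("membershipFrequencies"))

#' @rdname SimilarityRadius-class
#' @param x a \linkS4class{SimilarityRadius} or \linkS4class{CohortGraph}.
#' @export
setGeneric("similarityThreshold",
           function(x) standardGeneric("similarityThreshold"))
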