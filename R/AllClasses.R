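#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
#' @importFrom utils head tail
#' @importFrom stats quantile median setNames
NULL

#' Mission time grid
#'
#' The canonical 8-bin mission grid: two pre-flight bins (-180, -45 days),
#' three in-flight bins (33, 82, 132 days), return (165 days) and two
#' post-return bins (195, 225 days). Bin boundaries are half-open day
#' intervals \code{[lower, upper)} that partition the study window; the
#' default boundaries are midpoints between adjacent bin labels, extended to
#' -200 and +240 days at the ends.
#'
#' @slot labels numeric vector of bin labels in days relative to launch,
#'   strictly increasing.
#' @slot boundaries numeric vector of length \code{length(labels) + 1}
#'   delimiting the half-open bin intervals.
#' @slot baselineDay the day label of the pre-flight baseline bin used for
#'   differencing (default -45).
#'
#' @seealso [missionGrid()]
#' @export
setClass("MissionGrid",
  representation(labels = "numeric", boundaries = "numeric",
                 baselineDay = "numeric"))

setValidity("MissionGrid", function(object) {
  msg <- NULL
  if (any(diff(object@labels) <= 0))
    msg <- c(msg, "bin labels must be strictly increasing")
  if (length(object@boundaries) != length(object@labels) + 1L)
    msg <- c(msg, "need one more boundary than labels")
  if (any(diff(object@boundaries) <= 0))
    msg <- c(msg, "boundaries must be strictly increasing")
  if (length(msg) == 0L &&
      any(object@labels < head(object@boundaries, -1) |
          object@labels >= object@boundaries[-1]))
    msg <- c(msg, "each label must fall inside its bin interval")
  if (!(object@baselineDay %in% object@labels))
    msg <- c(msg, "baselineDay must be one of the bin labels")
  if (is.null(msg)) TRUE else msg
})

#' Cohort of binned biomarker series
#'
#' A \linkS4class{SummarizedExperiment} whose rows are (subject, measurement)
#' series and whose columns are the bins of a \linkS4class{MissionGrid}.
#' The \code{"binned"} assay holds per-bin means of the raw records (NA where
#' a bin has no records); preprocessing adds a \code{"normalized"} assay of
#' baseline-differenced, unit Euclidean norm series. Row metadata accumulates
#' filter flags, spectral profiles, trend classes and cluster labels as the
#' pipeline stages run.
#'
#' @seealso [binRecords()], [baselineNormalize()], [classifyCohort()]
#' @export
setClass("MissionExperiment", contains = "SummarizedExperiment")

setValidity("MissionExperiment", function(object) {
  msg <- NULL
  grid <- metadata(object)$grid
  if (is.null(grid) || !is(grid, "MissionGrid"))
    msg <- c(msg, "metadata(object)$grid must be a MissionGrid")
  else if (ncol(object) != length(grid@labels))
    msg <- c(msg, "one column per grid bin required")
  if (!("day" %in% colnames(colData(object))))
    msg <- c(msg, "colData must contain a 'day' column")
  rd <- colnames(rowData(object))
  if (!all(c("subject_id", "measurement_id") %in% rd))
    msg <- c(msg, "rowData must contain subject_id and measurement_id")
  if (is.null(msg)) TRUE else msg
})

#' Bootstrap null distribution for trend classification
#'
#' Per-lag autocorrelation thresholds and spike-extremum thresholds obtained
#' from bootstrap series resampled (with replacement) from a subject's pooled
#' normalized values. \code{rhoQ} holds the upper quantile of the null
#' autocorrelation at each lag 1..L; \code{maxQ} is the upper quantile of
#' bootstrap maxima and \code{minQ} the lower-tail quantile of bootstrap
#' minima, so that exceeding either is rare under the null. The sorted null
#' statistics (\code{nullMaxRho}, \code{nullMaxima}, \code{nullMinima}) back
#' the empirical p-values; they may be dropped (length 0) to slim the object
#' once p-values have been computed.
#'
#' @seealso [buildNull()], [classifySeries()]
#' @export
setClass("SpectralNull",
  representation(rhoQ = "numeric", maxQ = "numeric", minQ = "numeric",
                 level = "numeric", nBoot = "integer", seed = "numeric",
                 nullMaxRho = "numeric", nullMaxima = "numeric",
                 nullMinima = "numeric"))

setValidity("SpectralNull", function(object) {
  msg <- NULL
  if (length(object@rhoQ) < 1L || any(!is.finite(object@rhoQ)))
    msg <- c(msg, "rhoQ must hold one finite threshold per lag")
  if (length(object@maxQ) != 1L || length(object@minQ) != 1L)
    msg <- c(msg, "maxQ and minQ must be scalars")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must be in (0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' Natural visibility graph of a mission series
#'
#' Vertices are the present timepoints of a series in time order; two
#' vertices are joined when the straight line between their (time, intensity)
#' points passes strictly above every intermediate point. Adjacent timepoints
#' are always joined, so the graph is connected. \code{vertices} holds the
#' 0-based indices of the present bins on the original grid, matching the
#' clockwise vertex labelling used when the graph is drawn.
#'
#' @seealso [naturalVisibilityGraph()], [visibilityCommunities()]
#' @export
setClass("VisibilityGraph",
  representation(adjacency = "matrix", times = "numeric", values = "numeric",
                 vertices = "integer"))

setValidity("VisibilityGraph", function(object) {
  msg <- NULL
  n <- length(object@times)
  a <- object@adjacency
  if (!is.logical(a) || nrow(a) != n || ncol(a) != n)
    msg <- c(msg, "adjacency must be a logical n x n matrix")
  else {
    if (any(diag(a))) msg <- c(msg, "no self-loops allowed")
    if (!identical(a, t(a))) msg <- c(msg, "adjacency must be symmetric")
    if (n > 1L && !all(a[cbind(1:(n - 1L), 2:n)]))
      msg <- c(msg, "adjacent timepoints must be connected")
  }
  if (length(object@values) != n || length(object@vertices) != n)
    msg <- c(msg, "times, values and vertices must have equal length")
  if (is.null(msg)) TRUE else msg
})

#' Null radius for periodogram similarity
#'
#' The distance threshold \code{dq} below which two subjects' periodograms of
#' the same measurement are called temporally similar: the stated quantile
#' (default 0.99) of distances between periodograms of bootstrap series.
#'
#' @seealso [similarityRadius()], [restrictedAdjacency()]
#' @export
setClass("SimilarityRadius",
  representation(dq = "numeric", level = "numeric", nSignals = "integer",
                 seed = "numeric"))

setValidity("SimilarityRadius", function(object) {
  if (length(object@dq) != 1L || !is.finite(object@dq) || object@dq < 0)
    "dq must be a single nonnegative number"
  else TRUE
})

#' Cross-subject similarity network
#'
#' Weighted graph over subjects where the integer edge weight counts the
#' measurements for which the two subjects' periodograms lie strictly within
#' the similarity radius. \code{restricted} keeps the per-measurement binary
#' matrices so community reports can attribute edges to measurements.
#' Consensus community detection fills \code{communities} (final label per
#' subject), \code{frequencies} (membership frequency per subject and label
#' over the consensus runs) and the run parameters.
#'
#' @seealso [restrictedAdjacency()], [consensusCommunities()]
#' @export
setClass("CohortGraph",
  representation(adjacency = "matrix", subjects = "character", dq = "numeric",
                 restricted = "list", communities = "integer",
                 frequencies = "matrix", k = "integer", dim = "integer",
                 nRuns = "integer"))

setValidity("CohortGraph", function(object) {
  msg <- NULL
  a <- object@adjacency
  n <- length(object@subjects)
  if (nrow(a) != n || ncol(a) != n)
    msg <- c(msg, "adjacency dimension must match the subject roster")
  else {
    if (!isTRUE(all.equal(a, t(a)))) msg <- c(msg, "adjacency must be symmetric")
    if (any(a < 0) || any(a != round(a)))
      msg <- c(msg, "edge weights must be nonnegative integers")
    if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
  }
  if (length(object@communities) &&
      length(object@communities) != n)
    msg <- c(msg, "one community label per subject required")
  if (is.null(msg)) TRUE else msg
})
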