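#' Construct the mission time grid
#'
#' Builds the canonical 8-bin mission grid used to collapse raw, unevenly
#' sampled records onto comparable timepoints: pre-flight bins at -180 and
#' -45 days, in-flight bins at 33, 82 and 132 days, return at 165 days, and
#' post-return bins at 195 and 225 days. Bin boundaries default to midpoints
#' between adjacent labels, extended to \code{window} at the ends, so the
#' bins partition the study window into half-open intervals
#' \code{[lower, upper)}.
#'
#' @param labels bin labels in days relative to launch (strictly increasing).
#' @param boundaries optional explicit boundaries (one more than labels).
#' @param baselineDay label of the pre-flight baseline bin (default -45).
#' @param window two-element vector giving the outer study window, used only
#'   when \code{boundaries} is NULL.
#' @return a \linkS4class{MissionGrid}.
#' @examples
#' g <- missionGrid()
#' gridDays(g)
#' @export
missionGrid <- function(labels = c(-180, -45, 33, 82, 132, 165, 195, 225),
                        boundaries = NULL, baselineDay = -45,
                        window = c(-200, 240)) {
  if (is.null(boundaries)) {
    mids <- (head(labels, -1) + labels[-1]) / 2
    boundaries <- c(window[1], mids, window[2])
  }
  new("MissionGrid", labels = as.numeric(labels),
      boundaries = as.numeric(boundaries),
      baselineDay = as.numeric(baselineDay))
}

#' @rdname MissionGrid-class
#' @export
setMethod("gridDays", "MissionGrid", function(x) x@labels)

#' @rdname MissionGrid-class
#' @export
setMethod("gridBoundaries", "MissionGrid", function(x) x@boundaries)

#' @rdname MissionGrid-class
#' @export
setMethod("baselineIndex", "MissionGrid",
          function(x) match(x@baselineDay, x@labels))

setMethod("show", "MissionGrid", function(object) {
  cat("MissionGrid with", length(object@labels), "bins:",
      paste(object@labels, collapse = ", "), "days\n")
  cat("  baseline bin:", object@baselineDay, "days\n")
  cat("  window: [", object@boundaries[1], ",",
      tail(object@boundaries, 1), ") days\n")
})

#' @rdname MissionExperiment-class
#' @export
setMethod("gridDays", "MissionExperiment",
          function(x) gridDays(metadata(x)$grid))

#' @rdname MissionExperiment-class
#' @export
setMethod("baselineIndex", "MissionExperiment",
          function(x) baselineIndex(metadata(x)$grid))

#' @rdname MissionExperiment-class
#' @export
setMethod("binnedMatrix", "MissionExperiment",
          function(x) assay(x, "binned"))

#' @rdname MissionExperiment-class
#' @export
setMethod("normalizedMatrix", "MissionExperiment", function(x) {
  if (!"normalized" %in% assayNames(x))
    stop("no 'normalized' assay; run baselineNormalize() first")
  assay(x, "normalized")
})

#' @rdname MissionExperiment-class
#' @export
setMethod("keptSeries", "MissionExperiment", function(x) {
  if (!"kept" %in% colnames(rowData(x)))
    stop("no filter flags; run filterSeries() first")
  x[rowData(x)$kept, ]
})

#' @rdname MissionExperiment-class
#' @export
setMethod("trendClasses", "MissionExperiment", function(x) {
  rd <- rowData(x)
  if (!"trendClass" %in% colnames(rd))
    stop("no trend classes; run classifyCohort() first")
  as.data.frame(rd[, c("subject_id", "measurement_id", "trendClass",
                       "lagM", "empiricalP", "significant",
                       "bhSignificant")])
})
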