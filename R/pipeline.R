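#' Run the full trend-analysis pipeline
#'
#' Executes every stage end to end: synthetic-cohort generation (or a cohort
#' CSV), binning onto the mission grid, baseline normalization, spectral
#' trend classification with bootstrap nulls and the per-subject FDR gate,
#' two-level trend clustering, visibility-graph summaries, the cross-subject
#' similarity network with consensus communities, and the cohort trend
#' table. All stage outputs plus a run manifest (seed, parameters, package
#' version) are written under \code{outDir}; the run is fully deterministic
#' given \code{seed}.
#'
#' @param cohort either NULL (simulate with \code{simArgs}), a path to a
#'   cohort CSV, or a records data.frame.
#' @param outDir output directory.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param simArgs list of arguments for [simulateCohort()].
#' @param minBins filter threshold (see [filterSeries()]).
#' @param nBoot bootstrap series per subject null (default 1e5).
#' @param level bootstrap quantile level (default 0.95).
#' @param alpha FDR level (default 0.05).
#' @param nSignals bootstrap signals for the similarity radius
#'   (default 50000).
#' @param radiusLevel similarity-radius quantile (default 0.99).
#' @param kMode,k community count selection (see [consensusCommunities()]).
#' @param nRuns consensus repetitions (default 1000).
#' @return invisibly, a list with the experiment, the graph, the summary and
#'   the output paths.
#' @export
runPipeline <- function(cohort = NULL, outDir, seed = 1,
                        simArgs = list(), minBins = 5, nBoot = 1e5,
                        level = 0.95, alpha = 0.05, nSignals = 50000,
                        radiusLevel = 0.99, kMode = "auto", k = 5,
                        nRuns = 1000) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  truth <- NULL
  records <- step("cohort", {
    if (is.null(cohort)) {
      sim <- do.call(simulateCohort,
                     c(simArgs, list(seed = childSeed(seed, 1L))))
      truth <- sim$truth
      writeCohort(sim$records, file.path(outDir, "cohort.csv"))
      writeGroundTruth(truth, file.path(outDir, "ground_truth.json"))
      sim$records
    } else if (is.character(cohort)) readCohort(cohort)
    else cohort
  })
  me <- step("preprocess", preprocessCohort(records, minBins = minBins))
  step("preprocess", writePreprocessed(me, outDir))
  me <- step("classify", classifyCohort(me, nBoot = nBoot, level = level,
                                        alpha = alpha,
                                        seed = childSeed(seed, 2L)))
  step("classify", {
    cls <- trendClasses(me)
    cls <- cls[order(cls$subject_id, cls$measurement_id), ]
    utils::write.table(cls, file.path(outDir, "classification.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  })
  me <- step("cluster", clusterTrends(me))
  step("cluster", writeClusters(me, file.path(outDir, "clusters.tsv")))
  step("visibility",
       writeVisibilityJSON(visibilitySummary(me),
                           file.path(outDir, "visibility.json")))
  cg <- step("network", {
    D <- periodogramDistances(me)
    Q <- normalizedMatrix(me)
    radius <- similarityRadius(Q[is.finite(Q)], seq_len(ncol(me)) - 1,
                               nSignals = nSignals, level = radiusLevel,
                               seed = childSeed(seed, 3L))
    cg <- restrictedAdjacency(D, radius)
    consensusCommunities(cg, kMode = kMode, k = k, nRuns = nRuns,
                         seed = childSeed(seed, 4L))
  })
  step("network", writeCohortGraph(cg, outDir))
  summary <- step("summarize", summarizeTrends(me))
  step("summarize",
       writeTrendSummary(summary, file.path(outDir, "trend_summary.tsv")))
  manifest <- list(
    seed = seed,
    package = as.character(utils::packageVersion("missionTrends")),
    parameters = list(minBins = minBins, nBoot = nBoot, level = level,
                      alpha = alpha, nSignals = nSignals,
                      radiusLevel = radiusLevel, kMode = kMode, k = cg@k,
                      nRuns = nRuns),
    nSubjects = length(unique(rowData(me)$subject_id)),
    nSeries = nrow(me))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(experiment = me, graph = cg, summary = summary,
                 truth = truth, outDir = outDir))
}
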