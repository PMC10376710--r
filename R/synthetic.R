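.archetypeNames <- c("flight_rise_persist", "flight_rise_revert",
                     "landing_spike", "landing_dip", "flat")

# default affected bins (day labels) per archetype on the canonical grid
.archetypeBins <- function(name, grid) {
  days <- gridDays(grid)
  switch(name,
    flight_rise_persist = days[days >= 33],
    flight_rise_revert  = days[days >= 33 & days <= 132],
    landing_spike       = 165,
    landing_dip         = 165,
    flat                = numeric(0),
    .stopf("unknown archetype '%s'", name))
}

#' Trend archetype template on the mission grid
#'
#' Returns the noiseless binned signal of a named trend archetype:
#' \describe{
#'   \item{flight_rise_persist}{zero pre-flight, elevated by
#'     \code{amplitude} from early flight through two months post-return.}
#'   \item{flight_rise_revert}{elevated only during flight (33/82/132 d
#'     bins), back to baseline at return.}
#'   \item{landing_spike}{a single positive excursion at the return bin
#'     (165 d).}
#'   \item{landing_dip}{a single negative excursion at the return bin.}
#'   \item{flat}{all zeros.}
#' }
#'
#' @param name archetype name.
#' @param amplitude excursion intensity (arbitrary units); must be finite.
#' @param affectedBins optional day labels overriding the default affected
#'   bins; must be a subset of the grid labels.
#' @param grid a \linkS4class{MissionGrid}.
#' @return named numeric vector over the grid bins.
#' @examples
#' archetypeTemplate("landing_spike", amplitude = 2)
#' @export
archetypeTemplate <- function(name, amplitude = 1, affectedBins = NULL,
                              grid = missionGrid()) {
  name <- match.arg(name, .archetypeNames)
  if (!is.finite(amplitude)) .stopf("amplitude must be finite")
  days <- gridDays(grid)
  if (is.null(affectedBins)) affectedBins <- .archetypeBins(name, grid)
  if (!all(affectedBins %in% days))
    .stopf("affectedBins must be a subset of the grid labels")
  tpl <- stats::setNames(numeric(length(days)), days)
  sign <- if (name == "landing_dip") -1 else 1
  tpl[as.character(affectedBins)] <- sign * amplitude
  tpl
}

#' Generate a seeded synthetic cohort with planted trend archetypes
#'
#' Emulates a multi-subject biomarker panel study: subjects are split into
#' contiguous blocks, a fraction of the measurements is planted with
#' block-specific trend archetypes (cycling through \code{archetypes},
#' assigned to blocks round-robin), and the remaining measurements are flat
#' noise. Raw records are drawn on a per-subject schedule of roughly
#' \code{samplingInterval}-day spaced observation days with Gaussian jitter
#' and independent per-record dropout; each record's value is the archetype
#' template value of its mission-grid bin plus i.i.d. Gaussian noise. The
#' planted class and block structure are returned as ground truth, so every
#' downstream stage (classification, clustering, the cross-subject network)
#' has a recoverable answer.
#'
#' @param nSubjects,nMeasurements cohort dimensions (defaults mirror the
#'   27-subject, 264-measurement scale of the motivating cohort).
#' @param nBlocks number of subject blocks sharing archetype sets.
#' @param plantedFraction fraction of measurements planted with an archetype.
#' @param amplitude archetype excursion amplitude (intensity units).
#' @param noiseSd standard deviation of the additive observation noise.
#' @param samplingInterval,jitterSd raw sampling cadence in days and jitter.
#' @param dropout per-record dropout probability in \[0, 1\].
#' @param archetypes archetype menu cycled over planted measurements.
#' @param grid a \linkS4class{MissionGrid}.
#' @param seed integer seed; the same configuration and seed reproduce the
#'   records and truth exactly.
#' @return list with \code{records} (long-format data.frame: subject_id,
#'   measurement_id, fluid, time_days, value, units) and \code{truth} (list
#'   with \code{assignments}, one row per planted subject-measurement pair
#'   with archetype and expected trend-class family, and \code{blocks}, the
#'   named block label per subject).
#' @examples
#' sim <- simulateCohort(nSubjects = 4, nMeasurements = 8, seed = 1)
#' head(sim$records)
#' sim$truth$blocks
#' @export
simulateCohort <- function(nSubjects = 27, nMeasurements = 264, nBlocks = 4,
                           plantedFraction = 0.25, amplitude = 5,
                           noiseSd = 1, samplingInterval = 15, jitterSd = 3,
                           dropout = 0.1,
                           archetypes = c("flight_rise_persist",
                                          "flight_rise_revert",
                                          "landing_spike", "landing_dip"),
                           grid = missionGrid(), seed = NULL) {
  if (nSubjects < 0 || nMeasurements < 0)
    .stopf("counts must be nonnegative")
  if (dropout < 0 || dropout > 1) .stopf("dropout must be in [0, 1]")
  archetypes <- vapply(archetypes, match.arg, "", choices = .archetypeNames)
  emptyRecords <- data.frame(subject_id = character(0),
                             measurement_id = character(0),
                             fluid = character(0), time_days = numeric(0),
                             value = numeric(0), units = character(0),
                             stringsAsFactors = FALSE)
  if (nSubjects == 0L || nMeasurements == 0L)
    return(list(records = emptyRecords,
                truth = list(assignments = data.frame(
                  subject_id = character(0), measurement_id = character(0),
                  archetype = character(0), expectedClass = character(0)),
                  blocks = integer(0))))

  subjects <- sprintf("S%02d", seq_len(nSubjects))
  measurements <- sprintf("M%03d", seq_len(nMeasurements))
  blocks <- stats::setNames(
    sort(rep_len(seq_len(max(1L, nBlocks)), nSubjects)), subjects)

  nPlanted <- round(plantedFraction * nMeasurements)
  planted <- data.frame(
    measurement_id = measurements[seq_len(nPlanted)],
    block = rep_len(seq_len(max(1L, nBlocks)), nPlanted),
    archetype = rep_len(archetypes, nPlanted),
    stringsAsFactors = FALSE)

  classOf <- c(flight_rise_persist = "Lag", flight_rise_revert = "Lag",
               landing_spike = "SpikeMax", landing_dip = "SpikeMin",
               flat = "NoTrend")
  days <- gridDays(grid)
  bnd <- gridBoundaries(grid)
  templates <- lapply(stats::setNames(nm = unique(planted$archetype)),
                      archetypeTemplate, amplitude = amplitude, grid = grid)
  flatTpl <- stats::setNames(numeric(length(days)), days)

  withSeed(seed, {
    recs <- vector("list", nSubjects)
    truthRows <- list()
    for (si in seq_len(nSubjects)) {
      s <- subjects[si]
      sched <- seq(min(days), max(days), by = samplingInterval) +
        stats::rnorm(length(seq(min(days), max(days), by = samplingInterval)),
                     sd = jitterSd)
      sched <- pmin(pmax(sched, bnd[1]), tail(bnd, 1) - 1e-9)
      bin <- findInterval(sched, bnd, rightmost.closed = FALSE)
      subjRecs <- vector("list", nMeasurements)
      for (mi in seq_len(nMeasurements)) {
        m <- measurements[mi]
        pi <- match(m, planted$measurement_id)
        isPlanted <- !is.na(pi) && planted$block[pi] == blocks[[s]]
        tpl <- if (isPlanted) templates[[planted$archetype[pi]]] else flatTpl
        keep <- stats::runif(length(sched)) >= dropout
        if (!any(keep)) next
        vals <- tpl[bin[keep]] +
          (if (noiseSd > 0) stats::rnorm(sum(keep), sd = noiseSd) else 0)
        subjRecs[[mi]] <- data.frame(
          subject_id = s, measurement_id = m, fluid = "panel",
          time_days = sched[keep], value = as.numeric(vals), units = "a.u.",
          stringsAsFactors = FALSE)
        if (isPlanted)
          truthRows[[length(truthRows) + 1L]] <- data.frame(
            subject_id = s, measurement_id = m,
            archetype = planted$archetype[pi],
            expectedClass = classOf[[planted$archetype[pi]]],
            stringsAsFactors = FALSE)
      }
      recs[[si]] <- do.call(rbind, subjRecs)
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    assignments <- if (length(truthRows)) do.call(rbind, truthRows)
      else data.frame(subject_id = character(0),
                      measurement_id = character(0),
                      archetype = character(0), expectedClass = character(0))
    rownames(assignments) <- NULL
    list(records = records,
         truth = list(assignments = assignments, blocks = blocks))
  })
}

#' Write / read a cohort as long-format CSV
#'
#' The on-disk format is one header row and the columns subject_id,
#' measurement_id, fluid, time_days, value, units; missing values are empty
#' fields. \code{readCohort} validates the header and reports malformed
#' numeric fields with their row numbers.
#'
#' @param records long-format records data.frame (see [simulateCohort()]).
#' @param path file path.
#' @return \code{readCohort} returns the records data.frame;
#'   \code{writeCohort} returns \code{path} invisibly.
#' @export
writeCohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  req <- c("subject_id", "measurement_id", "fluid", "time_days", "value",
           "units")
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "")
  if (!all(req %in% colnames(raw)))
    .stopf("cohort file lacks required columns: %s",
           paste(setdiff(req, colnames(raw)), collapse = ", "))
  parseNum <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad))
      .stopf("non-numeric %s in row(s) %s", col,
             paste(utils::head(bad, 5), collapse = ", "))
    x
  }
  data.frame(subject_id = raw$subject_id,
             measurement_id = raw$measurement_id, fluid = raw$fluid,
             time_days = parseNum("time_days"), value = parseNum("value"),
             units = raw$units, stringsAsFactors = FALSE)
}

#' Write / read planted ground truth as JSON
#'
#' @param truth ground-truth list from [simulateCohort()].
#' @param path file path.
#' @return \code{readGroundTruth} returns the truth list.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(assignments = truth$assignments,
         blocks = as.list(truth$blocks)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- unlist(x$blocks)
  assignments <- as.data.frame(x$assignments, stringsAsFactors = FALSE)
  list(assignments = assignments,
       blocks = stats::setNames(as.integer(blocks), names(blocks)))
}
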