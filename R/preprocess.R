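#' Collapse raw records onto the mission grid
#'
#' Builds one binned series per (subject, measurement): each bin value is the
#' arithmetic mean of the raw values whose time falls in that bin's half-open
#' interval (repeated assays within a bin are averaged); bins with no records
#' are missing. Records outside the study window are dropped and logged in
#' \code{metadata(result)$outOfWindow}.
#'
#' @param records long-format records (see [readCohort()] for the columns).
#' @param grid a \linkS4class{MissionGrid}.
#' @return a \linkS4class{MissionExperiment} with the \code{"binned"} assay.
#' @examples
#' sim <- simulateCohort(nSubjects = 2, nMeasurements = 3, seed = 1)
#' me <- binRecords(sim$records)
#' binnedMatrix(me)[1:3, ]
#' @export
binRecords <- function(records, grid = missionGrid()) {
  req <- c("subject_id", "measurement_id", "time_days", "value")
  if (!all(req %in% colnames(records)))
    .stopf("records lack required columns: %s",
           paste(setdiff(req, colnames(records)), collapse = ", "))
  bnd <- gridBoundaries(grid)
  days <- gridDays(grid)
  nBins <- length(days)
  inWindow <- records$time_days >= bnd[1] & records$time_days < tail(bnd, 1) &
    is.finite(records$value)
  dropped <- records[!inWindow, , drop = FALSE]
  if (nrow(dropped))
    message(nrow(dropped), " record(s) outside the study window were dropped")
  records <- records[inWindow, , drop = FALSE]

  key <- paste(records$subject_id, records$measurement_id, sep = "\r")
  series <- sort(unique(key))
  bin <- findInterval(records$time_days, bnd, rightmost.closed = FALSE)
  ri <- match(key, series)
  li <- ri + (bin - 1L) * length(series)          # column-major linear index
  agg <- rowsum(cbind(records$value, 1), group = li)
  X <- matrix(NA_real_, length(series), nBins)
  counts <- matrix(0L, length(series), nBins)
  at <- as.integer(rownames(agg))
  X[at] <- agg[, 1] / agg[, 2]
  counts[at] <- as.integer(agg[, 2])

  parts <- strsplit(series, "\r", fixed = TRUE)
  rd <- DataFrame(subject_id = vapply(parts, `[`, "", 1L),
                  measurement_id = vapply(parts, `[`, "", 2L))
  rd$nPresent <- as.integer(rowSums(counts > 0L))
  dimnames(X) <- list(paste(rd$subject_id, rd$measurement_id, sep = "."),
                      as.character(days))
  se <- SummarizedExperiment(
    assays = list(binned = X), rowData = rd,
    colData = DataFrame(day = days, row.names = as.character(days)),
    metadata = list(grid = grid, outOfWindow = dropped))
  new("MissionExperiment", se)
}

#' Flag series usable for classification
#'
#' A series is kept when its baseline bin is present and at least
#' \code{minBins} of the grid bins are present; otherwise it is dropped with
#' a recorded reason ("no baseline" or "too few bins"). No imputation is
#' performed anywhere in the pipeline: the spectral machinery tolerates
#' missing bins directly.
#'
#' @param me a \linkS4class{MissionExperiment}.
#' @param minBins minimum number of present bins (default 5 of 8).
#' @return the experiment with logical \code{kept} and character
#'   \code{dropReason} columns in \code{rowData}.
#' @export
filterSeries <- function(me, minBins = 5) {
  stopifnot(is(me, "MissionExperiment"))
  X <- binnedMatrix(me)
  bi <- baselineIndex(me)
  present <- is.finite(X)
  reason <- rep(NA_character_, nrow(me))
  reason[!present[, bi]] <- "no baseline"
  few <- is.na(reason) & rowSums(present) < minBins
  reason[few] <- "too few bins"
  rowData(me)$kept <- is.na(reason)
  rowData(me)$dropReason <- reason
  metadata(me)$minBins <- minBins
  me
}

#' Baseline-difference and Euclidean-normalize binned series
#'
#' For every kept series, subtracts the pre-flight baseline bin value
#' (\code{-45} d by default) from each bin and scales the result to unit
#' Euclidean norm over its present bins, yielding series comparable across
#' measurements and subjects. Series identical to their baseline at every
#' present bin have zero norm; they are flagged \code{degenerate}, excluded
#' from classification downstream, and never divided by zero.
#'
#' @param me a \linkS4class{MissionExperiment}; [filterSeries()] is applied
#'   with its default first if filter flags are missing.
#' @param tol norm below which a differenced series counts as degenerate.
#' @return the experiment with a \code{"normalized"} assay (NA rows for
#'   dropped or degenerate series) and a logical \code{degenerate} column.
#' @export
baselineNormalize <- function(me, tol = 1e-12) {
  stopifnot(is(me, "MissionExperiment"))
  if (!"kept" %in% colnames(rowData(me))) me <- filterSeries(me)
  X <- binnedMatrix(me)
  bi <- baselineIndex(me)
  Q <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  degenerate <- rep(FALSE, nrow(X))
  for (i in which(rowData(me)$kept)) {
    x <- X[i, ]
    if (!is.finite(x[bi]))
      .stopf("series %d lacks its baseline bin; filterSeries should have dropped it", i)
    xt <- x - x[bi]
    nrm <- sqrt(sum(xt[is.finite(xt)]^2))
    if (nrm < tol) degenerate[i] <- TRUE else Q[i, ] <- xt / nrm
  }
  rowData(me)$degenerate <- degenerate
  assay(me, "normalized") <- Q
  me
}

#' One-call preprocessing: bin, filter, normalize
#'
#' @inheritParams binRecords
#' @inheritParams filterSeries
#' @return a \linkS4class{MissionExperiment} carrying both assays.
#' @export
preprocessCohort <- function(records, grid = missionGrid(), minBins = 5) {
  baselineNormalize(filterSeries(binRecords(records, grid), minBins))
}

#' Write preprocessing outputs as TSV
#'
#' Writes the binned matrix, the normalized matrix and a drop log (series
#' with their drop reasons) as tab-separated files.
#'
#' @param me a preprocessed \linkS4class{MissionExperiment}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writePreprocessed <- function(me, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- rowData(me)
  ann <- data.frame(subject_id = rd$subject_id,
                    measurement_id = rd$measurement_id)
  paths <- file.path(dir, c("binned.tsv", "normalized.tsv", "drop_log.tsv"))
  utils::write.table(cbind(ann, as.data.frame(binnedMatrix(me))), paths[1],
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  utils::write.table(cbind(ann, as.data.frame(normalizedMatrix(me))),
                     paths[2], sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  drop <- ann[!rd$kept, , drop = FALSE]
  drop$reason <- rd$dropReason[!rd$kept]
  utils::write.table(drop, paths[3], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
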