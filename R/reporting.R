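.phaseArrow <- function(m, epsilon) {
  if (!is.finite(m)) return(NA_character_)
  if (m > epsilon) "↑" else if (m < -epsilon) "↓" else "−"
}

# majority symbol; ties (or no votes) give the neutral "-"
.majority <- function(symbols) {
  symbols <- symbols[!is.na(symbols)]
  if (!length(symbols)) return("−")
  tab <- sort(table(symbols), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) "−" else names(tab)[1L]
}

#' Cohort-level trend summary table
#'
#' Counts, per measurement, the subjects with a BH-significant trend class,
#' and summarizes the majority direction of each mission phase relative to
#' the pre-flight baseline: F (flight, mean of the 33/82/132 d bins),
#' R (return, 165 d) and PR (post-return, mean of 195/225 d). A phase is
#' coded up-arrow when the subject's phase mean of the normalized series
#' exceeds \code{+epsilon}, down-arrow below \code{-epsilon}, and "-"
#' inside the deadband; the reported trend is the per-phase majority over
#' the significant subjects (ties are neutral). When at least
#' \code{secondaryFraction} of those subjects share a common triple that
#' differs from the primary one, the most frequent such triple is reported
#' as a secondary trend. Rows are ordered by descending subject count, ties
#' by measurement id.
#'
#' @param me a classified \linkS4class{MissionExperiment}.
#' @param epsilon deadband on the normalized scale (default 0.1); normalized
#'   series have unit norm, so a fixed deadband is comparable across
#'   measurements.
#' @param secondaryFraction minimum fraction of subjects sharing a deviating
#'   triple for it to be reported (default 0.25).
#' @param gate which significance flag selects the counted subjects:
#'   \code{"class"} (the quantile rule assigned a trend class, the method's
#'   own definition of a significant trend) or \code{"bh"} (additionally
#'   survives the per-subject BH gate).
#' @return data.frame with measurement_id, n_subjects, trendF, trendR,
#'   trendPR and secondary (a 3-character triple or NA).
#' @export
summarizeTrends <- function(me, epsilon = 0.1, secondaryFraction = 0.25,
                            gate = c("class", "bh")) {
  gate <- match.arg(gate)
  rd <- rowData(me)
  if (!"significant" %in% colnames(rd)) .stopf("run classifyCohort() first")
  Q <- normalizedMatrix(me)
  days <- gridDays(me)
  fBins <- which(days >= 33 & days <= 132)
  rBins <- which(days == 165)
  prBins <- which(days > 165)
  sig <- which(if (gate == "bh") rd$bhSignificant else rd$significant)
  out <- list()
  for (m in sort(unique(rd$measurement_id[sig]))) {
    rows <- sig[rd$measurement_id[sig] == m]
    triples <- t(vapply(rows, function(i) {
      q <- Q[i, ]
      c(.phaseArrow(mean(q[fBins], na.rm = TRUE), epsilon),
        .phaseArrow(mean(q[rBins], na.rm = TRUE), epsilon),
        .phaseArrow(mean(q[prBins], na.rm = TRUE), epsilon))
    }, character(3)))
    primary <- apply(triples, 2, .majority)
    tripleStr <- apply(triples, 1, paste, collapse = "")
    tripleStr <- tripleStr[!grepl("NA", tripleStr, fixed = TRUE)]
    secondary <- NA_character_
    others <- tripleStr[tripleStr != paste(primary, collapse = "")]
    if (length(others)) {
      tab <- sort(table(others), decreasing = TRUE)
      if (tab[1L] / length(rows) >= secondaryFraction)
        secondary <- names(tab)[1L]
    }
    out[[m]] <- data.frame(measurement_id = m, n_subjects = length(rows),
                           trendF = primary[1L], trendR = primary[2L],
                           trendPR = primary[3L], secondary = secondary,
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(measurement_id = character(0),
                      n_subjects = integer(0), trendF = character(0),
                      trendR = character(0), trendPR = character(0),
                      secondary = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(-res$n_subjects, res$measurement_id), ]
  rownames(res) <- NULL
  res
}

#' Write the trend summary as TSV
#'
#' @param summary output of [summarizeTrends()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTrendSummary <- function(summary, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(summary, con, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
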