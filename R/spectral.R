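#' Spectral analysis frequency grid for a set of timepoints
#'
#' Returns the run-level frequency grid shared by every series of an
#' analysis: \code{f_k = k / (2 * span)} for \code{k = 1..nLags *
#' oversampling}, where span is the width of the time window and
#' \code{nLags = floor(N/2)}. The grid starts at half a cycle per window --
#' essential for slow monotone trends, whose power sits below one cycle per
#' window -- and extends past the pseudo-Nyquist rate of the mean sampling
#' interval, oversampled fourfold by default so that all representable lags
#' on a short window are resolved.
#'
#' An alternative is the natural grid \code{f_k = k/(N * d)},
#' \code{k = 1..floor(N/2)} (\code{oversampling = NULL}), at which the
#' inverse Fourier transform of the periodogram of a complete, evenly
#' sampled window reproduces the circular lagged-product autocorrelations
#' exactly; it resolves trend classes poorly on 8-point windows and is kept
#' for verification.
#'
#' @param times numeric vector of sampling times (the full grid, not only the
#'   observed subset).
#' @param oversampling frequency oversampling factor (default 4); NULL
#'   selects the natural grid.
#' @return list with \code{frequencies}, \code{lagStep} (the mean interval
#'   \code{d = span/(N-1)}, the time unit of one lag) and \code{nLags}
#'   (= floor(N/2)).
#' @examples
#' spectralGrid(gridDays(missionGrid()))
#' @export
spectralGrid <- function(times, oversampling = 4) {
  n <- length(times)
  if (n < 2L) .stopf("need at least 2 timepoints")
  span <- diff(range(times))
  d <- span / (n - 1)
  nl <- n %/% 2L
  freqs <- if (is.null(oversampling)) seq_len(nl) / (n * d)
    else seq_len(nl * oversampling) / (2 * span)
  list(frequencies = freqs, lagStep = d, nLags = nl)
}

# Precompute the Lomb-Scargle design for one set of observed times: the
# tau-rotated cosine/sine bases and their squared sums, with degenerate
# components (vanishing basis, e.g. the sine at an exact Nyquist frequency of
# an integer grid) zeroed out so they contribute no power.
lombScargleDesign <- function(times, freqs) {
  w <- 2 * pi * freqs
  n <- length(times)
  Ct <- matrix(0, n, length(freqs))
  St <- matrix(0, n, length(freqs))
  CC <- numeric(length(freqs))
  SS <- numeric(length(freqs))
  for (j in seq_along(freqs)) {
    tau <- atan2(sum(sin(2 * w[j] * times)), sum(cos(2 * w[j] * times))) /
      (2 * w[j])
    ct <- cos(w[j] * (times - tau))
    st <- sin(w[j] * (times - tau))
    cc <- sum(ct^2)
    ss <- sum(st^2)
    if (cc < 1e-10) { ct[] <- 0; cc <- 1 }
    if (ss < 1e-10) { st[] <- 0; ss <- 1 }
    Ct[, j] <- ct; St[, j] <- st
    CC[j] <- cc; SS[j] <- ss
  }
  list(Ct = Ct, St = St, CC = CC, SS = SS)
}

# Vectorized classical Lomb-Scargle power for many complete series sharing
# one time grid. Y: n_series x n_times. Returns n_series x n_freqs.
periodogramMatrix <- function(Y, design) {
  Yc <- Y - rowMeans(Y)
  A <- Yc %*% design$Ct
  B <- Yc %*% design$St
  0.5 * (sweep(A^2, 2, design$CC, "/") + sweep(B^2, 2, design$SS, "/"))
}

#' Classical Lomb-Scargle periodogram
#'
#' Least-squares spectral power of a (possibly unevenly sampled) series at a
#' set of frequencies. Missing values are simply absent from the fit: no
#' imputation is performed. At each frequency f the power equals the
#' reduction in residual sum of squares, divided by two, obtained by fitting
#' \code{a*cos(2*pi*f*t) + b*sin(2*pi*f*t)} to the mean-centered observed
#' values, computed in closed form via the classical phase-shift (tau)
#' formulation.
#'
#' @param values numeric series values; NA marks missing observations.
#' @param times observation times, same length as \code{values}.
#' @param frequencies frequencies (1/day) at which to evaluate the power;
#'   defaults to the natural grid of \code{times} (see [spectralGrid()]).
#' @return numeric vector of nonnegative power values, one per frequency.
#' @examples
#' t <- gridDays(missionGrid())
#' y <- cos(2 * pi * t / 200)
#' lombScarglePeriodogram(y, t)
#' @export
lombScarglePeriodogram <- function(values, times,
                                   frequencies = spectralGrid(times)$frequencies) {
  if (length(values) != length(times))
    .stopf("values and times must have equal length")
  ok <- is.finite(values)
  if (sum(ok) < 3L)
    .stopf("need at least 3 present points, got %d", sum(ok))
  d <- lombScargleDesign(times[ok], frequencies)
  drop(periodogramMatrix(matrix(values[ok], nrow = 1L), d))
}

#' Autocorrelations from a periodogram
#'
#' Inverse Fourier transform of the spectral power, evaluated at integer
#' multiples of the lag step: \code{rho_l = sum_k P_k cos(2*pi*f_k*l*d) /
#' sum_k P_k}. The normalization makes \code{rho_0 = 1} exactly, and
#' nonnegative power bounds every \code{|rho_l|} by 1. On a complete, evenly
#' sampled window with the natural frequency grid this reproduces the direct
#' (circular) lagged-product autocorrelation of the centered series to
#' machine precision.
#'
#' @param power nonnegative periodogram values.
#' @param frequencies the frequencies the power was evaluated at.
#' @param lagStep time length of one lag (the grid's mean sampling interval).
#' @param nLags largest lag; defaults to \code{length(power)} (= floor(N/2)
#'   on the natural grid).
#' @return numeric vector \code{rho} of length \code{nLags + 1} (lags
#'   0..nLags).
#' @examples
#' g <- spectralGrid(0:7)
#' p <- lombScarglePeriodogram(rnorm(8), 0:7, g$frequencies)
#' autocorrelations(p, g$frequencies, g$lagStep)
#' @export
autocorrelations <- function(power, frequencies, lagStep,
                             nLags = length(power)) {
  if (length(power) != length(frequencies))
    .stopf("power and frequencies must have equal length")
  if (any(power < -1e-12)) .stopf("power must be nonnegative")
  tot <- sum(power)
  if (tot <= 1e-300)
    .stopf("all-zero power: degenerate series should be excluded upstream")
  phases <- 2 * pi * outer(frequencies * lagStep, 0:nLags)
  drop(crossprod(power, cos(phases))) / tot
}

#' Bootstrap series periodograms and autocorrelations
#'
#' Draws \code{n} bootstrap series by resampling pooled values with
#' replacement onto the time grid and returns their Lomb-Scargle
#' periodograms (one row per series) on the run-level frequency grid;
#' \code{bootstrapAutocorrelations} additionally inverts them to
#' autocorrelation profiles (lags 0..floor(N/2)). These are the null-model
#' building blocks behind [buildNull()] and [similarityRadius()], exposed so
#' calibration checks can draw held-out null sets under the same scheme.
#'
#' @param pool numeric vector of pooled values.
#' @param times the full sampling grid.
#' @param n number of bootstrap series.
#' @param seed integer seed.
#' @param frequencies frequency grid (defaults to [spectralGrid()] of
#'   \code{times}).
#' @return a numeric matrix: periodogram power (n x n_frequencies), or
#'   autocorrelations (n x (nLags + 1)).
#' @export
bootstrapPeriodograms <- function(pool, times, n, seed = NULL,
                                  frequencies = spectralGrid(times)$frequencies) {
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0L) .stopf("empty bootstrap pool")
  design <- lombScargleDesign(times, frequencies)
  withSeed(seed, {
    Y <- matrix(sample(pool, n * length(times), replace = TRUE), nrow = n)
    periodogramMatrix(Y, design)
  })
}

#' @rdname bootstrapPeriodograms
#' @export
bootstrapAutocorrelations <- function(pool, times, n, seed = NULL,
                                      frequencies = spectralGrid(times)$frequencies) {
  sg <- spectralGrid(times)
  P <- bootstrapPeriodograms(pool, times, n, seed, frequencies)
  autocorrelationMatrix(P, frequencies, sg$lagStep, sg$nLags)
}

# rho for many series sharing a frequency grid; rows with (near) zero total
# power get rho = 0 at all lags >= 1 (no resolvable structure).
autocorrelationMatrix <- function(P, frequencies, lagStep, nLags) {
  phases <- 2 * pi * outer(frequencies * lagStep, 0:nLags)
  tot <- rowSums(P)
  zero <- tot <= 1e-300
  tot[zero] <- 1
  R <- (P %*% cos(phases)) / tot
  if (any(zero)) R[zero, ] <- rep(c(1, rep(0, nLags)), each = sum(zero))
  R
}

#' Compute periodograms and autocorrelation profiles for a cohort
#'
#' Evaluates the Lomb-Scargle periodogram of every kept, non-degenerate
#' normalized series on the run-level frequency grid shared by all series,
#' and the corresponding autocorrelation profile at lags 0..floor(N/2).
#' Results are stored as matrix columns of \code{rowData} (\code{periodogram}
#' and \code{acf}); rows that were dropped or are degenerate get NA.
#' Series with fewer than 3 present bins cannot support a periodogram and are
#' additionally marked dropped.
#'
#' @param me a \linkS4class{MissionExperiment} after [baselineNormalize()].
#' @return the experiment with spectral profiles in \code{rowData} and the
#'   frequency grid in \code{metadata(me)$spectral}.
#' @export
computeSpectra <- function(me) {
  stopifnot(is(me, "MissionExperiment"))
  Q <- normalizedMatrix(me)
  days <- gridDays(me)
  # spectra live in grid-step time: lags are defined in grid steps, and the
  # uneven day spacing would otherwise leak sampling-gap structure into
  # every spectrum
  stepTime <- seq_along(days) - 1
  sg <- spectralGrid(stepTime)
  nf <- length(sg$frequencies)
  nl <- sg$nLags
  P <- matrix(NA_real_, nrow(me), nf)
  R <- matrix(NA_real_, nrow(me), nl + 1L)
  rd <- rowData(me)
  use <- rd$kept & !rd$degenerate
  fullDesign <- lombScargleDesign(stepTime, sg$frequencies)
  for (i in which(use)) {
    q <- Q[i, ]
    ok <- is.finite(q)
    if (sum(ok) < 3L) { use[i] <- FALSE; next }
    p <- if (all(ok)) drop(periodogramMatrix(matrix(q, nrow = 1L), fullDesign))
         else lombScarglePeriodogram(q, stepTime, sg$frequencies)
    P[i, ] <- p
    R[i, ] <- autocorrelations(p, sg$frequencies, sg$lagStep, nl)
  }
  rd$periodogram <- P
  rd$acf <- R
  rowData(me) <- rd
  metadata(me)$spectral <- sg
  me
}

#' Bootstrap null distribution for a subject
#'
#' Draws \code{nBoot} bootstrap series by sampling, with replacement, from a
#' pool of observed normalized values onto the full time grid, and computes
#' (i) the per-lag upper quantiles of their autocorrelations (the lag-class
#' thresholds), (ii) the upper quantile of their maxima and the lower-tail
#' quantile of their minima (the spike thresholds), and (iii) the sorted null
#' statistics used for empirical p-values.
#'
#' @param pool numeric vector of pooled values (typically all present
#'   normalized values of one subject across measurements and times).
#' @param times the full sampling grid the bootstrap series live on.
#' @param nBoot number of bootstrap series (default 1e5).
#' @param level quantile level for the thresholds (default 0.95); minima use
#'   the symmetric lower tail \code{1 - level}.
#' @param seed integer seed; identical seeds give identical nulls.
#' @return a \linkS4class{SpectralNull}.
#' @examples
#' null <- buildNull(rnorm(200), gridDays(missionGrid()),
#'                   nBoot = 1000, seed = 7)
#' rhoThresholds(null)
#' @export
buildNull <- function(pool, times, nBoot = 1e5, level = 0.95, seed = NULL) {
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0L) .stopf("empty bootstrap pool")
  if (nBoot < 1L) .stopf("nBoot must be positive")
  n <- length(times)
  sg <- spectralGrid(times)
  design <- lombScargleDesign(times, sg$frequencies)
  withSeed(seed, {
    Y <- matrix(sample(pool, nBoot * n, replace = TRUE), nrow = nBoot)
    P <- periodogramMatrix(Y, design)
    R <- autocorrelationMatrix(P, sg$frequencies, sg$lagStep, sg$nLags)
    rhoQ <- apply(R[, -1L, drop = FALSE], 2, stats::quantile, probs = level,
                  names = FALSE)
    maxima <- do.call(pmax, as.data.frame(Y))
    minima <- do.call(pmin, as.data.frame(Y))
    maxRho <- do.call(pmax, as.data.frame(R[, -1L, drop = FALSE]))
    new("SpectralNull",
        rhoQ = as.numeric(rhoQ),
        maxQ = as.numeric(stats::quantile(maxima, level, names = FALSE)),
        minQ = as.numeric(stats::quantile(minima, 1 - level, names = FALSE)),
        level = level, nBoot = as.integer(nBoot),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed),
        nullMaxRho = sort(maxRho), nullMaxima = sort(maxima),
        nullMinima = sort(minima))
  })
}

#' @rdname SpectralNull-class
#' @export
setMethod("rhoThresholds", "SpectralNull", function(x) x@rhoQ)

#' @rdname SpectralNull-class
#' @export
setMethod("spikeThresholds", "SpectralNull",
          function(x) c(max = x@maxQ, min = x@minQ))

setMethod("show", "SpectralNull", function(object) {
  cat("SpectralNull:", object@nBoot, "bootstrap series, level",
      object@level, "\n")
  cat("  rho thresholds (lags 1..", length(object@rhoQ), "): ",
      paste(signif(object@rhoQ, 4), collapse = ", "), "\n", sep = "")
  cat("  spike thresholds: max >", signif(object@maxQ, 4),
      ", min <", signif(object@minQ, 4), "\n")
})

# empirical upper-tail p with add-one correction
.empiricalP <- function(sortedNull, observed, lower = FALSE) {
  n <- length(sortedNull)
  if (n == 0L) return(NA_real_)
  if (lower) {
    k <- findInterval(observed, sortedNull, left.open = TRUE)  # strictly below
    (1 + k) / (n + 1)
  } else {
    k <- n - findInterval(observed, sortedNull)                # strictly above? >=
    (1 + k) / (n + 1)
  }
}

#' Classify one series into a trend class
#'
#' Applies the lag rule first: the series is assigned class LagM where M is
#' the smallest lag whose autocorrelation meets or exceeds its per-lag null
#' threshold. Only series failing the lag criterion at every lag are tested
#' for spikes: a maximum strictly above the null maxima threshold gives
#' SpikeMax, otherwise a minimum strictly below the null minima threshold
#' gives SpikeMin; all remaining series are NoTrend. The empirical p-value
#' of the deciding statistic (max-over-lags autocorrelation, or the spike
#' extremum) is computed against the stored null distribution with an
#' add-one correction.
#'
#' @param rho autocorrelation profile (lags 0..L) of the series.
#' @param values the normalized series values the spike test applies to
#'   (NA allowed).
#' @param null a \linkS4class{SpectralNull} sharing the lag range.
#' @return list with \code{kind} ("Lag1".."LagL", "SpikeMax", "SpikeMin" or
#'   "NoTrend"), \code{M} (the lag, NA unless a lag class) and \code{p}.
#' @export
classifySeries <- function(rho, values, null) {
  stopifnot(is(null, "SpectralNull"))
  L <- length(null@rhoQ)
  if (length(rho) < L + 1L)
    .stopf("profile has %d lags but null has %d", length(rho) - 1L, L)
  lagRho <- rho[2:(L + 1L)]
  hit <- which(lagRho >= null@rhoQ)
  maxRho <- max(lagRho)
  if (length(hit)) {
    M <- hit[1L]
    return(list(kind = paste0("Lag", M), M = M,
                p = .empiricalP(null@nullMaxRho, maxRho)))
  }
  v <- values[is.finite(values)]
  if (length(v) && max(v) > null@maxQ)
    return(list(kind = "SpikeMax", M = NA_integer_,
                p = .empiricalP(null@nullMaxima, max(v))))
  if (length(v) && min(v) < null@minQ)
    return(list(kind = "SpikeMin", M = NA_integer_,
                p = .empiricalP(null@nullMinima, min(v), lower = TRUE)))
  list(kind = "NoTrend", M = NA_integer_,
       p = .empiricalP(null@nullMaxRho, maxRho))
}

#' Benjamini-Hochberg significance gate
#'
#' Selects the p-values surviving Benjamini-Hochberg false-discovery-rate
#' control at level \code{alpha}, via \code{stats::p.adjust}.
#'
#' @param p numeric vector of empirical p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return logical vector: TRUE where selected.
#' @examples
#' significanceAdjust(c(0.001, 0.02, 0.8))
#' @export
significanceAdjust <- function(p, alpha = 0.05) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH") <= alpha
  out
}

#' Classify every series of a cohort
#'
#' For each subject, pools all present normalized values across that
#' subject's kept, non-degenerate series, builds a bootstrap null
#' ([buildNull()]) with a subject-specific seed derived from \code{seed},
#' classifies each series ([classifySeries()]), and gates the resulting
#' empirical p-values per subject with Benjamini-Hochberg at \code{alpha}.
#' A series is reported as significant when it has a trend class (not
#' NoTrend) and survives the FDR gate.
#'
#' @param me a \linkS4class{MissionExperiment}; [computeSpectra()] is run
#'   first if spectra are missing.
#' @param nBoot bootstrap series per subject (default 1e5).
#' @param level null quantile level (default 0.95).
#' @param alpha FDR level for the per-subject gate (default 0.05).
#' @param seed integer seed; per-subject seeds are derived deterministically.
#' @param keepNulls keep the full null statistic vectors in
#'   \code{metadata(me)$nulls} (large); by default slimmed objects with only
#'   the thresholds are stored.
#' @return the experiment with \code{trendClass}, \code{lagM},
#'   \code{empiricalP}, \code{significant} (the series has a trend class:
#'   the quantile rule itself defines a statistically significant trend) and
#'   \code{bhSignificant} (additionally survives the per-subject BH gate on
#'   the empirical p-values) columns in \code{rowData}.
#' @export
classifyCohort <- function(me, nBoot = 1e5, level = 0.95, alpha = 0.05,
                           seed = NULL, keepNulls = FALSE) {
  stopifnot(is(me, "MissionExperiment"))
  if (!"acf" %in% colnames(rowData(me))) me <- computeSpectra(me)
  rd <- rowData(me)
  Q <- normalizedMatrix(me)
  stepTime <- seq_len(ncol(me)) - 1
  n <- nrow(me)
  cls <- rep(NA_character_, n)
  lagM <- rep(NA_integer_, n)
  pval <- rep(NA_real_, n)
  subjects <- sort(unique(rd$subject_id))
  nulls <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    rows <- which(rd$subject_id == s & rd$kept & !rd$degenerate &
                    is.finite(rd$acf[, 1L]))
    if (!length(rows)) next
    pool <- as.vector(Q[rows, , drop = FALSE])
    null <- buildNull(pool, stepTime, nBoot = nBoot, level = level,
                      seed = childSeed(seed, si))
    for (i in rows) {
      res <- classifySeries(rd$acf[i, ], Q[i, ], null)
      cls[i] <- res$kind
      lagM[i] <- res$M
      pval[i] <- res$p
    }
    if (!keepNulls) {
      null@nullMaxRho <- numeric(0)
      null@nullMaxima <- numeric(0)
      null@nullMinima <- numeric(0)
    }
    nulls[[s]] <- null
  }
  bh <- rep(FALSE, n)
  for (s in subjects) {
    rows <- which(rd$subject_id == s & !is.na(cls))
    if (!length(rows)) next
    bh[rows] <- significanceAdjust(pval[rows], alpha) & cls[rows] != "NoTrend"
  }
  rd$trendClass <- cls
  rd$lagM <- lagM
  rd$empiricalP <- pval
  rd$significant <- !is.na(cls) & cls != "NoTrend"
  rd$bhSignificant <- bh
  rowData(me) <- rd
  metadata(me)$nulls <- nulls
  metadata(me)$classification <- list(nBoot = nBoot, level = level,
                                      alpha = alpha, seed = seed)
  me
}
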