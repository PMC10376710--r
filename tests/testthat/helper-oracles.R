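# Independent oracles used across the suite. Each reimplements the checked
# quantity by the most direct route available, never through the package's
# own code path.

# least-squares sinusoid-fit power at one frequency: (RSS0 - RSS)/2 after
# fitting a*cos + b*sin to the mean-centered values
oracleLsPower <- function(y, t, freqs) {
  ok <- is.finite(y)
  yc <- y[ok] - mean(y[ok])
  t <- t[ok]
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    X <- cbind(cos(w * t), sin(w * t))
    # a basis function that vanishes at every sample point (e.g. the sine at
    # an exact Nyquist frequency of an integer grid) spans nothing
    X <- X[, sqrt(colSums(X^2)) > 1e-6, drop = FALSE]
    if (ncol(X) == 0L) return(0)
    fit <- lm.fit(X, yc)
    (sum(yc^2) - sum(fit$residuals^2)) / 2
  }, 0)
}

# direct circular lagged-product autocorrelation of the centered series
oracleCircularRho <- function(y, nLags) {
  yc <- y - mean(y)
  n <- length(yc)
  c0 <- sum(yc^2)
  vapply(0:nLags, function(l) {
    sum(yc * yc[((seq_len(n) - 1 + l) %% n) + 1]) / c0
  }, 0)
}

# breadth-first search returning the fewest-hop, lexicographically smallest
# path from vertex 1 to vertex n
oracleBfsPath <- function(A) {
  n <- nrow(A)
  best <- NULL
  frontier <- list(1L)
  visitedDepth <- rep(Inf, n)
  visitedDepth[1L] <- 0
  repeat {
    nxt <- list()
    for (path in frontier) {
      v <- path[length(path)]
      if (v == n) {
        if (is.null(best)) best <- path
        else {
          for (i in seq_along(path)) {          # lexicographic comparison
            if (path[i] < best[i]) { best <- path; break }
            if (path[i] > best[i]) break
          }
        }
        next
      }
      for (u in which(A[v, ])) {
        d <- length(path)
        if (d <= visitedDepth[u]) {
          visitedDepth[u] <- d
          nxt[[length(nxt) + 1L]] <- c(path, u)
        }
      }
    }
    if (!is.null(best)) return(best)
    if (!length(nxt)) return(NULL)
    frontier <- nxt
  }
}

# count of shortest paths (to detect ties)
oracleCountShortest <- function(A) {
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  length(igraph::all_shortest_paths(g, from = 1, to = n)$vpaths)
}

# normalized series the way the pipeline defines it (for building fixtures)
normalizeSeries <- function(x, baselineIdx = 2L) {
  xt <- x - x[baselineIdx]
  xt / sqrt(sum(xt[is.finite(xt)]^2))
}

# small classified experiment built from raw parts, for reporting tests
makeClassifiedExperiment <- function(Q, subjects, measurements, classes,
                                     significant = classes != "NoTrend") {
  days <- gridDays(missionGrid())
  records <- do.call(rbind, lapply(seq_len(nrow(Q)), function(i) {
    data.frame(subject_id = subjects[i], measurement_id = measurements[i],
               fluid = "panel", time_days = days, value = Q[i, ],
               units = "a.u.")
  }))
  me <- preprocessCohort(records)
  rd <- rowData(me)
  key <- paste(subjects, measurements)
  ord <- match(paste(rd$subject_id, rd$measurement_id), key)
  assay(me, "normalized", withDimnames = FALSE) <- Q[ord, , drop = FALSE]
  rd$trendClass <- classes[ord]
  rd$lagM <- ifelse(grepl("^Lag", classes[ord]), 1L, NA_integer_)
  rd$empiricalP <- ifelse(classes[ord] == "NoTrend", 0.8, 0.01)
  rd$significant <- significant[ord]
  rd$bhSignificant <- significant[ord]
  rowData(me) <- rd
  me
}
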