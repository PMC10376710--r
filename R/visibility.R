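#' Median signal of a set of normalized series
#'
#' Per-bin median across the member series, ignoring missing values; bins
#' missing in every member stay missing.
#'
#' @param members matrix of normalized series (rows = members) or a single
#'   numeric series.
#' @return numeric vector of per-bin medians.
#' @export
medianGroupSignal <- function(members) {
  members <- rbind(members)
  if (nrow(members) == 0L) .stopf("empty member set")
  out <- apply(members, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) stats::median(v) else NA_real_
  })
  as.numeric(out)
}

#' Natural visibility graph of a series
#'
#' Connects two timepoints i < j when the straight line between
#' \code{(t_i, y_i)} and \code{(t_j, y_j)} passes strictly above every
#' intermediate point: \code{y_k < y_j + (y_i - y_j) (t_j - t_k)/(t_j - t_i)}
#' for all i < k < j. Adjacent timepoints are always connected (the
#' criterion is vacuous), so the graph is connected; the strict inequality
#' means a constant series yields a path graph. Missing values are dropped:
#' vertices are the present timepoints in time order, and \code{vertices}
#' records their 0-based positions on the original grid.
#'
#' @param values series values (NA allowed).
#' @param times timepoints, same length; defaults to the index sequence.
#' @return a \linkS4class{VisibilityGraph}.
#' @examples
#' vg <- naturalVisibilityGraph(c(0, 0, 0, 0, 0, 2, 0, 0),
#'                              gridDays(missionGrid()))
#' adjacency(vg)
#' @export
naturalVisibilityGraph <- function(values, times = seq_along(values) - 1) {
  if (length(values) != length(times))
    .stopf("values and times must have equal length")
  ok <- is.finite(values)
  if (sum(ok) < 2L) .stopf("need at least 2 present points")
  y <- values[ok]
  t <- times[ok]
  n <- length(y)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ks <- seq_len(j - i - 1L) + i
      visible <- all(y[ks] < y[j] + (y[i] - y[j]) * (t[j] - t[ks]) /
                       (t[j] - t[i]))
      A[i, j] <- A[j, i] <- visible
    }
  }
  new("VisibilityGraph", adjacency = A, times = as.numeric(t),
      values = as.numeric(y), vertices = as.integer(which(ok) - 1L))
}

#' @rdname VisibilityGraph-class
#' @export
setMethod("adjacency", "VisibilityGraph", function(x) x@adjacency)

setMethod("show", "VisibilityGraph", function(object) {
  cat("VisibilityGraph:", length(object@times), "vertices,",
      sum(object@adjacency) / 2, "edges\n")
})

# lexicographically smallest among the fewest-hop paths from the first to
# the last vertex (vertices in time order)
.shortestPath <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  paths <- igraph::all_shortest_paths(g, from = 1, to = nrow(A))$vpaths
  seqs <- lapply(paths, as.integer)
  ord <- do.call(order, as.data.frame(do.call(rbind, seqs)))
  seqs[[ord[1L]]]
}

#' Temporal communities from a visibility graph
#'
#' Finds the endpoint shortest path (fewest hops from the first to the last
#' timepoint; ties broken toward the lexicographically smallest vertex
#' sequence) and delimits temporal communities at the path vertices that
#' terminate a multi-step jump: a path edge skipping over intermediate
#' timepoints marks a change of temporal regime, while a stretch of the path
#' that advances one timepoint at a time stays inside a single community.
#' Communities are therefore the contiguous runs between consecutive
#' delimiting vertices; each delimiting vertex joins the adjacent community
#' with which it shares more visibility edges (processed in time order; ties
#' go to the earlier community), so the final partition is contiguous in
#' time and covers every vertex exactly once.
#'
#' @param vg a \linkS4class{VisibilityGraph}.
#' @return list with \code{shortestPath} (0-based grid indices along the
#'   path), \code{membership} (community id per vertex, in time order) and
#'   \code{communities} (list of 0-based grid index vectors).
#' @export
visibilityCommunities <- function(vg) {
  stopifnot(is(vg, "VisibilityGraph"))
  A <- vg@adjacency
  n <- nrow(A)
  path <- .shortestPath(A)
  b <- sort(unique(path))
  # community delimiters: endpoints, plus both ends of every multi-step jump
  jump <- which(diff(b) > 1L)
  J <- sort(unique(c(b[1L], b[jump], b[jump + 1L], b[length(b)])))
  nSeg <- max(length(J) - 1L, 1L)
  members <- vector("list", nSeg)
  if (length(J) == 1L) members[[1L]] <- J[1L]
  else {
    for (i in seq_len(nSeg)) {
      lo <- J[i] + 1L; hi <- J[i + 1L] - 1L
      members[[i]] <- if (lo <= hi) lo:hi else integer(0)
    }
    members[[1L]] <- sort(c(J[1L], members[[1L]]))
    for (i in seq_len(nSeg)[-1L]) {
      v <- J[i]
      left <- sum(A[v, members[[i - 1L]]])
      right <- sum(A[v, members[[i]]])
      if (right > left) members[[i]] <- sort(c(v, members[[i]]))
      else members[[i - 1L]] <- sort(c(members[[i - 1L]], v))
    }
    members[[nSeg]] <- sort(c(members[[nSeg]], J[nSeg + 1L]))
  }
  members <- members[vapply(members, length, 0L) > 0L]
  membership <- integer(n)
  for (ci in seq_along(members)) membership[members[[ci]]] <- ci
  list(shortestPath = vg@vertices[path],
       membership = membership,
       communities = lapply(members, function(ix) vg@vertices[ix]))
}

#' Visibility summaries for every clustered group
#'
#' For each (subject, class, group, subgroup) cell of a clustered cohort,
#' computes the median normalized signal of its members, its natural
#' visibility graph and temporal communities.
#'
#' @param me a clustered \linkS4class{MissionExperiment}
#'   (see [clusterTrends()]).
#' @return nested list keyed subject / class / "G<g>S<s>", each element
#'   holding \code{median}, \code{edges} (2-column 0-based matrix),
#'   \code{communities} and \code{shortestPath}.
#' @export
visibilitySummary <- function(me) {
  rd <- rowData(me)
  if (!"group" %in% colnames(rd)) .stopf("run clusterTrends() first")
  Q <- normalizedMatrix(me)
  days <- gridDays(me)
  out <- list()
  cells <- which(!is.na(rd$group))
  if (!length(cells)) return(out)
  keyDf <- data.frame(s = rd$subject_id[cells], cl = rd$trendClass[cells],
                      g = rd$group[cells], sg = rd$subgroup[cells])
  for (key in unique(paste(keyDf$s, keyDf$cl, keyDf$g, keyDf$sg))) {
    rows <- cells[paste(keyDf$s, keyDf$cl, keyDf$g, keyDf$sg) == key]
    med <- medianGroupSignal(Q[rows, , drop = FALSE])
    if (sum(is.finite(med)) < 2L) next
    vg <- naturalVisibilityGraph(med, days)
    vc <- visibilityCommunities(vg)
    s <- rd$subject_id[rows[1L]]
    cl <- rd$trendClass[rows[1L]]
    cell <- sprintf("G%dS%d", rd$group[rows[1L]], rd$subgroup[rows[1L]])
    e <- which(vg@adjacency & upper.tri(vg@adjacency), arr.ind = TRUE)
    out[[s]][[cl]][[cell]] <- list(
      median = med,
      vertices = vg@vertices,
      edges = cbind(vg@vertices[e[, 1L]], vg@vertices[e[, 2L]]),
      communities = vc$communities,
      shortestPath = vc$shortestPath,
      members = rd$measurement_id[rows])
  }
  out
}

#' Write visibility summaries as JSON
#'
#' @param summaries output of [visibilitySummary()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeVisibilityJSON <- function(summaries, path) {
  jsonlite::write_json(summaries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
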