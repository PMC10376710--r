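#' Per-measurement periodogram distance matrices
#'
#' For each measurement, the symmetric matrix of Euclidean distances between
#' the subjects' periodograms of that measurement, over the full subject
#' roster; entries are NA when either subject lacks a usable series for the
#' measurement. All periodograms share the run-level frequency grid.
#'
#' @param me a \linkS4class{MissionExperiment} after [computeSpectra()].
#' @return named list (one element per measurement) of subject-by-subject
#'   distance matrices.
#' @export
periodogramDistances <- function(me) {
  rd <- rowData(me)
  if (!"periodogram" %in% colnames(rd)) .stopf("run computeSpectra() first")
  subjects <- sort(unique(rd$subject_id))
  usable <- rd$kept & !rd$degenerate & is.finite(rd$periodogram[, 1L])
  out <- list()
  for (m in sort(unique(rd$measurement_id))) {
    rows <- which(usable & rd$measurement_id == m)
    D <- matrix(NA_real_, length(subjects), length(subjects),
                dimnames = list(subjects, subjects))
    if (length(rows) >= 2L) {
      P <- rd$periodogram[rows, , drop = FALSE]
      d <- as.matrix(stats::dist(P))
      who <- rd$subject_id[rows]
      D[who, who] <- d
    }
    diag(D) <- 0
    out[[m]] <- D
  }
  out
}

#' Bootstrap similarity radius for periodogram distances
#'
#' Draws \code{nSignals} bootstrap series by resampling pooled normalized
#' values onto the time grid, computes their periodograms, pairs consecutive
#' signals into \code{nSignals/2} disjoint pairs, and returns the stated
#' quantile (default 0.99) of the pairwise periodogram distances as the
#' similarity radius d_q: two subjects' periodograms within this radius are
#' closer than all but the most-dissimilar 1 percent of null pairs.
#'
#' @param pool numeric vector of pooled normalized values (cohort-wide).
#' @param times the full sampling grid.
#' @param nSignals number of bootstrap signals (default 50000).
#' @param level quantile level (default 0.99).
#' @param seed integer seed.
#' @return a \linkS4class{SimilarityRadius}.
#' @export
similarityRadius <- function(pool, times, nSignals = 50000, level = 0.99,
                             seed = NULL) {
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0L) .stopf("empty bootstrap pool")
  nSignals <- as.integer(nSignals)
  if (nSignals < 2L) .stopf("need at least 2 signals")
  sg <- spectralGrid(times)
  design <- lombScargleDesign(times, sg$frequencies)
  withSeed(seed, {
    Y <- matrix(sample(pool, nSignals * length(times), replace = TRUE),
                nrow = nSignals)
    P <- periodogramMatrix(Y, design)
    odd <- seq(1L, nSignals - 1L, by = 2L)
    d <- sqrt(rowSums((P[odd, , drop = FALSE] -
                         P[odd + 1L, , drop = FALSE])^2))
    new("SimilarityRadius",
        dq = as.numeric(stats::quantile(d, level, names = FALSE)),
        level = level, nSignals = nSignals,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  })
}

#' @rdname SimilarityRadius-class
#' @export
setMethod("similarityThreshold", "SimilarityRadius", function(x) x@dq)

setMethod("show", "SimilarityRadius", function(object) {
  cat("SimilarityRadius: d_q =", signif(object@dq, 6), "(level",
      object@level, "from", object@nSignals, "signals)\n")
})

#' Restricted adjacency: the cross-subject similarity network
#'
#' Binarizes every per-measurement distance matrix strictly below the
#' similarity radius (R_m = 1 iff D_m < d_q) and sums them into the integer
#' weighted adjacency A = sum_m R_m; pairs lacking a shared measurement
#' contribute nothing, and the diagonal is forced to zero. The edge weight
#' therefore counts the measurements on which two subjects show similar
#' temporal behavior; subjects sharing no measurement are kept as isolated
#' nodes.
#'
#' @param D distance matrices from [periodogramDistances()].
#' @param radius a \linkS4class{SimilarityRadius} or a plain numeric d_q.
#' @return a \linkS4class{CohortGraph} (communities not yet assigned).
#' @export
restrictedAdjacency <- function(D, radius) {
  dq <- if (is(radius, "SimilarityRadius")) radius@dq else as.numeric(radius)
  if (length(D) == 0L) .stopf("no distance matrices supplied")
  subjects <- rownames(D[[1L]])
  A <- matrix(0, length(subjects), length(subjects),
              dimnames = list(subjects, subjects))
  R <- list()
  for (m in names(D)) {
    Rm <- (D[[m]] < dq) * 1
    Rm[is.na(Rm)] <- 0
    diag(Rm) <- 0
    R[[m]] <- Rm
    A <- A + Rm
  }
  new("CohortGraph", adjacency = A, subjects = subjects, dq = dq,
      restricted = R, communities = integer(0),
      frequencies = matrix(0, 0, 0), k = NA_integer_, dim = NA_integer_,
      nRuns = NA_integer_)
}

#' @rdname CohortGraph-class
#' @export
setMethod("adjacency", "CohortGraph", function(x) x@adjacency)

#' @rdname CohortGraph-class
#' @export
setMethod("communityLabels", "CohortGraph", function(x) {
  if (!length(x@communities)) stop("run consensusCommunities() first")
  stats::setNames(x@communities, x@subjects)
})

#' @rdname CohortGraph-class
#' @export
setMethod("membershipFrequencies", "CohortGraph", function(x) x@frequencies)

#' @rdname CohortGraph-class
#' @export
setMethod("similarityThreshold", "CohortGraph", function(x) x@dq)

setMethod("show", "CohortGraph", function(object) {
  cat("CohortGraph:", length(object@subjects), "subjects,",
      sum(object@adjacency > 0) / 2, "edges, d_q =",
      signif(object@dq, 6), "\n")
  if (length(object@communities))
    cat("  consensus communities (k =", object@k, "):",
        paste(table(object@communities), collapse = "/"),
        "members\n")
})

# regularized spectral embedding of a (possibly disconnected) weighted
# adjacency: degree-normalize A + reg/n, take the top singular vectors
.spectralEmbedding <- function(A, dim = 2, reg = 0.01) {
  n <- nrow(A)
  shift <- reg * (mean(A) + 1e-8)
  Ar <- A + shift
  dg <- rowSums(Ar)
  L <- Ar / sqrt(outer(dg, dg))
  sv <- svd(L, nu = min(dim, n), nv = 0)
  emb <- sv$u * rep(sv$d[seq_len(min(dim, n))], each = n)
  if (dim > n) emb <- cbind(emb, matrix(0, n, dim - n))
  emb
}

# greedy label alignment: map run labels onto reference labels by descending
# contingency overlap
.alignLabels <- function(labels, ref, k) {
  C <- table(factor(labels, levels = seq_len(k)),
             factor(ref, levels = seq_len(k)))
  map <- integer(k)
  usedR <- usedC <- logical(k)
  for (step in seq_len(k)) {
    C2 <- C
    C2[usedR, ] <- -1
    C2[, usedC] <- -1
    ij <- which(C2 == max(C2), arr.ind = TRUE)[1L, ]
    map[ij[1L]] <- ij[2L]
    usedR[ij[1L]] <- TRUE
    usedC[ij[2L]] <- TRUE
  }
  map[labels]
}

#' Consensus community detection on the cohort graph
#'
#' Embeds the weighted adjacency in \code{dim} dimensions via a regularized
#' spectral (singular value) decomposition of the degree-normalized matrix,
#' then repeats k-means \code{nRuns} times with varied random
#' initializations. The number of communities is selected by the silhouette
#' method on the embedding (\code{kMode = "auto"}) or fixed
#' (\code{kMode = "fixed"}). Runs are combined through a co-association
#' matrix (fraction of runs in which two subjects co-cluster); the consensus
#' partition cuts an average-linkage tree of 1 - co-association at k, each
#' run's labels are aligned to it, and every subject receives its
#' highest-frequency membership, with the per-label frequencies retained.
#'
#' @param cg a \linkS4class{CohortGraph}.
#' @param dim embedding dimension (default 2).
#' @param kMode "auto" (silhouette) or "fixed".
#' @param k number of communities when \code{kMode = "fixed"}.
#' @param nRuns consensus repetitions (default 1000).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param kMax silhouette cap in auto mode.
#' @return the graph with \code{communities}, \code{frequencies}, \code{k},
#'   \code{dim} and \code{nRuns} filled in.
#' @export
consensusCommunities <- function(cg, dim = 2, kMode = c("auto", "fixed"),
                                 k = 5, nRuns = 1000, seed = NULL,
                                 kMax = 8) {
  stopifnot(is(cg, "CohortGraph"))
  kMode <- match.arg(kMode)
  n <- length(cg@subjects)
  if (n < 2L) .stopf("need at least 2 nodes")
  emb <- .spectralEmbedding(cg@adjacency, dim)
  nDistinct <- nrow(unique(round(emb, 10)))
  if (kMode == "auto") {
    de <- stats::dist(emb)
    ks <- seq_len(min(n - 1L, kMax, nDistinct))[-1L]
    if (!length(ks)) k <- 1L
    else {
      sil <- vapply(ks, function(kk) {
        cl <- withSeed(childSeed(seed, 999L + kk),
                       stats::kmeans(emb, centers = kk, nstart = 10)$cluster)
        if (length(unique(cl)) < 2L) return(-Inf)
        mean(cluster::silhouette(cl, de)[, "sil_width"])
      }, 0)
      k <- ks[which.max(sil)]
    }
  }
  k <- as.integer(k)
  if (k > n) .stopf("fewer nodes (%d) than communities (%d)", n, k)
  if (k > nDistinct)
    .stopf("only %d distinct embedding positions for %d communities",
           nDistinct, k)
  if (k == 1L) {
    cg@communities <- rep(1L, n)
    cg@frequencies <- matrix(1, n, 1, dimnames = list(cg@subjects, "C0"))
    cg@k <- 1L
    cg@dim <- as.integer(dim)
    cg@nRuns <- as.integer(nRuns)
    return(cg)
  }
  labels <- matrix(0L, n, nRuns)
  for (r in seq_len(nRuns)) {
    labels[, r] <- withSeed(childSeed(seed, r), {
      km <- NULL
      for (try in 1:10) {
        km <- tryCatch(stats::kmeans(emb, centers = k, nstart = 1),
                       error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km)) .stopf("k-means failed to initialize")
      km$cluster
    })
  }
  coassoc <- matrix(0, n, n)
  for (r in seq_len(nRuns))
    coassoc <- coassoc + outer(labels[, r], labels[, r], "==")
  coassoc <- coassoc / nRuns
  consensus <- if (k == 1L) rep(1L, n) else {
    hc <- stats::hclust(stats::as.dist(1 - coassoc), method = "average")
    unname(stats::cutree(hc, k))
  }
  freq <- matrix(0, n, k,
                 dimnames = list(cg@subjects, paste0("C", seq_len(k) - 1L)))
  for (r in seq_len(nRuns)) {
    al <- .alignLabels(labels[, r], consensus, k)
    freq[cbind(seq_len(n), al)] <- freq[cbind(seq_len(n), al)] + 1 / nRuns
  }
  final <- max.col(freq, ties.method = "first")
  cg@communities <- as.integer(final)
  cg@frequencies <- freq
  cg@k <- k
  cg@dim <- as.integer(dim)
  cg@nRuns <- as.integer(nRuns)
  cg
}

#' Export the cohort graph
#'
#' Writes the network as GraphML (node attributes: community and membership
#' frequencies; edge attribute: weight) and as an edge-list TSV, and a JSON
#' community report with per-community sizes and the measurements driving
#' the most intra-community edges.
#'
#' @param cg a \linkS4class{CohortGraph} with communities assigned.
#' @param dir output directory.
#' @param topMeasurements how many edge-driving measurements to report per
#'   community.
#' @return invisibly, the paths written.
#' @export
writeCohortGraph <- function(cg, dir, topMeasurements = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- igraph::graph_from_adjacency_matrix(cg@adjacency, mode = "undirected",
                                           weighted = TRUE)
  if (length(cg@communities)) {
    igraph::V(g)$community <- cg@communities - 1L
    for (j in seq_len(ncol(cg@frequencies)))
      g <- igraph::set_vertex_attr(g, paste0("freq_", colnames(cg@frequencies)[j]),
                                   value = cg@frequencies[, j])
  }
  paths <- file.path(dir, c("network.graphml", "edges.tsv",
                            "communities.json"))
  igraph::write_graph(g, paths[1], format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  utils::write.table(el, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  report <- list()
  if (length(cg@communities)) {
    for (ci in sort(unique(cg@communities))) {
      nodes <- which(cg@communities == ci)
      counts <- vapply(cg@restricted, function(Rm) {
        sum(Rm[nodes, nodes, drop = FALSE]) / 2
      }, 0)
      counts <- sort(counts[counts > 0], decreasing = TRUE)
      report[[paste0("community_", ci - 1L)]] <- list(
        size = length(nodes), subjects = cg@subjects[nodes],
        topMeasurements = as.list(utils::head(counts, topMeasurements)))
    }
  }
  jsonlite::write_json(report, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
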