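#' Silhouette-selected number of clusters for an agglomerative tree
#'
#' Cuts an average-linkage tree of the supplied dissimilarities at each
#' candidate k in \code{2..min(n - 1, kMax)} and returns the k maximizing
#' the mean silhouette width; ties go to the smallest k, and fewer than 3
#' items give k = 1 (the silhouette is undefined there).
#'
#' @param d a \code{dist} or symmetric zero-diagonal matrix of
#'   dissimilarities.
#' @param kMax cap on the number of clusters (default 8).
#' @return list with the chosen \code{k}, the integer \code{labels} from
#'   cutting the tree at k, and the mean silhouette per candidate k.
#' @export
chooseKSilhouette <- function(d, kMax = 8) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L || max(d) < 1e-12)   # too few items, or all items coincide
    return(list(k = 1L, labels = rep(1L, max(n, 0L)), silhouettes = NULL))
  hc <- stats::hclust(d, method = "average")
  ks <- 2:min(n - 1L, kMax)
  sil <- vapply(ks, function(k) {
    mean(cluster::silhouette(stats::cutree(hc, k), d)[, "sil_width"])
  }, 0)
  k <- ks[which.max(sil)]   # which.max takes the first maximum: smallest k
  list(k = k, labels = unname(stats::cutree(hc, k)),
       silhouettes = stats::setNames(sil, ks))
}

# correlation dissimilarity between rows, robust to zero-variance rows
.corDist <- function(M) {
  v <- apply(M, 1, stats::sd)
  C <- suppressWarnings(stats::cor(t(M)))
  flat <- v < 1e-12
  if (any(flat)) {
    # zero-variance profiles: identical rows are at distance 0, others at 1
    for (i in which(flat)) {
      same <- vapply(seq_len(nrow(M)),
                     function(j) isTRUE(all.equal(M[i, ], M[j, ])), TRUE)
      C[i, ] <- ifelse(same, 1, 0)
      C[, i] <- C[i, ]
    }
  }
  C[!is.finite(C)] <- 0
  d <- 1 - C
  diag(d) <- 0
  stats::as.dist(d)
}

#' First-level (group) clustering of autocorrelation profiles
#'
#' Agglomerative (average linkage) clustering of the series of one trend
#' class within one subject, using the correlation-based dissimilarity
#' \code{1 - Pearson r} between autocorrelation profiles; the number of
#' groups is chosen by the silhouette method.
#'
#' @param profiles matrix of autocorrelation profiles, one row per series
#'   (lags 0..L).
#' @param kMax silhouette cap (default 8).
#' @return integer group label per row, numbered in order of appearance.
#' @export
clusterGroups <- function(profiles, kMax = 8) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n == 1L) return(1L)
  chooseKSilhouette(.corDist(profiles), kMax)$labels
}

#' Second-level (subgroup) clustering of normalized series
#'
#' Agglomerative (average linkage) clustering of the members of one group,
#' using Euclidean dissimilarity between the normalized series; the number
#' of subgroups is chosen by the silhouette method. Missing bins contribute
#' nothing to the distances (pairwise-complete Euclidean distance).
#'
#' @param members matrix of normalized series, one row per member.
#' @param kMax silhouette cap (default 8).
#' @return integer subgroup label per row.
#' @export
clusterSubgroups <- function(members, kMax = 8) {
  members <- as.matrix(members)
  n <- nrow(members)
  if (n == 1L) return(1L)
  chooseKSilhouette(stats::dist(members), kMax)$labels
}

#' Two-level trend clustering for every subject and class
#'
#' Within each subject, takes the significant series of each trend class and
#' assigns nested group (G, by autocorrelation profile) and subgroup (S, by
#' normalized series) labels. Groups with a single member skip the
#' silhouette and form one subgroup.
#'
#' @param me a classified \linkS4class{MissionExperiment}
#'   (see [classifyCohort()]).
#' @param kMax silhouette cap for both levels.
#' @param significantOnly cluster only BH-significant series (default TRUE).
#' @return the experiment with integer \code{group} and \code{subgroup}
#'   columns in \code{rowData} (NA outside the clustered set).
#' @export
clusterTrends <- function(me, kMax = 8, significantOnly = TRUE) {
  stopifnot(is(me, "MissionExperiment"))
  rd <- rowData(me)
  if (!"trendClass" %in% colnames(rd))
    .stopf("run classifyCohort() first")
  Q <- normalizedMatrix(me)
  G <- rep(NA_integer_, nrow(me))
  S <- rep(NA_integer_, nrow(me))
  inSet <- !is.na(rd$trendClass) & rd$trendClass != "NoTrend"
  if (significantOnly) inSet <- inSet & rd$significant
  for (s in unique(rd$subject_id)) {
    for (cl in unique(rd$trendClass[inSet & rd$subject_id == s])) {
      rows <- which(inSet & rd$subject_id == s & rd$trendClass == cl)
      g <- clusterGroups(rd$acf[rows, , drop = FALSE], kMax)
      G[rows] <- g
      for (gi in unique(g)) {
        sub <- rows[g == gi]
        S[sub] <- clusterSubgroups(Q[sub, , drop = FALSE], kMax)
      }
    }
  }
  rd$group <- G
  rd$subgroup <- S
  rowData(me) <- rd
  me
}

#' Write per-subject trend clusters as TSV
#'
#' @param me a clustered \linkS4class{MissionExperiment}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeClusters <- function(me, path) {
  rd <- rowData(me)
  keep <- !is.na(rd$group)
  out <- data.frame(subject_id = rd$subject_id,
                    measurement_id = rd$measurement_id,
                    class = rd$trendClass, G = rd$group,
                    S = rd$subgroup)[keep, ]
  out <- out[order(out$subject_id, out$class, out$G, out$S,
                   out$measurement_id), ]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
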