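# small classified cohort shared by the network tests
networkFixture <- function(seed = 71, nSubjects = 8, noiseSd = 1) {
  sim <- simulateCohort(nSubjects = nSubjects, nMeasurements = 12,
                        nBlocks = 2, plantedFraction = 0.5, amplitude = 15,
                        noiseSd = noiseSd, dropout = 0, seed = seed)
  list(me = computeSpectra(preprocessCohort(sim$records)), sim = sim)
}

test_that("periodogram distances match a brute-force oracle", {
  fx <- networkFixture()
  D <- periodogramDistances(fx$me)
  rd <- rowData(fx$me)
  for (m in names(D)[1:4]) {
    rows <- which(rd$measurement_id == m & rd$kept & !rd$degenerate)
    for (i in rows) for (j in rows) {
      want <- sqrt(sum((rd$periodogram[i, ] - rd$periodogram[j, ])^2))
      expect_equal(D[[m]][rd$subject_id[i], rd$subject_id[j]], want,
                   tolerance = 1e-10)
    }
    expect_equal(D[[m]], t(D[[m]]))
    expect_true(all(diag(D[[m]]) == 0))
    expect_true(all(D[[m]][!is.na(D[[m]])] >= 0))
  }
})

test_that("identical periodograms are at distance zero", {
  fx <- networkFixture(noiseSd = 0)   # planted shapes identical within block
  D <- periodogramDistances(fx$me)
  rd <- rowData(fx$me)
  blocks <- fx$sim$truth$blocks
  m <- fx$sim$truth$assignments$measurement_id[1]
  subj <- rd$subject_id[rd$measurement_id == m & rd$kept & !rd$degenerate]
  sameBlock <- outer(blocks[subj], blocks[subj], "==")
  expect_true(all(D[[m]][subj, subj][sameBlock] == 0))
})

test_that("the similarity radius is reproducible and level-monotone", {
  set.seed(72)
  pool <- rnorm(500)
  a <- similarityRadius(pool, 0:7, nSignals = 2000, seed = 5)
  b <- similarityRadius(pool, 0:7, nSignals = 2000, seed = 5)
  expect_equal(similarityThreshold(a), similarityThreshold(b))
  mid <- similarityRadius(pool, 0:7, nSignals = 2000, level = 0.5, seed = 5)
  expect_gte(similarityThreshold(a), similarityThreshold(mid))
  expect_error(similarityRadius(numeric(0), 0:7), "empty")
})

test_that("restricted adjacency binarizes strictly below the radius", {
  D <- list(m1 = matrix(c(0, 0.5, 0.5, 0), 2,
                        dimnames = list(c("a", "b"), c("a", "b"))),
            m2 = matrix(c(0, 1.0, 1.0, 0), 2,
                        dimnames = list(c("a", "b"), c("a", "b"))),
            m3 = matrix(c(0, 0.9, 0.9, 0), 2,
                        dimnames = list(c("a", "b"), c("a", "b"))))
  cg <- restrictedAdjacency(D, 1.0)
  expect_equal(adjacency(cg)["a", "b"], 2)  # 0.5 and 0.9 in, 1.0 out (strict)
  # undefined pairs contribute nothing; fully-missing subjects are isolated
  D$m1[] <- NA; D$m2[] <- NA; D$m3[] <- NA
  cg2 <- restrictedAdjacency(D, 1.0)
  expect_true(all(adjacency(cg2) == 0))
})

test_that("edge weights count similar measurements exactly", {
  fx <- networkFixture()
  D <- periodogramDistances(fx$me)
  dq <- 0.3
  cg <- restrictedAdjacency(D, dq)
  A <- adjacency(cg)
  subjects <- cg@subjects
  for (x in subjects[1:4]) for (y in subjects[5:8]) {
    want <- sum(vapply(D, function(d) {
      v <- d[x, y]
      !is.na(v) && v < dq && x != y
    }, TRUE))
    expect_equal(A[x, y], want)
  }
  expect_true(all(A <= length(D)))
  expect_true(all(A == round(A)))
})

test_that("noise-free two-block cohorts are recovered exactly", {
  skip_if_not_installed("mclust")
  fx <- networkFixture(noiseSd = 0)
  Q <- normalizedMatrix(fx$me)
  radius <- similarityRadius(Q[is.finite(Q)], 0:7, nSignals = 2000, seed = 7)
  cg <- restrictedAdjacency(periodogramDistances(fx$me), radius)
  cg <- consensusCommunities(cg, kMode = "auto", nRuns = 100, seed = 11)
  ari <- mclust::adjustedRandIndex(communityLabels(cg),
                                   fx$sim$truth$blocks[cg@subjects])
  expect_equal(ari, 1)
})

test_that("consensus labeling is deterministic and permutation-invariant", {
  skip_if_not_installed("mclust")
  fx <- networkFixture(noiseSd = 0)   # unambiguous two-block structure
  Q <- normalizedMatrix(fx$me)
  radius <- similarityRadius(Q[is.finite(Q)], 0:7, nSignals = 2000, seed = 7)
  D <- periodogramDistances(fx$me)
  cg <- restrictedAdjacency(D, radius)
  a <- consensusCommunities(cg, kMode = "fixed", k = 2, nRuns = 50, seed = 3)
  b <- consensusCommunities(cg, kMode = "fixed", k = 2, nRuns = 50, seed = 3)
  expect_identical(communityLabels(a), communityLabels(b))
  expect_identical(membershipFrequencies(a), membershipFrequencies(b))
  # node relabeling: permute the roster, expect the same partition
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  Dp <- lapply(D, function(d) d[perm, perm])
  cgp <- consensusCommunities(restrictedAdjacency(Dp, radius),
                              kMode = "fixed", k = 2, nRuns = 50, seed = 3)
  ari <- mclust::adjustedRandIndex(communityLabels(a)[cgp@subjects],
                                   communityLabels(cgp))
  expect_equal(ari, 1)
})

test_that("membership frequencies sum to one and fixed k bounds communities", {
  fx <- networkFixture(nSubjects = 8)
  Q <- normalizedMatrix(fx$me)
  radius <- similarityRadius(Q[is.finite(Q)], 0:7, nSignals = 2000, seed = 7)
  cg <- restrictedAdjacency(periodogramDistances(fx$me), radius)
  cg5 <- consensusCommunities(cg, kMode = "fixed", k = 5, nRuns = 50,
                              seed = 9)
  expect_true(all(abs(rowSums(membershipFrequencies(cg5)) - 1) < 1e-9))
  expect_lte(length(unique(communityLabels(cg5))), 5L)
  expect_equal(unname(communityLabels(cg5)),
               unname(apply(membershipFrequencies(cg5), 1, which.max)))
  expect_error(consensusCommunities(cg, kMode = "fixed", k = 50), "nodes")
})

test_that("graph exports are written and round-trip the topology", {
  fx <- networkFixture()
  Q <- normalizedMatrix(fx$me)
  radius <- similarityRadius(Q[is.finite(Q)], 0:7, nSignals = 2000, seed = 7)
  cg <- restrictedAdjacency(periodogramDistances(fx$me), radius)
  cg <- consensusCommunities(cg, kMode = "fixed", k = 2, nRuns = 20, seed = 1)
  dir <- withr::local_tempdir()
  paths <- writeCohortGraph(cg, dir)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[1], format = "graphml")
  expect_equal(igraph::vcount(g), length(cg@subjects))
  rep <- jsonlite::read_json(paths[3])
  expect_equal(sum(vapply(rep, function(x) x$size, 0)),
               length(cg@subjects))
})
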