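test_that("median group signals are missing-aware medians", {
  q <- c(0, 0, 1, 2, 2, 1, 0, 0)
  expect_equal(medianGroupSignal(q), q)
  M <- rbind(c(1, NA, 3), c(2, NA, 4), c(3, NA, 5))
  expect_equal(medianGroupSignal(M), c(2, NA, 4))
  expect_error(medianGroupSignal(matrix(0, 0, 8)), "empty")
})

test_that("a strictly convex series gives a complete visibility graph", {
  t <- 0:7
  y <- (t - 3.5)^2
  A <- adjacency(naturalVisibilityGraph(y, t))
  expect_true(all(A[upper.tri(A)]))
})

test_that("a constant series gives a path graph under strict visibility", {
  A <- adjacency(naturalVisibilityGraph(rep(1, 8)))
  expected <- matrix(FALSE, 8, 8)
  expected[cbind(1:7, 2:8)] <- TRUE
  expect_equal(A, expected | t(expected))
})

test_that("adjacent timepoints are always connected", {
  set.seed(61)
  for (r in 1:20) {
    y <- rnorm(8)
    A <- adjacency(naturalVisibilityGraph(y, gridDays(missionGrid())))
    expect_true(all(A[cbind(1:7, 2:8)]))
    expect_true(isSymmetric(A))
    expect_false(any(diag(A)))
  }
  expect_error(naturalVisibilityGraph(c(1, NA, NA, NA)), "2 present")
})

test_that("missing bins are dropped and vertex indices preserved", {
  y <- c(0, 1, NA, 3, 2, NA, 1, 0)
  vg <- naturalVisibilityGraph(y, 0:7)
  expect_equal(vg@vertices, c(0L, 1L, 3L, 4L, 6L, 7L))
  expect_equal(length(vg@values), 6L)
})

test_that("shortest paths agree with a breadth-first-search oracle", {
  set.seed(62)
  for (r in 1:50) {
    y <- rnorm(sample(4:8, 1))
    A <- adjacency(naturalVisibilityGraph(y))
    got <- missionTrends:::.shortestPath(A)
    want <- oracleBfsPath(A)
    expect_equal(length(got), length(want))
    if (oracleCountShortest(A) == 1L) expect_equal(got, want)
  }
})

test_that("a complete graph yields a direct path and one community", {
  t <- 0:7
  vg <- naturalVisibilityGraph((t - 3.5)^2, t)
  vc <- visibilityCommunities(vg)
  expect_equal(vc$shortestPath, c(0L, 7L))
  expect_equal(length(vc$communities), 1L)
  expect_equal(vc$communities[[1]], 0:7)
})

test_that("two plateaus joined by a step split into two contiguous communities", {
  vc <- visibilityCommunities(naturalVisibilityGraph(c(1, 1, 1, 1, 0, 0, 0, 0)))
  expect_equal(length(vc$communities), 2L)
  # contiguity and coverage
  all_v <- sort(unlist(vc$communities))
  expect_equal(all_v, 0:7)
  for (comm in vc$communities)
    expect_equal(comm, seq(min(comm), max(comm)))
  # the split falls at the plateau boundary region
  expect_true(max(vc$communities[[1]]) %in% 2:4)
})

test_that("community partitions always cover every vertex exactly once", {
  set.seed(63)
  for (r in 1:30) {
    y <- rnorm(8)
    vc <- visibilityCommunities(naturalVisibilityGraph(y))
    expect_equal(sort(unlist(vc$communities)), 0:7)
    expect_equal(vc$shortestPath[1], 0L)
    expect_equal(vc$shortestPath[length(vc$shortestPath)], 7L)
  }
})

test_that("time reversal reverses the community partition", {
  # the visibility criterion is reversal-symmetric; the only asymmetry the
  # deterministic tie rules (lexicographic path choice, earlier-community
  # attachment) can introduce is a boundary-vertex shift, so on unique-path
  # inputs the reversed partition must match up to one vertex per cut
  set.seed(64)
  tested <- 0
  for (r in 1:60) {
    y <- rnorm(8)
    A <- adjacency(naturalVisibilityGraph(y))
    Ar <- adjacency(naturalVisibilityGraph(rev(y)))
    if (oracleCountShortest(A) != 1L || oracleCountShortest(Ar) != 1L) next
    tested <- tested + 1
    f <- visibilityCommunities(naturalVisibilityGraph(y))
    b <- visibilityCommunities(naturalVisibilityGraph(rev(y)))
    # reversed shortest path maps onto the forward one exactly
    expect_equal(sort(7 - b$shortestPath), sort(f$shortestPath))
    cutsF <- vapply(f$communities, max, 0L)
    cutsF <- cutsF[-length(cutsF)]
    cutsB <- vapply(b$communities, max, 0L)
    cutsB <- cutsB[-length(cutsB)]
    mapped <- sort(6 - cutsB)
    expect_lte(abs(length(cutsF) - length(mapped)), 1L)
    if (length(mapped) == length(cutsF) && length(cutsF))
      expect_true(all(abs(mapped - cutsF) <= 1))
  }
  expect_gt(tested, 10)
})

test_that("visibility summaries are produced for every clustered cell", {
  sim <- simulateCohort(nSubjects = 2, nMeasurements = 20, nBlocks = 1,
                        plantedFraction = 0.4, amplitude = 15, noiseSd = 1,
                        seed = 65)
  me <- clusterTrends(classifyCohort(preprocessCohort(sim$records),
                                     nBoot = 2000, seed = 6))
  vs <- visibilitySummary(me)
  rd <- rowData(me)
  expect_equal(sort(names(vs)), sort(unique(rd$subject_id[rd$significant])))
  path <- withr::local_tempfile(fileext = ".json")
  writeVisibilityJSON(vs, path)
  expect_true(file.exists(path))
  back <- jsonlite::read_json(path)
  expect_equal(sort(names(back)), sort(names(vs)))
})
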