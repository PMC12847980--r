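test_that("edge contributions match their closed forms", {
  expect_equal(edgeContribution("H", 1, 3), 0.5)
  expect_equal(edgeContribution("HZ", 2, 3), 25)
  expect_equal(edgeContribution("ABC", 2, 2), 1 / sqrt(2))
  expect_equal(edgeContribution("GA", 1, 3), 2 * sqrt(3) / 4)
  expect_equal(edgeContribution("SS", 2, 2), 1)
  expect_equal(edgeContribution("SS", 2, 2, ssVariant = "inverseSquare"),
               1 / 16)
  expect_error(edgeContribution("WIENER", 1, 2))
  expect_error(edgeContribution("RI", 0, 2), ">= 1")
})

test_that("computeIndex sums count-weighted contributions", {
  lin <- partitionFromCounts(c("1,2" = 1, "1,3" = 2, "2,2" = 15, "2,3" = 1))
  expect_equal(computeIndex("M1", lin), 76)
  ser <- drugPartition("serine")
  expect_equal(computeIndex("RI", ser), 3.1807, tolerance = 1e-4)
  cys <- drugPartition("cystine")
  expect_equal(computeIndex("ABC", cys), 9.7678, tolerance = 1e-4)
  # each (2,2) edge of a cycle contributes exactly 1 to GA
  expect_equal(computeIndex("GA", partitionFromCounts(c("2,2" = 11))), 11)
  expect_error(computeIndex("XX", lin))
})

test_that("vertex forms of M1 and F match the glycine example", {
  expect_equal(computeIndexVertexForm("M1", c(1, 2, 3, 1, 1)), 16)
  expect_equal(computeIndexVertexForm("F", c(1, 2, 3, 1, 1)), 38)
  expect_equal(computeIndexVertexForm("M1", c(1, 1)), 2)
  expect_error(computeIndexVertexForm("M2", c(1, 2)))
})

test_that("the two Schultz-second variants disagree as documented", {
  gly <- drugPartition("glycine")
  # by-hand evaluation of the reciprocal-square form: 1/9 + 2/16 + 1/25
  expect_equal(computeIndex("SS", gly, ssVariant = "inverseSquare"),
               1 / 9 + 2 / 16 + 1 / 25)
  expect_equal(computeIndex("SS", gly), 3.6440, tolerance = 1e-4)
  expect_equal(computeIndex("SS", partitionFromCounts(c("2,2" = 9))), 9)
})

test_that("computeAllIndices returns all ten values, positive", {
  tyr <- drugPartition("tyrosine")
  v <- computeAllIndices(tyr)
  expect_named(v, indexIds())
  expect_true(all(v > 0))
  expect_equal(unname(v[c("M1", "M2", "F", "HZ")]), c(68, 75, 190, 340))
  expect_equal(unname(v["H"]), 5.9190, tolerance = 1e-4)
  expect_equal(unname(v["SS"]), 14.3282, tolerance = 1e-4)
  # integer-valued indices are integers to machine precision
  expect_true(all(v[c("M1", "M2", "F", "HZ")] == round(v[c("M1", "M2",
                                                           "F", "HZ")])))
  nag <- computeAllIndices(drugPartition("N-acetylglucosamine"))
  expect_equal(unname(nag[c("SS", "H")]), c(15.0640, 6.7000),
               tolerance = 1e-4)
})

test_that("partition route equals brute-force edge loop on random graphs", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(3:18, 1)
    g <- randomChemlikeGraph(n, ringEdges = if (n > 5) sample(0:2, 1) else 0,
                             seed = 200 + rep)
    p <- edgeDegreePartition(g)
    for (id in indexIds())
      expect_equal(computeIndex(id, p), bruteIndex(id, g), tolerance = 1e-12)
    expect_equal(computeIndex("SS", p, ssVariant = "inverseSquare"),
                 bruteIndex("SS", g, "inverseSquare"), tolerance = 1e-12)
  }
})

test_that("vertex and edge forms of M1 and F agree on random graphs", {
  set.seed(12)
  for (rep in 1:15) {
    g <- randomChemlikeGraph(sample(2:20, 1), seed = 300 + rep)
    p <- edgeDegreePartition(g)
    deg <- vertexDegrees(g)
    expect_equal(computeIndex("M1", p), computeIndexVertexForm("M1", deg))
    expect_equal(computeIndex("F", p), computeIndexVertexForm("F", deg))
  }
})

test_that("indices are additive over disjoint unions of partitions", {
  p1 <- drugPartition("serine")
  p2 <- drugPartition("tyrosine")
  merged <- partitionFromCounts(c(pairCounts(p1), pairCounts(p2)))
  for (id in indexIds())
    expect_equal(computeIndex(id, merged),
                 computeIndex(id, p1) + computeIndex(id, p2))
})

test_that("cycle closed forms hold", {
  for (n in c(3, 8, 50)) {
    v <- computeAllIndices(edgeDegreePartition(buildGraph(cycleEdges(n))))
    expect_equal(unname(v), c(4 * n, 4 * n, n / 2, 8 * n, n, n / sqrt(2),
                              n / 2, n / 2, n, 16 * n))
  }
})

test_that("recoverEdgeContributions identifies an edge-additive formula", {
  # synthetic check: generate partitions, tabulate a known index, recover it
  set.seed(13)
  parts <- lapply(1:12, function(i)
    edgeDegreePartition(randomChemlikeGraph(sample(4:16, 1),
                                            ringEdges = sample(0:1, 1))))
  vals <- vapply(parts, function(p) computeIndex("GA", p), numeric(1))
  f <- recoverEdgeContributions(parts, vals)
  est <- !is.na(f)
  ab <- vapply(strsplit(names(f), ","), as.numeric, numeric(2))
  expect_equal(unname(f[est]),
               unname(2 * sqrt(ab[1, est] * ab[2, est]) /
                        (ab[1, est] + ab[2, est])),
               tolerance = 1e-8)
  # a lone cycle determines exactly one contribution
  f1 <- recoverEdgeContributions(list(partitionFromCounts(c("2,2" = 6))), 6)
  expect_equal(unname(f1["2,2"]), 1)
})

test_that("index table reproduces the bundled reference values", {
  tab <- indexTable(drugPartitions(), digits = 4)
  expect_equal(tab, referenceIndices(), tolerance = 1e-12)
})
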