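glycineEdges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5))

test_that("buildGraph validates and computes degrees", {
  g <- buildGraph(glycineEdges)
  expect_s4_class(g, "MolecularGraph")
  deg <- vertexDegrees(g)
  expect_identical(sort(unname(deg)), c(1L, 1L, 1L, 2L, 3L))
  expect_identical(sum(deg), 2L * nrow(bondMatrix(g)))

  expect_identical(unname(vertexDegrees(buildGraph(rbind(c("a", "b"))))),
                   c(1L, 1L))
  cyc <- buildGraph(cycleEdges(6))
  expect_true(all(vertexDegrees(cyc) == 2L))
  star <- buildGraph(cbind("hub", paste0("leaf", 1:4)))
  expect_identical(unname(sort(vertexDegrees(star), decreasing = TRUE)[1]), 4L)
})

test_that("buildGraph rejects malformed molecules", {
  expect_error(buildGraph(rbind(c(1, 1))), "self-loop")
  expect_error(buildGraph(rbind(c(1, 2), c(2, 1))), "duplicate edge")
  expect_error(buildGraph(rbind(c(1, 2), c(3, 4))), "disconnected")
  # components are named in the error
  expect_error(buildGraph(rbind(c(1, 2), c(3, 4))), "\\{1,2\\}")
  expect_error(buildGraph(list()), "empty")
  expect_warning(buildGraph(cbind("c", paste0("x", 1:5))), "degree above 4")
})

test_that("edge-degree partition tallies min/max degree pairs", {
  p <- edgeDegreePartition(buildGraph(glycineEdges))
  expect_identical(pairCounts(p), c("1,2" = 1L, "1,3" = 2L, "2,3" = 1L))
  expect_identical(edgeTotal(p), 4L)

  expect_identical(pairCounts(edgeDegreePartition(buildGraph(cycleEdges(7)))),
                   c("2,2" = 7L))
  path4 <- buildGraph(rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_identical(pairCounts(edgeDegreePartition(path4)),
                   c("1,2" = 2L, "2,2" = 1L))
})

test_that("partitionFromCounts canonicalizes and validates", {
  p <- partitionFromCounts(c("1,2" = 1, "1,3" = 2, "2,2" = 15, "2,3" = 1))
  expect_identical(edgeTotal(p), 19L)
  # reversed orientation is folded in
  expect_identical(pairCounts(partitionFromCounts(c("3,1" = 2))),
                   c("1,3" = 2L))
  expect_identical(
    pairCounts(partitionFromCounts(c("3,1" = 1, "1,3" = 2))),
    c("1,3" = 3L))
  # zero counts dropped, negative / fractional / bad degrees rejected
  expect_identical(edgeTotal(partitionFromCounts(c("1,2" = 1, "3,3" = 0))), 1L)
  expect_error(partitionFromCounts(c("1,2" = -1)), "nonnegative")
  expect_error(partitionFromCounts(c("0,2" = 1)), ">= 1")
  expect_error(partitionFromCounts(numeric()), "non-empty")
  expect_error(partitionFromCounts(c("1,2" = 0)), "empty")
})

test_that("readEdgeList parses the text dialect", {
  f <- withr::local_tempfile(fileext = ".edges")
  writeLines(c("# glycine backbone", "N1 C2", "C2 C3", "", "C3 O4  # =O",
               "C3 O5"), f)
  g <- readEdgeList(f)
  expect_identical(sort(unname(vertexDegrees(g))), c(1L, 1L, 1L, 2L, 3L))
  writeLines("N1 C2 C3", f)
  expect_error(readEdgeList(f), "line 1")
})

test_that("partition is invariant under vertex relabeling", {
  set.seed(42)
  for (seed in 1:20) {
    n <- sample(5:15, 1)
    g <- randomChemlikeGraph(n, ringEdges = sample(0:min(2, n - 4), 1),
                             seed = seed)
    e <- bondMatrix(g)
    perm <- sample(length(unique(as.vector(e))))
    names(perm) <- unique(as.vector(e))
    relab <- matrix(paste0("w", perm[e]), ncol = 2)
    expect_identical(pairCounts(edgeDegreePartition(buildGraph(relab))),
                     pairCounts(edgeDegreePartition(g)))
  }
})

test_that("handshake and round-trip identities hold on random graphs", {
  set.seed(43)
  for (seed in 1:25) {
    n <- sample(2:20, 1)
    g <- randomChemlikeGraph(n, ringEdges = if (n > 5) sample(0:2, 1) else 0,
                             seed = 100 + seed)
    p <- edgeDegreePartition(g)
    expect_identical(sum(vertexDegrees(g)), 2L * edgeTotal(p))
    expect_identical(edgeTotal(p), nrow(bondMatrix(g)))
  }
})
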