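# Shorten one vertical (DV-oriented) junction below threshold and return
# the modified mesh plus the edge's incident cells.
shortenOneEdge <- function(mesh, len = 0.05, params = vertexModelParams()) {
  eg <- vertexGBE:::.edgeGeometry(mesh)
  e <- which(abs(eg$vec[, 1]) < 1e-9)[1]
  a <- meshEdges(mesh)[e, 1]; b <- meshEdges(mesh)[e, 2]
  mid <- mesh@vertices[a, ] +
    0.5 * vertexGBE:::.minImage(mesh@vertices[b, ] - mesh@vertices[a, ], mesh@box)
  dir <- vertexGBE:::.minImage(mesh@vertices[b, ] - mesh@vertices[a, ], mesh@box)
  dir <- dir / sqrt(sum(dir^2))
  mesh@vertices[a, ] <- (mid - dir * len / 2) %% mesh@box
  mesh@vertices[b, ] <- (mid + dir * len / 2) %% mesh@box
  list(mesh = mesh, cells = meshEdgeCells(mesh)[e, ])
}

test_that("a short junction collapses into a rank-4 vertex (protorosette)", {
  p <- vertexModelParams()
  sh <- shortenOneEdge(hexTissue(6, 6))
  res <- attemptEdgeMerges(sh$mesh, p)
  expect_equal(nrow(res$records), 1)
  m2 <- res$mesh
  expect_equal(nCells(m2), 36)                     # cell count unchanged
  expect_equal(nVertices(m2) - nEdges(m2) + nCells(m2), 0)
  expect_equal(sum(vertexRank(m2) == 4), 1)
  expect_equal(unname(censusVertexRanks(m2)$counts[["4"]]), 4)  # 4 cells share it
  expect_true(validObject(m2))
  # the losing pair is recorded for the later T1 completion
  expect_setequal(c(m2@mergeInfo$losingA, m2@mergeInfo$losingB), sh$cells)
})

test_that("merging into an existing rank-4 vertex makes a rank-5 rosette", {
  p <- vertexModelParams()
  sh <- shortenOneEdge(hexTissue(6, 6))
  m2 <- attemptEdgeMerges(sh$mesh, p)$mesh
  v4 <- which(vertexRank(m2) == 4)
  # shorten an edge attached to the rank-4 vertex
  e2 <- which(m2@edges[, 1] == v4 | m2@edges[, 2] == v4)[1]
  a <- m2@edges[e2, 1]; b <- m2@edges[e2, 2]
  d <- vertexGBE:::.minImage(m2@vertices[b, ] - m2@vertices[a, ], m2@box)
  keepEnd <- if (a == v4) a else b
  moveEnd <- if (a == v4) b else a
  m2@vertices[moveEnd, ] <- (m2@vertices[keepEnd, ] +
    0.4 * p@lMerge * d / sqrt(sum(d^2)) * (if (a == v4) 1 else -1)) %% m2@box
  res <- attemptEdgeMerges(m2, p)
  expect_gte(nrow(res$records), 1)
  expect_equal(max(vertexRank(res$mesh)), 5)
  expect_equal(nVertices(res$mesh) - nEdges(res$mesh) + nCells(res$mesh), 0)
})

test_that("meshes with no short edges are returned unchanged", {
  p <- vertexModelParams()
  mesh <- hexTissue(4, 4)
  res <- attemptEdgeMerges(mesh, p)
  expect_equal(nrow(res$records), 0)
  expect_identical(res$mesh@vertices, mesh@vertices)
  expect_identical(res$mesh@edges, mesh@edges)
})

test_that("rank-4 resolution completes the T1: losing pair separated, gaining pair joined", {
  p <- vertexModelParams(p4Rate = 1e9)  # resolve with certainty
  sh <- shortenOneEdge(hexTissue(6, 6))
  m2 <- attemptEdgeMerges(sh$mesh, p)$mesh
  set.seed(1)
  res <- resolveVertices(m2, p)
  expect_equal(nrow(res$records), 1)
  m3 <- res$mesh
  expect_true(all(vertexRank(m3) == 3))
  adjacent <- function(m, x, y) any(
    (m@edgeCells[, 1] == x & m@edgeCells[, 2] == y) |
    (m@edgeCells[, 1] == y & m@edgeCells[, 2] == x))
  expect_false(adjacent(m3, sh$cells[1], sh$cells[2]))
  expect_true(adjacent(m3, res$records$cellA, res$records$cellB))
  # new junction has length lNew
  newEdge <- nrow(m3@edges)
  d <- vertexGBE:::.minImage(m3@vertices[m3@edges[newEdge, 2], ] -
                             m3@vertices[m3@edges[newEdge, 1], ], m3@box)
  expect_equal(sqrt(sum(d^2)), p@lNew, tolerance = 1e-12)
  expect_true(validObject(m3))
})

test_that("rank-5+ vertices never resolve at rate zero", {
  p <- vertexModelParams(p4Rate = 0, p5plusRate = 0)
  sh <- shortenOneEdge(hexTissue(6, 6))
  m2 <- attemptEdgeMerges(sh$mesh, p)$mesh
  set.seed(2)
  for (i in 1:50) {
    res <- resolveVertices(m2, p)
    expect_equal(nrow(res$records), 0)
  }
  expect_equal(sum(vertexRank(res$mesh) == 4), 1)
})

test_that("per-step resolution probability follows 1 - exp(-rate * dt)", {
  # rate-to-probability convention, checked against an empirical frequency
  p <- vertexModelParams(p4Rate = 1, dt = 0.01)
  expect_equal(vertexGBE:::.ratePerStep(1, 0.01), 1 - exp(-0.01))
  sh <- shortenOneEdge(hexTissue(4, 4))
  m2 <- attemptEdgeMerges(sh$mesh, p)$mesh
  pStep <- 1 - exp(-p@p4Rate * p@dt)
  nTrial <- 20000
  set.seed(7)
  hits <- 0L
  for (i in seq_len(nTrial))
    hits <- hits + (nrow(resolveVertices(m2, p)$records) > 0)
  se <- sqrt(pStep * (1 - pStep) / nTrial)
  expect_lt(abs(hits / nTrial - pStep), 3 * se)
})

test_that("cell class census partitions the tissue", {
  mesh <- hexTissue(6, 6)
  cen <- censusVertexRanks(mesh)
  expect_equal(unname(cen$counts[["3"]]), 36)
  expect_equal(sum(cen$counts), nCells(mesh))
  sh <- shortenOneEdge(mesh)
  m2 <- attemptEdgeMerges(sh$mesh, vertexModelParams())$mesh
  cen2 <- censusVertexRanks(m2)
  expect_equal(unname(cen2$counts[["4"]]), 4)
  expect_equal(sum(cen2$counts), 36)
})
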