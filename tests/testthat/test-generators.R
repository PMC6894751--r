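test_that("zero gradient gives static tracks", {
  tr <- generateAffineFlowTracks(matrix(0, 2, 2), nFrames = 4,
                                 nRows = 3, nCols = 3)
  cl <- trackCells(tr)
  f0 <- cl[cl$frame == 0, ]
  for (f in 1:3) {
    ff <- cl[cl$frame == f, ]
    expect_identical(ff$x, f0$x)
    expect_identical(ff$outline, f0$outline)
  }
})

test_that("pure-shear flow stretches centroid separations by (1 + G dt) per step", {
  G <- diag(c(0.02, -0.02))
  tr <- generateAffineFlowTracks(G, nFrames = 6, nRows = 3, nCols = 4)
  cl <- trackCells(tr)
  dtMin <- frameInterval(tr) / 60
  x0 <- cl$x[cl$frame == 0]
  for (f in 1:5) {
    xf <- cl$x[cl$frame == f]
    sep0 <- diff(range(x0)); sepf <- diff(range(xf))
    expect_equal(sepf / sep0, (1 + 0.02 * dtMin)^f, tolerance = 1e-12)
  }
})

test_that("rigid rotation conserves pairwise distances", {
  # the documented per-step map x -> (I + G dt) x is first order, so a
  # rotation conserves distances to O((omega dt)^2) per frame; at
  # omega = 1e-3/min and 30-s frames that is 2.5e-7 per frame
  om <- 1e-3
  G <- matrix(c(0, om, -om, 0), 2, 2)   # antisymmetric
  tr <- generateAffineFlowTracks(G, nFrames = 8, nRows = 3, nCols = 3)
  cl <- trackCells(tr)
  d0 <- dist(cl[cl$frame == 0, c("x", "y")])
  for (f in c(3, 7)) {
    df <- dist(cl[cl$frame == f, c("x", "y")])
    expect_lt(max(abs(df - d0) / d0), 1e-6 * f)
  }
})

test_that("scripted swap reverted after 3 frames restores the initial connectivity", {
  tr <- generateScriptedT1Lattice(
    list(list(row = 2, col = 2, start = 3, swap = 8, plateau = 0, end = 11,
              revert = TRUE)),
    nFrames = 20, nRows = 6, nCols = 6)
  conn <- vertexGBE:::.frameConnectivity(tr)
  expect_setequal(conn[["19"]], conn[["0"]])
  expect_equal(nrow(detectT1Events(tr)), 0)
})

test_that("scripted interface length hits zero exactly once with no four-way frames", {
  tr <- generateScriptedT1Lattice(
    list(list(row = 1, col = 1, start = 2, swap = 10, plateau = 0, end = 16)),
    nFrames = 20, nRows = 5, nCols = 6)
  it <- trackInterfaces(tr)
  len <- interfaceLengths(tr)
  # the losing pair is (row 1, col 1)-(row 1, col 2)
  a <- 1 * 6 + 1 + 1; b <- 1 * 6 + 2 + 1
  pq <- it$cell_a == min(a, b) & it$cell_b == max(a, b)
  expect_equal(sum(len[pq] == 0), 1)
  expect_equal(it$frame[pq][len[pq] == 0], 10)
})

test_that("scripts sharing a cell are rejected", {
  expect_error(generateScriptedT1Lattice(
    list(list(row = 2, col = 2, start = 2, swap = 6, end = 10),
         list(row = 2, col = 3, start = 3, swap = 7, end = 11)),
    nFrames = 15, nRows = 6, nCols = 6), "share a cell")
  expect_error(generateScriptedT1Lattice(
    list(list(row = 0, col = 2, start = 2, swap = 6, end = 10)),
    nFrames = 15), "interior")
  expect_error(generateScriptedT1Lattice(
    list(list(row = 2, col = 2, start = 6, swap = 2, end = 10)),
    nFrames = 15), "script error")
})

test_that("generated tracks always pass the schema validation", {
  # validate = TRUE inside the generators throws on violation; spot-check
  # a scripted lattice across its phases and an advected lattice
  tr1 <- generateScriptedT1Lattice(
    list(list(row = 2, col = 1, start = 1, swap = 5, plateau = 3, end = 12)),
    nFrames = 15, nRows = 6, nCols = 5)
  expect_s4_class(tr1, "EmbryoTracks")
  tr2 <- generateAffineFlowTracks(matrix(c(0.03, 0.01, 0.01, -0.02), 2, 2),
                                  nFrames = 10, nRows = 4, nCols = 4,
                                  noiseSd = 0.05, seed = 9)
  expect_s4_class(tr2, "EmbryoTracks")
})
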