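test_that("domains are a focal cell plus its interface corona over a 5-frame window", {
  tr <- generateAffineFlowTracks(matrix(0, 2, 2), nFrames = 7,
                                 nRows = 5, nCols = 5)
  doms <- assembleDomains(tr, frame = 3)
  expect_equal(length(doms), 25)
  # interior cell of a hexagonal lattice has 6 neighbours -> 7 members
  sizes <- vapply(doms, function(d) length(d$members), integer(1))
  expect_true(any(sizes == 7))
  interior <- doms[[which(sizes == 7)[1]]]
  expect_equal(interior$frames, 1:5)
  # a cell lost from tracking within the window is skipped
  cl <- trackCells(tr)
  drop <- interior$focal
  cl2 <- cl[!(cl$frame == 5 & cl$cell_id == drop), , drop = FALSE]
  cl2$next_id[cl2$frame == 4 & cl2$cell_id == drop] <- -1L
  cl2$prev_id[cl2$frame == 6 & cl2$cell_id == drop] <- -1L
  it2 <- trackInterfaces(tr)
  it2 <- it2[!(it2$frame == 5 & (it2$cell_a == drop | it2$cell_b == drop)), ]
  tr2 <- embryoTracks(cl2, it2, frameIntervalS = 30, meta = tr@meta)
  doms2 <- assembleDomains(tr2, frame = 3)
  expect_lt(length(doms2), 25)
  expect_false(drop %in% vapply(doms2, `[[`, numeric(1), "focal"))
})

test_that("tissue strain rate recovers an imposed affine flow and ignores rigid motion", {
  G <- matrix(c(0.02, 0, 0, -0.03), 2, 2)
  tr <- generateAffineFlowTracks(G, nFrames = 21, nRows = 10, nCols = 10)
  sr <- strainRateTable(tr, frames = 10, components = "tissue")
  expect_lt(max(abs(sr$txx - 0.02)), 1e-6)
  expect_lt(max(abs(sr$tyy + 0.03)), 1e-6)
  expect_lt(max(abs(sr$txy)), 1e-6)
  # rigid rotation: zero symmetric strain rate
  Gr <- matrix(c(0, 0.05, -0.05, 0), 2, 2)
  trR <- generateAffineFlowTracks(Gr, nFrames = 7, nRows = 5, nCols = 5)
  srR <- strainRateTable(trR, frames = 3, components = "tissue")
  expect_lt(max(abs(c(srR$txx, srR$txy, srR$tyy))), 1e-6)
  # static tracks: exactly zero
  tr0 <- generateAffineFlowTracks(matrix(0, 2, 2), nFrames = 5,
                                  nRows = 4, nCols = 4)
  sr0 <- strainRateTable(tr0, frames = 2)
  expect_equal(max(abs(c(sr0$txx, sr0$sxx, sr0$ixx))), 0)
  expect_error(tissueStrainRate(list(cbind(c(0, 1, 2), 0),
                                     cbind(c(0, 1, 2), 0) + 0.1), 0.5),
               "collinear")
})

test_that("the decomposition identity holds exactly and intercalation vanishes for affine flows", {
  G <- matrix(c(0.02, 0.005, 0.005, -0.03), 2, 2)
  tr <- generateAffineFlowTracks(G, nFrames = 9, nRows = 6, nCols = 6)
  sr <- strainRateTable(tr, frames = c(3, 5))
  expect_equal(max(abs(sr$txx - sr$sxx - sr$ixx)), 0)
  expect_equal(max(abs(sr$txy - sr$sxy - sr$ixy)), 0)
  expect_equal(max(abs(sr$tyy - sr$syy - sr$iyy)), 0)
  # cells deform with the flow, no rearrangement -> intercalation ~ 0
  expect_lt(max(abs(c(sr$ixx, sr$ixy, sr$iyy))), 1e-6)
})

test_that("noisy centroids still recover the flow with small bias", {
  # jitter draws are shared across overlapping domains, so bias is judged
  # on the grand mean over independent seeds
  G <- diag(c(0.02, -0.02))
  ms <- vapply(1:5, function(s) {
    tr <- generateAffineFlowTracks(G, nFrames = 21, nRows = 10, nCols = 10,
                                   noiseSd = 0.1, seed = s)
    sr <- strainRateTable(tr, frames = c(5, 10, 15), components = "tissue")
    mean(sr$txx)
  }, numeric(1))
  expect_lt(abs(mean(ms) - 0.02) / 0.02, 0.10)
})

test_that("recovered per-minute rates are invariant to the frame interval", {
  G <- diag(c(0.03, -0.01))
  trA <- generateAffineFlowTracks(G, nFrames = 11, nRows = 5, nCols = 5,
                                  frameIntervalS = 30)
  trB <- generateAffineFlowTracks(G, nFrames = 21, nRows = 5, nCols = 5,
                                  frameIntervalS = 15)
  srA <- strainRateTable(trA, frames = 5, components = "tissue")
  srB <- strainRateTable(trB, frames = 10, components = "tissue")
  expect_lt(abs(mean(srA$txx) - mean(srB$txx)) / 0.03, 0.01)
})

test_that("area weighting averages identical per-cell tensors to themselves", {
  sq <- function(s) rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  S <- matrix(c(0.02, 0, 0, -0.01), 2, 2)
  dtMin <- 0.5
  M <- diag(2) + S * dtMin
  outlines <- lapply(c(1, sqrt(3)), function(s)
    list(sq(s), sq(s) %*% t(M)))
  res <- cellShapeStrainRate(outlines, areas = c(1, 3), dtMin = dtMin)
  expect_equal(res$tensor, S, tolerance = 1e-12)
  expect_equal(res$perCell[[1]], res$perCell[[2]], tolerance = 1e-12)
})

test_that("shape maps resample outlines when vertex counts differ", {
  hexo <- vertexGBE:::.hexPatchCell(1, 1, 2)
  octo <- vertexGBE:::.resampleClosed(hexo, 8)
  M <- vertexGBE:::.shapeMap(hexo, octo)
  expect_equal(M, diag(2), tolerance = 0.05)
})

test_that("strain-rate projection onto the embryonic axes", {
  S <- matrix(c(0.02, 0.004, 0.004, -0.03), 2, 2)
  pr <- projectStrainRate(S)
  expect_equal(unname(pr["ap"]), 0.02)
  expect_equal(unname(pr["dv"]), -0.03)
  iso <- projectStrainRate(0.01 * diag(2))
  expect_equal(unname(iso), c(0.01, 0.01))
  rot <- projectStrainRate(S, list(ap = c(0, 1), dv = c(-1, 0)))
  expect_equal(unname(rot["ap"]), -0.03)
  expect_equal(unname(rot["dv"]), 0.02)
})

test_that("time zero is the first frame above the synchronisation threshold", {
  s <- c(0, 0.002, 0.005, 0.009, 0.02, 0.03)
  expect_equal(synchronizeTimeZero(s), 4)          # 0-based frames
  expect_equal(synchronizeTimeZero(c(0.02, 0.05)), 0)
  expect_error(synchronizeTimeZero(rep(0, 10)), "never exceeds")
  expect_equal(synchronizeTimeZero(rep(c(0.005, 0.011), each = 7),
                                   threshold = 0.01), 7)
  # strictly greater than: exactly 0.01 does not trigger
  expect_equal(synchronizeTimeZero(c(0.01, 0.011)), 1)
})

test_that("within-embryo confidence intervals pool the within-embryo variances", {
  d <- data.frame(embryo = rep(c("e1", "e2"), each = 4),
                  time = rep(1, 8),
                  value = c(1, 1, 1, 1, 2, 2, 2, 2))
  r <- averageWithinEmbryoCI(d)
  expect_equal(r$mean, 1.5)
  expect_equal(r$withinVar, 0)
  expect_equal(r$ciLow, r$ciHigh)
  # two embryos with within-variances v and 3v pool to 2v
  set.seed(5)
  v <- 0.04
  d2 <- data.frame(
    embryo = rep(c("e1", "e2"), each = 2000),
    time = 1,
    value = c(rnorm(2000, 0, sqrt(v)), rnorm(2000, 0, sqrt(3 * v))))
  r2 <- averageWithinEmbryoCI(d2)
  expect_equal(r2$withinVar, 2 * v, tolerance = 0.1)
  expect_equal(r2$ciHigh - r2$mean, 1.96 * sqrt(r2$withinVar / 4000),
               tolerance = 1e-12)
  # one embryo: the mean is that embryo's mean
  r1 <- averageWithinEmbryoCI(d[d$embryo == "e1", ])
  expect_equal(r1$mean, 1)
})

test_that("simulated wild-type tissue shows positive mean AP intercalation", {
  sim <- simulateGBE(gbePreset("WT", seed = 3))
  tr <- simulationTracks(sim, validate = FALSE)
  sr <- strainRateTable(tr, frames = c(35, 45))
  expect_gt(mean(sr$iAP), 0)
  # the synchronisation threshold is crossed while the pull is active
  srT <- strainRateTable(tr, frames = 2:14, components = "tissue")
  t0 <- synchronizeTimeZero(apTissueSeries(srT)$apMedian, firstFrame = 2L)
  expect_lt(t0, 15)
})

test_that("log-ratio of intercalation to tissue strain rates with exclusions", {
  r <- logRatioIntercalation(c(0.02, 0.01, -0.01, 0.02), c(0.02, 0.02, 0.02, 0))
  expect_equal(r$logRatio[1], 0)
  expect_equal(r$logRatio[2], log(0.5))
  expect_true(is.na(r$logRatio[3]))
  expect_true(is.na(r$logRatio[4]))
  expect_equal(r$nExcluded, 2)
})
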