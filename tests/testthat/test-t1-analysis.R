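scriptedT1 <- function(start = 5, swap = 45, plateau = 0, end = 60,
                       nFrames = 61, revert = FALSE) {
  generateScriptedT1Lattice(
    list(list(row = 2, col = 2, start = start, swap = swap,
              plateau = plateau, end = end, revert = revert)),
    nFrames = nFrames, nRows = 6, nCols = 6)
}

test_that("ownership smoothing reverses short bouts and keeps real swaps", {
  # transient 3-frame swap smoothed away
  r <- canonicalizeOwnership(c(rep(1L, 10), rep(2L, 3), rep(1L, 10)))
  expect_true(all(r$smoothed == 1L))
  expect_equal(nrow(r$events), 0)
  # a 5-frame bout survives (two events)
  r5 <- canonicalizeOwnership(c(rep(1L, 10), rep(2L, 5), rep(1L, 10)))
  expect_equal(nrow(r5$events), 2)
  # four-way frames assigned to the most recent owner; the gain frame is
  # the first raw contact of the new pair
  rp <- canonicalizeOwnership(c(rep(1L, 10), rep(0L, 4), rep(2L, 10)))
  expect_equal(rp$events$changeIdx, 15)
  expect_equal(rp$events$gainIdx, 15)
  expect_true(all(rp$smoothed[11:14] == 1L))
  # shortest bout reversed first, earliest on ties
  s <- c(rep(1L, 8), rep(2L, 2), 1L, rep(2L, 4), rep(1L, 8))
  rs <- canonicalizeOwnership(s)
  expect_equal(rle(rs$smoothed)$lengths, c(8, 7, 8))
  # idempotence
  expect_identical(canonicalizeOwnership(rs$smoothed)$smoothed, rs$smoothed)
})

test_that("the detector matches the brute-force rule oracle on random series", {
  set.seed(99)
  for (i in 1:300) {
    s <- randomOwnershipSeries(sample(10:40, 1))
    got <- canonicalizeOwnership(s)
    want <- oracleCanonicalize(s)
    expect_identical(got$smoothed, want$smoothed)
    expect_equal(got$events, want$events)
  }
})

test_that("a scripted permanent swap yields exactly one event at first contact", {
  tr <- scriptedT1()
  ev <- detectT1Events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gainFrame, 46)           # swap at 45, new pair appears at 46
  expect_setequal(c(ev$losingA, ev$losingB), c("15", "16"))
  expect_setequal(c(ev$gainingA, ev$gainingB), c("9", "21"))
})

test_that("a four-way plateau delays the gain to the new pair's first contact", {
  tr <- scriptedT1(swap = 30, plateau = 10, end = 55)
  ev <- detectT1Events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gainFrame, 41)           # 10 four-way frames after the swap
})

test_that("a reverted swap produces no events", {
  tr <- scriptedT1(start = 3, swap = 8, plateau = 0, end = 11, revert = TRUE,
                   nFrames = 30)
  expect_equal(nrow(detectT1Events(tr)), 0)
})

test_that("time reversal swaps the losing and gaining pairs", {
  tr <- scriptedT1(start = 10, swap = 30, plateau = 0, end = 50)
  ev <- detectT1Events(tr)
  rev <- reverseTracks(tr)
  evR <- detectT1Events(rev)
  expect_equal(nrow(evR), 1)
  expect_setequal(c(evR$losingA, evR$losingB), c(ev$gainingA, ev$gainingB))
  expect_setequal(c(evR$gainingA, evR$gainingB), c(ev$losingA, ev$losingB))
})

test_that("pre-swap orientation is measured 5 minutes before the gain frame", {
  tr <- scriptedT1()
  ev <- detectT1Events(tr)
  expect_equal(t1Orientation(ev[1, ], tr), 90)     # DV-parallel interface
  # an event too close to the start of tracking is excluded
  tr2 <- scriptedT1(start = 1, swap = 6, end = 20, nFrames = 40)
  ev2 <- detectT1Events(tr2)
  expect_true(is.na(t1Orientation(ev2[1, ], tr2)))
})

test_that("the corrected lost-gained angle is 90 degrees for the idealised quartet", {
  tr <- scriptedT1()
  ev <- detectT1Events(tr)
  expect_equal(correctedLostGainedAngle(ev[1, ], tr), 90)
  # parallel lost and gained interfaces give 0 (reverted regrowth of the
  # same orientation has no angular difference)
  expect_equal(vertexGBE:::.angleDiff180(90, 90), 0)
})

test_that("the rotation correction removes a rigid rotation between pre and post frames", {
  tr <- scriptedT1()
  ev <- detectT1Events(tr)
  off <- round(5 * 60 / frameInterval(tr))
  fPost <- ev$gainFrame + off
  # rotate the whole post frame by 30 degrees about the quartet centre
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(vertexGBE:::.centroidAt(tr, "15", fPost) +
           vertexGBE:::.centroidAt(tr, "16", fPost)) / 2 +
         c(vertexGBE:::.centroidAt(tr, "9", fPost) +
           vertexGBE:::.centroidAt(tr, "21", fPost)) / 2
  cl <- trackCells(tr); it <- trackInterfaces(tr)
  rot <- function(x, y) {
    p <- sweep(cbind(x, y), 2, ctr / 2) %*% t(R)
    sweep(p, 2, ctr / 2, FUN = "+")
  }
  sel <- cl$frame == fPost
  pc <- rot(cl$x[sel], cl$y[sel])
  cl$x[sel] <- pc[, 1]; cl$y[sel] <- pc[, 2]
  cl$outline[sel] <- vapply(which(sel), function(i) {
    p <- parseOutline(trackCells(tr)$outline[i])
    vertexGBE:::.formatOutline(rot(p[, 1], p[, 2]))
  }, character(1))
  si <- it$frame == fPost
  p1 <- rot(it$x1[si], it$y1[si]); p2 <- rot(it$x2[si], it$y2[si])
  it$x1[si] <- p1[, 1]; it$y1[si] <- p1[, 2]
  it$x2[si] <- p2[, 1]; it$y2[si] <- p2[, 2]
  trRot <- embryoTracks(cl, it, frameIntervalS = 30, meta = tr@meta,
                        validate = FALSE)
  expect_equal(correctedLostGainedAngle(ev[1, ], trRot), 90, tolerance = 1e-9)
})

test_that("the shortening-to-centroid angle is 0 for the idealised quartet at all lookbacks", {
  tr <- scriptedT1()
  ev <- detectT1Events(tr)
  sc <- shorteningToCentroidAngle(ev[1, ], tr)
  expect_gte(nrow(sc), 28)
  expect_lt(max(abs(sc$angleDeg)), 1e-9)
  expect_true(all(sc$minutesBefore <= 15))
  # a global rotation leaves the relative angle unchanged
  expect_equal(abs(vertexGBE:::.angleDiff180(120, 30)), 90)
})

test_that("productive T1 counting subtracts AP gains and normalises by DV interfaces", {
  tr <- scriptedT1()
  ev <- detectT1Events(tr)
  pr <- countProductiveT1s(ev, tr)
  n <- nrow(pr)
  expect_equal(pr$netCumulative[1], 0)
  expect_equal(pr$netCumulative[n], 1)     # one DV-oriented gain
  expect_true(all(diff(pr$netCumulative) >= 0))
  expect_equal(pr$normalized[n], 1 / pr$nDVInterfaces[n])
  # doubling the tissue (two disjoint copies) leaves the measure unchanged
  cl <- trackCells(tr); it <- trackInterfaces(tr)
  shift <- 200
  cl2 <- cl; cl2$cell_id <- cl2$cell_id + 1000L
  cl2$prev_id <- ifelse(cl2$prev_id == -1L, -1L, cl2$prev_id + 1000L)
  cl2$next_id <- ifelse(cl2$next_id == -1L, -1L, cl2$next_id + 1000L)
  cl2$x <- cl2$x + shift
  cl2$outline <- vapply(seq_len(nrow(cl2)), function(i) {
    p <- parseOutline(cl2$outline[i]); p[, 1] <- p[, 1] + shift
    vertexGBE:::.formatOutline(p)
  }, character(1))
  it2 <- it; it2$cell_a <- it2$cell_a + 1000L; it2$cell_b <- it2$cell_b + 1000L
  it2$interface_id <- paste0(it2$interface_id, "_copy")
  it2$prev_id <- ifelse(it2$prev_id == "-1", "-1", paste0(it2$prev_id, "_copy"))
  it2$next_id <- ifelse(it2$next_id == "-1", "-1", paste0(it2$next_id, "_copy"))
  it2$x1 <- it2$x1 + shift; it2$x2 <- it2$x2 + shift
  trD <- embryoTracks(rbind(cl, cl2), rbind(it, it2), frameIntervalS = 30,
                      meta = tr@meta, validate = FALSE)
  evD <- detectT1Events(trD)
  expect_equal(nrow(evD), 2)
  prD <- countProductiveT1s(evD, trD)
  expect_equal(prD$normalized[n], pr$normalized[n])
})

test_that("resolution phases are sub-threshold intervals straddling the swap", {
  # 8 frames below threshold at 30 s cadence -> 4 minutes; the smoothed
  # series is engineered to be below 0.75 um exactly on those frames
  lengths <- c(rep(2, 10), rep(0, 8), rep(2, 10))
  ph <- resolutionPhaseDuration(lengths, swapIdx = 14)
  expect_equal(ph$durationMin, 4)
  expect_equal(ph$endIdx - ph$startIdx + 1L, 8)
  # a series never below threshold has no phase
  expect_null(resolutionPhaseDuration(rep(2, 20), swapIdx = 10))
  # phases clipped by the series boundary are discarded
  expect_null(resolutionPhaseDuration(c(rep(0, 8), rep(2, 10)), swapIdx = 4))
  expect_null(resolutionPhaseDuration(c(rep(2, 10), rep(0, 8)), swapIdx = 14))
})

test_that("the immortal length series hands identity across the swap", {
  tr <- scriptedT1(start = 5, swap = 20, plateau = 4, end = 40)
  ev <- detectT1Events(tr)
  ls <- immortalLengthSeries(ev[1, ], tr)
  expect_equal(length(ls), 61)
  expect_true(all(ls[1:5 + 1] > 0))         # losing pair before shortening
  expect_true(all(ls[22:24 + 1] == 0))      # four-way frames
  expect_true(all(ls[26:40 + 1] > 0))       # gaining pair regrowing
  ph <- resolutionPhaseDuration(ls, swapIdx = ev$gainFrame + 1L)
  expect_false(is.null(ph))
  expect_true(ph$startIdx <= ev$gainFrame + 1L)
})
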