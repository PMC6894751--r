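test_that("a square fits an equal-area circle", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  e <- fitCellEllipse(sq)
  expect_equal(e$a, 2 / sqrt(pi), tolerance = 1e-6)
  expect_equal(e$b, 2 / sqrt(pi), tolerance = 1e-6)
  expect_equal(unname(e$centroid), c(1, 1), tolerance = 1e-12)
})

test_that("a 4:1 rectangle fits an axis-aligned ellipse matching a grid-search oracle", {
  rect <- rbind(c(0, 0), c(4, 0), c(4, 1), c(0, 1))
  e <- fitCellEllipse(rect)
  expect_lt(min(e$thetaDeg, 180 - e$thetaDeg), 1)   # major axis along x
  expect_gt(log(e$a / e$b), 0)
  # brute-force grid over (log aspect, theta) with the same constrained family
  A <- 4; ab <- A / pi
  grid <- expand.grid(la = seq(0.5, 2.5, by = 0.05),
                      th = seq(-pi / 4, pi / 4, by = pi / 32))
  mm <- mapply(function(la, th) {
    a <- sqrt(ab * exp(la)); b <- sqrt(ab / exp(la))
    ep <- vertexGBE:::.ellipsePolygon(c(2, 0.5), a, b, th, 128)
    inter <- abs(polygonSignedArea(vertexGBE:::.clipPolygonConvex(rect, ep)))
    A + abs(polygonSignedArea(ep)) - 2 * inter
  }, grid$la, grid$th)
  expect_lte(e$mismatchArea, min(mm) + 1e-3)
  expect_equal(e$a, sqrt(ab * exp(grid$la[which.min(mm)])), tolerance = 0.05)
})

test_that("ellipse fits are translation-equivariant", {
  poly <- rbind(c(0, 0), c(3, 0.2), c(3.5, 1.5), c(1.5, 2.3), c(-0.3, 1.2))
  e1 <- fitCellEllipse(poly)
  e2 <- fitCellEllipse(sweep(poly, 2, c(5, -3), FUN = "+"))
  expect_equal(e2$a, e1$a, tolerance = 1e-9)
  expect_equal(e2$b, e1$b, tolerance = 1e-9)
  expect_equal(e2$thetaDeg, e1$thetaDeg, tolerance = 1e-6)
  expect_equal(unname(e2$centroid - e1$centroid), c(5, -3), tolerance = 1e-9)
})

test_that("fit constraints hold and the refined fit beats the moment ellipse", {
  set.seed(21)
  for (i in 1:60) {
    poly <- randomConvexPolygon()
    A <- abs(polygonSignedArea(poly))
    refine <- i <= 20    # refinement is slower; constraint check on all
    e <- fitCellEllipse(poly, refine = refine)
    expect_equal(pi * e$a * e$b, A, tolerance = 1e-6 * A)
    expect_equal(unname(e$centroid), unname(polygonCentroid(poly)),
                 tolerance = 1e-9)
    if (refine) {
      eMoment <- fitCellEllipse(poly, refine = FALSE)
      expect_lte(e$mismatchArea, eMoment$mismatchArea + 1e-9)
    }
  }
})

test_that("axial shape elongation follows the composite formula and sign convention", {
  expect_equal(axialShapeElongation(list(a = 3, b = 1, thetaDeg = 45))$axialElongation, 0)
  expect_equal(axialShapeElongation(list(a = 1, b = 1, thetaDeg = 10))$axialElongation, 0)
  # DV-aligned elongated cell scores +anisotropy; the stated extreme is +1.5
  expect_equal(axialShapeElongation(list(a = exp(1.5), b = 1,
                                         thetaDeg = 90))$axialElongation, 1.5)
  # AP-aligned cell scores negative
  expect_equal(axialShapeElongation(list(a = 2, b = 1,
                                         thetaDeg = 0))$axialElongation, -log(2))
  # odd under reflection of orientation about 45 degrees
  for (th in c(10, 30, 44)) {
    up <- axialShapeElongation(list(a = 2, b = 1, thetaDeg = 90 - th))
    dn <- axialShapeElongation(list(a = 2, b = 1, thetaDeg = th))
    expect_equal(up$axialElongation, -dn$axialElongation, tolerance = 1e-12)
  }
})

test_that("axis-projected cell lengths match the closed form", {
  expect_equal(axisProjectedCellLength(list(a = 1.5, b = 1.5, thetaDeg = 33), "AP"), 3)
  expect_equal(axisProjectedCellLength(list(a = 1.5, b = 1.5, thetaDeg = 33), "DV"), 3)
  expect_equal(axisProjectedCellLength(list(a = 2, b = 1, thetaDeg = 0), "AP"), 4)
  expect_equal(axisProjectedCellLength(list(a = 2, b = 1, thetaDeg = 0), "DV"), 2)
  expect_equal(axisProjectedCellLength(list(a = 2, b = 1, thetaDeg = 45), "AP"),
               sqrt(10))
  # support-function oracle: max projection over dense boundary points
  a <- 2; b <- 1; th <- 45 * pi / 180
  t <- seq(0, 2 * pi, length.out = 20001)
  bx <- a * cos(t) * cos(th) - b * sin(t) * sin(th)
  expect_equal(axisProjectedCellLength(list(a = 2, b = 1, thetaDeg = 45), "AP"),
               2 * max(bx), tolerance = 1e-6)
})

test_that("interface orientation classes follow the 45-degree rule with DV tie-break", {
  expect_equal(classifyInterfaceOrientation(c(0, 0), c(cos(pi / 6), sin(pi / 6)))$class, "AP")
  expect_equal(classifyInterfaceOrientation(c(0, 0), c(cos(pi / 3), sin(pi / 3)))$class, "DV")
  expect_equal(classifyInterfaceOrientation(c(0, 0), c(1, 1))$class, "DV")
  expect_error(classifyInterfaceOrientation(c(1, 1), c(1, 1)), "zero-length")
  # angle is measured to the supplied AP axis
  r <- classifyInterfaceOrientation(c(0, 0), c(0, 1), apAxis = c(0, 1))
  expect_equal(r$angleDeg, 0)
  expect_equal(r$class, "AP")
})

test_that("heat maps bin by time and mirrored DV location", {
  tr <- generateAffineFlowTracks(matrix(0, 2, 2), nFrames = 61,
                                 nRows = 4, nCols = 4)
  vals <- trackCells(tr)[, c("frame", "cell_id")]
  vals$value <- 2.5
  hm <- spatiotemporalHeatmap(tr, vals)
  expect_equal(dim(hm$mean), c(30, 20))
  expect_true(all(hm$mean[hm$n > 0] == 2.5))
  expect_equal(sum(hm$n) + hm$spill, nrow(vals))
  # mirroring the tracks about the midline leaves the maps unchanged
  cl <- trackCells(tr); cl$y <- -cl$y
  cl$outline <- vapply(seq_len(nrow(cl)), function(i) {
    p <- parseOutline(trackCells(tr)$outline[i]); p[, 2] <- -p[, 2]
    vertexGBE:::.formatOutline(p[rev(seq_len(nrow(p))), ])
  }, character(1))
  it <- trackInterfaces(tr); it$y1 <- -it$y1; it$y2 <- -it$y2
  trM <- embryoTracks(cl, it, frameIntervalS = 30, meta = tr@meta)
  hmM <- spatiotemporalHeatmap(trM, vals)
  expect_identical(hmM$n, hm$n)
  expect_identical(hmM$mean, hm$mean)
})
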