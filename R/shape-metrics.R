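# Per-cell shape descriptors: area- and centroid-constrained best-fit
# ellipses (minimising the area of mismatch with the outline polygon),
# the axial shape elongation composite, axis-projected cell lengths,
# interface orientation classes and spatiotemporal heat-map binning.

# Sutherland-Hodgman clipping of an arbitrary simple polygon against a
# convex counter-clockwise clip polygon; vectorised over subject vertices.
.clipPolygonConvex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    m <- nrow(out)
    if (m == 0) return(out)
    a <- clip[i, ]
    b <- clip[if (i == n) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    d <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    keepV <- d >= 0
    if (all(keepV)) next   # this half-plane does not cut the subject
    nxt <- c(seq_len(m)[-1], 1L)
    dj <- d; dk <- d[nxt]
    crossing <- keepV != (dk >= 0)
    tt <- dj / (dj - dk)
    ip <- out + tt * (out[nxt, , drop = FALSE] - out)
    arr <- matrix(0, 2 * m, 2)
    arr[seq(1, 2 * m, 2), ] <- out
    arr[seq(2, 2 * m, 2), ] <- ip
    keep <- logical(2 * m)
    keep[seq(1, 2 * m, 2)] <- keepV
    keep[seq(2, 2 * m, 2)] <- crossing
    out <- arr[keep, , drop = FALSE]
  }
  out
}

# Counter-clockwise polygon approximation of an ellipse.
.ellipsePolygon <- function(centroid, a, b, thetaRad, n = 128L) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  ca <- cos(thetaRad); sa <- sin(thetaRad)
  x <- a * cos(ang); y <- b * sin(ang)
  cbind(centroid[1] + ca * x - sa * y,
        centroid[2] + sa * x + ca * y)
}

# Central second area moments of a polygon divided by its area (the
# covariance of the uniform density over the polygon).
.polygonCov <- function(p) {
  cen <- polygonCentroid(p)
  q <- sweep(p, 2, cen)
  n <- nrow(q)
  j <- c(2:n, 1)
  cr <- q[, 1] * q[j, 2] - q[j, 1] * q[, 2]
  A <- sum(cr) / 2
  sxx <- sum(cr * (q[, 1]^2 + q[, 1] * q[j, 1] + q[j, 1]^2)) / 12
  syy <- sum(cr * (q[, 2]^2 + q[, 2] * q[j, 2] + q[j, 2]^2)) / 12
  sxy <- sum(cr * (2 * q[, 1] * q[, 2] + q[, 1] * q[j, 2] +
                   q[j, 1] * q[, 2] + 2 * q[j, 1] * q[j, 2])) / 24
  matrix(c(sxx, sxy, sxy, syy), 2, 2) / A
}

#' Fit the area- and centroid-constrained best-fit ellipse to a cell outline
#'
#' The ellipse is constrained to the polygon's exact area and centroid (so
#' only the aspect ratio and orientation are free) and minimises the area
#' of mismatch (symmetric difference) with the outline. The search is
#' initialised from the polygon's second moments and refined with a
#' derivative-free local optimiser over (log aspect, orientation); the
#' mismatch area is evaluated by clipping the polygon against a 128-gon
#' approximation of the ellipse. Deterministic for a given polygon.
#'
#' @param polygon n x 2 matrix of outline vertices (simple, positive area).
#' @param apAxis unit vector of the AP axis used as the orientation
#'   reference (default x).
#' @param nGon number of vertices of the ellipse approximation
#'   (default 128).
#' @param refine run the mismatch-minimising refinement (default TRUE;
#'   FALSE returns the moment-based ellipse normalised to equal area).
#' @return a list of class \code{FittedEllipse}: \code{centroid},
#'   semi-axes \code{a >= b}, \code{thetaDeg} (major-axis orientation to
#'   the AP axis, in \[0, 180)), and \code{mismatchArea}.
#' @examples
#' sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
#' fitCellEllipse(sq)$a   # circle radius 2 / sqrt(pi)
#' @export
fitCellEllipse <- function(polygon, apAxis = c(1, 0), nGon = 128L,
                           refine = TRUE) {
  A <- polygonSignedArea(polygon)
  if (A < 0) { polygon <- polygon[rev(seq_len(nrow(polygon))), ]; A <- -A }
  if (A <= 0 || nrow(polygon) < 3)
    stop("fitCellEllipse: degenerate polygon")
  cen <- polygonCentroid(polygon)
  ab <- A / pi                       # product of semi-axes, fixed

  cov <- .polygonCov(polygon)
  ei <- eigen(cov, symmetric = TRUE)
  aspect0 <- sqrt(max(ei$values[1], 1e-12) / max(ei$values[2], 1e-12))
  theta0 <- atan2(ei$vectors[2, 1], ei$vectors[1, 1])

  mismatch <- function(par) {
    aspect <- exp(par[1])
    a <- sqrt(ab * aspect); b <- sqrt(ab / aspect)
    ep <- .ellipsePolygon(cen, a, b, par[2], nGon)
    inter <- abs(polygonSignedArea(.clipPolygonConvex(polygon, ep)))
    A + abs(polygonSignedArea(ep)) - 2 * inter
  }
  par <- c(log(aspect0), theta0)
  if (refine) {
    opt <- stats::optim(par, mismatch, method = "Nelder-Mead",
                        control = list(maxit = 80, reltol = 1e-7))
    if (opt$value <= mismatch(par)) par <- opt$par
  }
  aspect <- exp(par[1])
  if (aspect < 1) { aspect <- 1 / aspect; par[2] <- par[2] + pi / 2 }
  a <- sqrt(ab * aspect); b <- sqrt(ab / aspect)
  axAngle <- atan2(apAxis[2], apAxis[1])
  structure(list(centroid = cen, a = a, b = b,
                 thetaDeg = foldAngle180((par[2] - axAngle) * 180 / pi),
                 mismatchArea = mismatch(par)),
            class = "FittedEllipse")
}

#' @export
print.FittedEllipse <- function(x, ...) {
  cat(sprintf("FittedEllipse: a = %.4g, b = %.4g, theta = %.2f deg to AP, centroid (%.3g, %.3g)\n",
              x$a, x$b, x$thetaDeg, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Axial shape elongation score
#'
#' Composite of cell-shape anisotropy and orientation:
#' \deqn{(orientation/45 - 1) \times \ln(a/b)}
#' with the orientation of the major axis folded into \[0, 90\] degrees to
#' the AP axis. Isotropic cells and cells oriented at 45 degrees score 0;
#' negative values are AP-elongated cells, positive values DV-elongated.
#'
#' @param ellipse a \code{FittedEllipse} (or any list with \code{a},
#'   \code{b}, \code{thetaDeg}).
#' @return list with \code{anisotropy} (\eqn{\ln(a/b) \ge 0}),
#'   \code{orientationDeg} in \[0, 90\] and \code{axialElongation}.
#' @examples
#' axialShapeElongation(list(a = exp(1.5), b = 1, thetaDeg = 90))
#' @export
axialShapeElongation <- function(ellipse) {
  aniso <- log(ellipse$a / ellipse$b)
  o <- foldAngle180(ellipse$thetaDeg)
  if (o > 90) o <- 180 - o
  list(anisotropy = aniso, orientationDeg = o,
       axialElongation = (o / 45 - 1) * aniso)
}

#' Cell length along an embryonic axis
#'
#' Width (diameter) of the fitted cell-shape ellipse along the AP or DV
#' axis: \eqn{2\sqrt{a^2\cos^2\varphi + b^2\sin^2\varphi}} with
#' \eqn{\varphi} the angle between the axis and the major axis.
#'
#' @param ellipse a \code{FittedEllipse}.
#' @param axis "AP" or "DV".
#' @return length in the units of the ellipse (micrometres).
#' @examples
#' axisProjectedCellLength(list(a = 2, b = 1, thetaDeg = 45), "AP") # sqrt(10)
#' @export
axisProjectedCellLength <- function(ellipse, axis = c("AP", "DV")) {
  axis <- match.arg(axis)
  th <- ellipse$thetaDeg * pi / 180
  if (axis == "AP")
    2 * sqrt(ellipse$a^2 * cos(th)^2 + ellipse$b^2 * sin(th)^2)
  else
    2 * sqrt(ellipse$a^2 * sin(th)^2 + ellipse$b^2 * cos(th)^2)
}

#' Classify interface orientation relative to the AP axis
#'
#' The vertex-vertex line of an interface is AP-oriented when its acute
#' angle to the AP axis is below 45 degrees and DV-oriented otherwise
#' (exactly 45 degrees classifies as DV; the tie-break is documented, not
#' biological).
#'
#' @param p1,p2 interface endpoints: length-2 vectors or n x 2 matrices.
#' @param apAxis unit AP vector (default x).
#' @return data.frame with \code{angleDeg} (in \[0, 90\]) and \code{class}
#'   ("AP" or "DV").
#' @examples
#' classifyInterfaceOrientation(c(0, 0), c(1, 0.3))
#' @export
classifyInterfaceOrientation <- function(p1, p2, apAxis = c(1, 0)) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 2)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 2)
  v <- p2 - p1
  if (any(rowSums(v^2) == 0))
    stop("classifyInterfaceOrientation: zero-length interface")
  ang <- angleToAxis(v, apAxis)
  data.frame(angleDeg = ang, class = ifelse(ang < 45, "AP", "DV"))
}

#' Spatiotemporal heat map of a per-cell measure
#'
#' Bins (cell, frame) samples of a measure into time-into-GBE by
#' DV-location cells, where the DV location is the distance from the
#' ventral midline (the two embryo halves are pooled by mirroring).
#' Defaults give the 30 x 20 grid of 1-minute by 3-micrometre bins.
#'
#' @param tracks an [EmbryoTracks-class] (supplies cell y-positions, the
#'   midline and the frame cadence).
#' @param values data.frame with columns \code{frame}, \code{cell_id},
#'   \code{value}.
#' @param tZeroFrame frame defining time 0 (default 0).
#' @param timeBinMins,dvBinUm bin widths (default 1 min, 3 um).
#' @param nTimeBins,nDvBins grid size (default 30 x 20).
#' @return list with \code{mean} and \code{n} matrices (time bins in rows,
#'   DV bins in columns) and \code{spill}, the number of samples outside
#'   the grid.
#' @export
spatiotemporalHeatmap <- function(tracks, values, tZeroFrame = 0,
                                  timeBinMins = 1, dvBinUm = 3,
                                  nTimeBins = 30, nDvBins = 20) {
  cells <- tracks@cells
  key <- paste(cells$frame, cells$cell_id)
  idx <- match(paste(values$frame, values$cell_id), key)
  if (anyNA(idx))
    stop("spatiotemporalHeatmap: values cite (frame, cell_id) absent from tracks")
  dv <- abs(cells$y[idx] - tracks@axisFrame$midlineY)
  tmin <- (values$frame - tZeroFrame) * tracks@frameIntervalS / 60
  it <- floor(tmin / timeBinMins) + 1L
  id <- floor(dv / dvBinUm) + 1L
  ok <- it >= 1L & it <= nTimeBins & id >= 1L & id <= nDvBins & tmin >= 0
  mMean <- matrix(NA_real_, nTimeBins, nDvBins)
  mN <- matrix(0L, nTimeBins, nDvBins)
  if (any(ok)) {
    g <- paste(it[ok], id[ok])
    sums <- rowsum(values$value[ok], g)
    cnts <- rowsum(rep(1L, sum(ok)), g)
    ij <- do.call(rbind, lapply(strsplit(rownames(sums), " "), as.integer))
    mMean[ij] <- sums / cnts
    mN[ij] <- cnts
  }
  list(mean = mMean, n = mN, spill = sum(!ok))
}

#' Per-cell shape table for tracked data
#'
#' Convenience wrapper running [fitCellEllipse()] on every (cell, frame)
#' outline and deriving the shape scores and projected lengths.
#'
#' @param tracks an [EmbryoTracks-class].
#' @param frames frames to analyse (default all).
#' @param refine passed to [fitCellEllipse()].
#' @return data.frame with one row per cell and frame: a, b, thetaDeg,
#'   anisotropy, axialElongation, apLength, dvLength.
#' @export
shapeTable <- function(tracks, frames = NULL, refine = TRUE) {
  cells <- tracks@cells
  if (!is.null(frames)) cells <- cells[cells$frame %in% frames, , drop = FALSE]
  ap <- tracks@axisFrame$ap
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    el <- fitCellEllipse(parseOutline(cells$outline[i]), apAxis = ap,
                         refine = refine)
    sc <- axialShapeElongation(el)
    res[[i]] <- data.frame(
      frame = cells$frame[i], cell_id = cells$cell_id[i],
      a = el$a, b = el$b, thetaDeg = el$thetaDeg,
      anisotropy = sc$anisotropy, axialElongation = sc$axialElongation,
      apLength = axisProjectedCellLength(el, "AP"),
      dvLength = axisProjectedCellLength(el, "DV"))
  }
  do.call(rbind, res)
}
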