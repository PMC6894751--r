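# Strain-rate decomposition on focal-cell domains: tissue strain rates from
# the relative motion of tracked centroids, cell-shape strain rates from the
# best-fit linear map between consecutive outlines, and intercalation as
# their difference. All rates are symmetric 2x2 tensors in proportion per
# minute.

#' Assemble focal-cell domains for one central frame
#'
#' A domain is a focal cell plus one corona of neighbours (cells sharing an
#' interface with it at the central frame), followed over a 5-frame window
#' centred on that frame (2 minutes at 30-s cadence). Domains whose member
#' cells are not tracked through the whole window are skipped.
#'
#' @param tracks an [EmbryoTracks-class].
#' @param frame central frame (0-based); needs frames
#'   \code{frame - 2 .. frame + 2}.
#' @param window window length in frames (odd, default 5).
#' @return list of domains, each a list with \code{focal}, \code{members}
#'   (focal first) and \code{frames}; plus attribute \code{skipped} with
#'   the number of focal cells dropped.
#' @export
assembleDomains <- function(tracks, frame, window = 5L) {
  half <- (window - 1L) %/% 2L
  frames <- (frame - half):(frame + half)
  cells <- tracks@cells
  have <- split(cells$cell_id, cells$frame)
  if (!all(as.character(frames) %in% names(have)))
    stop("assembleDomains: window extends beyond the tracked frames")
  present <- Reduce(intersect, have[as.character(frames)])
  ifc <- tracks@interfaces
  ifc <- ifc[ifc$frame == frame, , drop = FALSE]
  out <- list()
  skipped <- 0L
  for (focal in intersect(have[[as.character(frame)]], present)) {
    nb <- unique(c(ifc$cell_b[ifc$cell_a == focal],
                   ifc$cell_a[ifc$cell_b == focal]))
    members <- c(focal, sort(nb))
    if (!all(members %in% present)) { skipped <- skipped + 1L; next }
    out[[length(out) + 1L]] <- list(focal = focal, members = members,
                                    frames = frames)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Tissue strain rate from centroid motion
#'
#' Least-squares fit of the velocity-gradient tensor to the centroid
#' displacements over the window: for each consecutive frame pair, the
#' velocity of every member cell is regressed on its mid-interval position
#' (centred on the domain mean), and the fitted gradient \eqn{G'} is
#' corrected for the finite frame interval as
#' \eqn{G = (I - G' \Delta t/2)^{-1} G'}, which recovers the per-frame
#' advection map exactly. Mid-interval positions make the position noise
#' uncorrelated with the velocity noise, so centroid jitter attenuates
#' rather than biases the fit. The symmetric part of \eqn{G} is the tissue
#' strain rate.
#'
#' @param centroids list of n x 2 centroid matrices, one per frame of the
#'   window (same cell order throughout).
#' @param dtMin minutes between consecutive frames.
#' @return list with \code{tensor} (2 x 2 symmetric, per minute) and
#'   \code{gradient} (the full fitted velocity gradient).
#' @export
tissueStrainRate <- function(centroids, dtMin) {
  nf <- length(centroids)
  if (nf < 2) stop("tissueStrainRate: need at least two frames")
  pos <- NULL; vel <- NULL
  for (j in seq_len(nf - 1)) {
    pos <- rbind(pos, (centroids[[j]] + centroids[[j + 1]]) / 2)
    vel <- rbind(vel, (centroids[[j + 1]] - centroids[[j]]) / dtMin)
  }
  pos <- sweep(pos, 2, colMeans(pos))
  X <- cbind(1, pos)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("tissueStrainRate: centroid positions are collinear (rank-deficient fit)")
  beta <- solve(XtX, crossprod(X, vel))
  Gp <- t(beta[2:3, , drop = FALSE])  # rows: velocity component; cols: x, y
  G <- solve(diag(2) - Gp * dtMin / 2, Gp)
  list(tensor = (G + t(G)) / 2, gradient = G)
}

# Best-fit linear map M minimising sum |M p - q|^2 over centroid-aligned
# boundary points; outlines with equal vertex counts are matched by vertex
# identity, otherwise both are resampled by arc length.
.shapeMap <- function(P, Q, nResample = 64L) {
  if (nrow(P) != nrow(Q)) {
    P <- .resampleClosed(P, nResample)
    Q <- .resampleClosed(Q, nResample)
  }
  P <- sweep(P, 2, polygonCentroid(P))
  Q <- sweep(Q, 2, polygonCentroid(Q))
  PtP <- crossprod(P)
  if (rcond(PtP) < 1e-12) stop("shape map: degenerate outline")
  t(solve(PtP, crossprod(P, Q)))
}

#' Cell-shape strain rate of a domain
#'
#' For each member cell and each consecutive frame pair, the linear map
#' that best carries the outline onto its successor (after centroid
#' alignment) is fitted by least squares over boundary points; its
#' symmetric deviation from the identity per minute is the cell's shape
#' strain rate, averaged over the window. The domain tensor is the
#' area-weighted average over member cells (areas at the central frame).
#'
#' @param outlines list (one per member cell) of lists of outline matrices,
#'   one per frame of the window.
#' @param areas cell areas used as weights (central frame).
#' @param dtMin minutes between consecutive frames.
#' @param nResample boundary points used when vertex counts differ
#'   (default 64).
#' @return list with \code{tensor} (2 x 2 symmetric, per minute) and
#'   \code{perCell} (list of per-cell tensors).
#' @export
cellShapeStrainRate <- function(outlines, areas, dtMin, nResample = 64L) {
  nc <- length(outlines)
  stopifnot(length(areas) == nc)
  perCell <- vector("list", nc)
  for (ci in seq_len(nc)) {
    ol <- outlines[[ci]]
    acc <- matrix(0, 2, 2)
    for (j in seq_len(length(ol) - 1)) {
      M <- .shapeMap(ol[[j]], ol[[j + 1]], nResample)
      acc <- acc + ((M + t(M)) / 2 - diag(2)) / dtMin
    }
    perCell[[ci]] <- acc / (length(ol) - 1)
  }
  tensor <- Reduce(`+`, Map(function(S, a) S * a, perCell, areas)) / sum(areas)
  list(tensor = tensor, perCell = perCell)
}

#' Intercalation strain rate
#'
#' Exact tensor difference between the tissue and cell-shape strain rates
#' of a domain; captures cells sliding past one another.
#'
#' @param tissue,shape 2 x 2 symmetric strain-rate tensors.
#' @return 2 x 2 symmetric tensor (per minute).
#' @export
intercalationStrainRate <- function(tissue, shape) tissue - shape

#' Project a strain-rate tensor onto the embryonic axes
#'
#' @param tensor 2 x 2 symmetric tensor.
#' @param axisFrame list with unit vectors \code{ap} and \code{dv}.
#' @return named numeric: \code{ap} and \code{dv} components
#'   (\eqn{\hat e^T S \hat e}).
#' @export
projectStrainRate <- function(tensor, axisFrame = list(ap = c(1, 0),
                                                       dv = c(0, 1))) {
  c(ap = as.numeric(t(axisFrame$ap) %*% tensor %*% axisFrame$ap),
    dv = as.numeric(t(axisFrame$dv) %*% tensor %*% axisFrame$dv))
}

#' Strain-rate table over tracked data
#'
#' Runs the domain assembly and the tissue / cell-shape / intercalation
#' decomposition for every focal cell at the requested central frames.
#'
#' @param tracks an [EmbryoTracks-class].
#' @param frames central frames (default: all frames with a full window).
#' @param window window length in frames (default 5).
#' @param components "tissue" only, or c("tissue", "shape") for the full
#'   decomposition (default).
#' @param nResample boundary points for the shape maps.
#' @return data.frame with one row per (frame, focal cell): tensor
#'   components (txx, txy, tyy; sxx..; ixx..) and AP/DV projections
#'   (tAP, tDV, sAP, sDV, iAP, iDV).
#' @export
strainRateTable <- function(tracks, frames = NULL, window = 5L,
                            components = c("tissue", "shape"),
                            nResample = 64L) {
  half <- (window - 1L) %/% 2L
  allFrames <- trackFrames(tracks)
  if (is.null(frames))
    frames <- allFrames[allFrames >= min(allFrames) + half &
                        allFrames <= max(allFrames) - half]
  doShape <- "shape" %in% components
  dtMin <- tracks@frameIntervalS / 60
  cells <- tracks@cells
  af <- tracks@axisFrame
  rows <- list()
  for (f in frames) {
    doms <- assembleDomains(tracks, f, window)
    if (!length(doms)) next
    win <- (f - half):(f + half)
    sub <- cells[cells$frame %in% win, , drop = FALSE]
    byFrame <- split(sub, sub$frame)
    # outlines are shared between overlapping domains: parse each once
    if (doShape) {
      oCache <- lapply(byFrame, function(d) {
        o <- lapply(d$outline, parseOutline)
        names(o) <- as.character(d$cell_id)
        o
      })
      aCache <- vapply(oCache[[as.character(f)]],
                       function(p) abs(polygonSignedArea(p)), numeric(1))
    }
    for (dm in doms) {
      centroids <- lapply(byFrame[as.character(win)], function(d) {
        i <- match(dm$members, d$cell_id)
        cbind(d$x[i], d$y[i])
      })
      tis <- tissueStrainRate(centroids, dtMin)$tensor
      if (doShape) {
        mem <- as.character(dm$members)
        outlines <- lapply(mem, function(m)
          lapply(oCache[as.character(win)], function(fo) fo[[m]]))
        areas <- unname(aCache[mem])
        shp <- cellShapeStrainRate(outlines, areas, dtMin, nResample)$tensor
      } else shp <- matrix(NA_real_, 2, 2)
      itc <- tis - shp
      pt <- projectStrainRate(tis, af)
      ps <- projectStrainRate(shp, af)
      pii <- pt - ps
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, focal = dm$focal, nMembers = length(dm$members),
        txx = tis[1, 1], txy = tis[1, 2], tyy = tis[2, 2],
        sxx = shp[1, 1], sxy = shp[1, 2], syy = shp[2, 2],
        ixx = itc[1, 1], ixy = itc[1, 2], iyy = itc[2, 2],
        tAP = pt["ap"], tDV = pt["dv"], sAP = ps["ap"], sDV = ps["dv"],
        iAP = pii["ap"], iDV = pii["dv"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synchronise movies to the onset of germband extension
#'
#' Time 0 of GBE is the first frame at which the tissue strain rate along
#' AP exceeds the threshold (0.01 proportion per minute). The per-frame
#' series is conventionally the median of the domain AP tissue strain
#' rates.
#'
#' @param apSeries numeric vector of per-frame AP tissue strain rates
#'   (per minute), named or indexed by frame starting at
#'   \code{firstFrame}.
#' @param threshold strain-rate threshold (default 0.01 per minute).
#' @param firstFrame frame index of the first entry (default 0).
#' @return the frame index of time 0.
#' @examples
#' synchronizeTimeZero(c(0, 0.005, 0.02, 0.03))  # frame 2
#' @export
synchronizeTimeZero <- function(apSeries, threshold = 0.01, firstFrame = 0L) {
  i <- which(apSeries > threshold)[1]
  if (is.na(i))
    stop("synchronizeTimeZero: series never exceeds the threshold")
  firstFrame + i - 1L
}

#' Per-frame median AP tissue strain rate
#'
#' @param srTable output of [strainRateTable()].
#' @return data.frame with \code{frame} and \code{apMedian}.
#' @export
apTissueSeries <- function(srTable) {
  agg <- stats::aggregate(tAP ~ frame, data = srTable, FUN = stats::median)
  data.frame(frame = agg$frame, apMedian = agg$tAP)
}

#' Genotype mean series with within-embryo confidence interval
#'
#' Cross-embryo mean per time point with an indicative confidence ribbon
#' computed from the mean of within-embryo variances: the half-width is
#' \eqn{1.96\sqrt{\bar v / N}} with \eqn{\bar v} the mean over embryos of
#' the within-embryo sample variance and \eqn{N} the total number of
#' samples at that time point. The pooled variance is exported so
#' alternative normalisations can be computed.
#'
#' @param data data.frame with columns for embryo, time and value.
#' @param valueCol,embryoCol,timeCol column names (defaults "value",
#'   "embryo", "time").
#' @return data.frame per time point: mean, ciLow, ciHigh, withinVar,
#'   nSamples, nEmbryos.
#' @export
averageWithinEmbryoCI <- function(data, valueCol = "value",
                                  embryoCol = "embryo", timeCol = "time") {
  sp <- split(data, data[[timeCol]])
  rows <- lapply(sp, function(d) {
    byE <- split(d[[valueCol]], d[[embryoCol]])
    means <- vapply(byE, mean, numeric(1))
    vars <- vapply(byE, function(x) if (length(x) > 1) stats::var(x) else 0,
                   numeric(1))
    vbar <- mean(vars)
    n <- nrow(d)
    half <- 1.96 * sqrt(vbar / n)
    m <- mean(means)
    data.frame(time = d[[timeCol]][1], mean = m,
               ciLow = m - half, ciHigh = m + half,
               withinVar = vbar, nSamples = n, nEmbryos = length(byE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$time), , drop = FALSE]
}

#' Log-ratio of intercalation to tissue strain rate
#'
#' \eqn{\ln(iAP / tAP)} per domain; log-ratio space is closer to linear
#' for averaging. Domains with a non-positive component are excluded and
#' counted.
#'
#' @param iAP,tAP AP components of the intercalation and tissue strain
#'   rates, per domain.
#' @return list with \code{logRatio} (NA where excluded) and
#'   \code{nExcluded}.
#' @examples
#' logRatioIntercalation(c(0.01, 0.02), c(0.02, 0.02))$logRatio
#' @export
logRatioIntercalation <- function(iAP, tAP) {
  ok <- iAP > 0 & tAP > 0
  out <- rep(NA_real_, length(iAP))
  out[ok] <- log(iAP[ok] / tAP[ok])
  list(logRatio = out, nExcluded = sum(!ok))
}
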