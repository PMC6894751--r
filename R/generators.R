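# Synthetic tracked-cell generators. Both build a finite patch of regular
# "pointy-top" hexagons (vertical interfaces between same-row neighbours,
# i.e. DV-oriented junctions) whose shared vertices come from one canonical
# coordinate table, so interface endpoints match cell outlines exactly.

# Canonical patch: per-cell outlines are assembled from the top (T) and
# bottom (B) vertices of the cell and of its diagonal neighbours, exactly
# as in the periodic builder but without wrapping.
.hexPatchCell <- function(r, c, side) {
  w <- sqrt(3) * side
  Tv <- function(rr, cc) c(w * (cc + 0.5 * (((rr %% 2) + 2) %% 2)),
                           1.5 * side * rr + side)
  Bv <- function(rr, cc) c(w * (cc + 0.5 * (((rr %% 2) + 2) %% 2)),
                           1.5 * side * rr - side)
  par <- r %% 2
  cL <- c - 1 + par
  cR <- c + par
  rbind(Tv(r, c), Bv(r + 1, cL), Tv(r - 1, cL),
        Bv(r, c), Tv(r - 1, cR), Bv(r + 1, cR))
}

.patchCellId <- function(r, c, nCols) r * nCols + c + 1L

# Interfaces from outlines by shared-vertex matching (coordinates rounded
# to 1e-9 um). Candidate pairs are restricted to lattice neighbours.
.patchInterfaces <- function(outlines, centers, side) {
  n <- length(outlines)
  w <- sqrt(3) * side
  out <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (sum((centers[a, ] - centers[b, ])^2) > (2.2 * w)^2) next
      ka <- paste(sprintf("%.9f", outlines[[a]][, 1]),
                  sprintf("%.9f", outlines[[a]][, 2]))
      kb <- paste(sprintf("%.9f", outlines[[b]][, 1]),
                  sprintf("%.9f", outlines[[b]][, 2]))
      shared <- intersect(ka, kb)
      if (length(shared) == 2) {
        p <- outlines[[a]][match(shared, ka), , drop = FALSE]
        out[[length(out) + 1L]] <- c(a, b, p[1, 1], p[1, 2], p[2, 1], p[2, 2])
      }
    }
  }
  if (!length(out))
    return(data.frame(cell_a = integer(), cell_b = integer(),
                      x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  m <- do.call(rbind, out)
  data.frame(cell_a = as.integer(m[, 1]), cell_b = as.integer(m[, 2]),
             x1 = m[, 3], y1 = m[, 4], x2 = m[, 5], y2 = m[, 6])
}

# Drop consecutive coincident vertices (cyclic) from an outline.
.dedupeOutline <- function(p, tol = 1e-12) {
  n <- nrow(p)
  nxt <- c(2:n, 1)
  dup <- sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2)) < tol
  keep <- !c(dup[n], dup[-n])
  p[keep, , drop = FALSE]
}

# Assemble an EmbryoTracks object from per-frame outline lists.
.tracksFromOutlines <- function(framesOutlines, framesIfaces, frameIntervalS,
                                cellType = "germband", meta = list(unit = "um"),
                                axisFrame = list(ap = c(1, 0), dv = c(0, 1),
                                                 midlineY = 0),
                                validate = TRUE) {
  nFrames <- length(framesOutlines)
  cellRows <- vector("list", nFrames)
  ifaceRows <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    ol <- framesOutlines[[f]]
    n <- length(ol)
    cen <- t(vapply(ol, polygonCentroid, numeric(2)))
    cellRows[[f]] <- data.frame(
      frame = f - 1L, cell_id = seq_len(n),
      x = cen[, 1], y = cen[, 2],
      outline = vapply(ol, .formatOutline, character(1)),
      cell_type = cellType,
      prev_id = if (f == 1) -1L else seq_len(n),
      next_id = if (f == nFrames) -1L else seq_len(n))
    ifc <- framesIfaces[[f]]
    ids <- paste0("i", ifc$cell_a, "_", ifc$cell_b)
    ifaceRows[[f]] <- data.frame(
      frame = f - 1L, interface_id = ids, cell_a = ifc$cell_a,
      cell_b = ifc$cell_b, x1 = ifc$x1, y1 = ifc$y1, x2 = ifc$x2,
      y2 = ifc$y2, prev_id = "-1", next_id = "-1")
  }
  # temporal links between interface episodes
  for (f in seq_len(nFrames)) {
    ids <- ifaceRows[[f]]$interface_id
    if (f > 1) {
      prev <- ifaceRows[[f - 1]]$interface_id
      ifaceRows[[f]]$prev_id <- ifelse(ids %in% prev, ids, "-1")
      ifaceRows[[f - 1]]$next_id <- ifelse(prev %in% ids, prev, "-1")
    }
  }
  embryoTracks(do.call(rbind, cellRows), do.call(rbind, ifaceRows),
               frameIntervalS = frameIntervalS, axisFrame = axisFrame,
               meta = meta, validate = validate)
}

#' Generate tracks advected by a constant velocity-gradient flow
#'
#' A hexagonal lattice of cells is advected by the per-frame affine map
#' \eqn{x(t + \Delta t) = (I + G \Delta t)\, x(t)} (applied to outlines,
#' centroids and interface endpoints about the lattice centroid), with no
#' topology changes. Optional isotropic Gaussian jitter displaces whole
#' cells (outline and centroid together) so that centroid tracks are noisy
#' while outline shapes stay exact. These tracks are the oracle input for
#' strain-rate recovery: the recovered tissue strain rate should equal
#' \code{sym(G)} and the intercalation strain rate should vanish.
#'
#' @param gradient 2 x 2 velocity-gradient tensor, per minute.
#' @param nFrames number of frames.
#' @param nRows,nCols lattice size (default 10 x 10).
#' @param side hexagon side in micrometres (default 2, cell area about
#'   10.4 um^2).
#' @param noiseSd centroid jitter standard deviation (micrometres,
#'   default 0).
#' @param frameIntervalS frame cadence in seconds (default 30).
#' @param seed RNG seed for the jitter.
#' @return an [EmbryoTracks-class] object.
#' @examples
#' tr <- generateAffineFlowTracks(diag(c(0.02, -0.02)), nFrames = 5,
#'                                nRows = 3, nCols = 4)
#' @export
generateAffineFlowTracks <- function(gradient, nFrames, nRows = 10, nCols = 10,
                                     side = 2, noiseSd = 0,
                                     frameIntervalS = 30, seed = 1L) {
  stopifnot(is.matrix(gradient), all(dim(gradient) == c(2, 2)), nFrames >= 1)
  dtMin <- frameIntervalS / 60
  step <- diag(2) + gradient * dtMin

  base <- list(); centers <- matrix(0, nRows * nCols, 2)
  for (r in 0:(nRows - 1)) for (c in 0:(nCols - 1)) {
    id <- .patchCellId(r, c, nCols)
    base[[id]] <- .hexPatchCell(r, c, side)
    centers[id, ] <- polygonCentroid(base[[id]])
  }
  origin <- colMeans(centers)
  baseIfc <- .patchInterfaces(base, centers, side)

  if (noiseSd > 0) set.seed(as.integer(seed))
  framesOutlines <- vector("list", nFrames)
  framesIfaces <- vector("list", nFrames)
  cur <- lapply(base, function(p) sweep(p, 2, origin))
  curIfc <- baseIfc
  curIfc$x1 <- curIfc$x1 - origin[1]; curIfc$x2 <- curIfc$x2 - origin[1]
  curIfc$y1 <- curIfc$y1 - origin[2]; curIfc$y2 <- curIfc$y2 - origin[2]
  for (f in seq_len(nFrames)) {
    ol <- lapply(cur, function(p) sweep(p, 2, origin, FUN = "+"))
    if (noiseSd > 0) {
      jit <- matrix(stats::rnorm(2 * length(ol), sd = noiseSd), ncol = 2)
      ol <- lapply(seq_along(ol), function(i)
        sweep(ol[[i]], 2, jit[i, ], FUN = "+"))
    }
    bad <- which(!vapply(ol, polygonIsSimple, logical(1)))[1]
    if (!is.na(bad))
      stop(sprintf("generateAffineFlowTracks: outline of cell %d self-intersects at frame %d",
                   bad, f - 1L))
    framesOutlines[[f]] <- ol
    ifc <- curIfc
    ifc$x1 <- ifc$x1 + origin[1]; ifc$x2 <- ifc$x2 + origin[1]
    ifc$y1 <- ifc$y1 + origin[2]; ifc$y2 <- ifc$y2 + origin[2]
    framesIfaces[[f]] <- ifc
    # advance
    cur <- lapply(cur, function(p) p %*% t(step))
    p1 <- cbind(curIfc$x1, curIfc$y1) %*% t(step)
    p2 <- cbind(curIfc$x2, curIfc$y2) %*% t(step)
    curIfc$x1 <- p1[, 1]; curIfc$y1 <- p1[, 2]
    curIfc$x2 <- p2[, 1]; curIfc$y2 <- p2[, 2]
  }
  .tracksFromOutlines(framesOutlines, framesIfaces, frameIntervalS,
                      meta = list(unit = "um",
                                  source = "synthetic affine flow",
                                  noiseSd = noiseSd))
}

#' Generate tracks with scripted T1 swaps on a hexagonal lattice
#'
#' Regular-hexagon tracks in which scripted DV-oriented junctions shorten
#' linearly to zero, optionally hold a four-way configuration, then regrow
#' between the orthogonal cell pair (or revert to the original pair). Each
#' script item targets the vertical junction between lattice cells
#' \code{(row, col)} and \code{(row, col + 1)}; the gaining pair are the
#' cells above and below the junction. All geometric fields stay consistent
#' with the topology at every frame, and the idealised symmetric geometry
#' gives a 90-degree lost-gained interface angle and a 0-degree
#' shortening-to-centroid angle.
#'
#' @param script list of items, each a list with fields \code{row},
#'   \code{col} (0-based lattice position of the left cell), \code{start}
#'   (frame at which shortening begins), \code{swap} (frame at which the
#'   junction length reaches zero), \code{plateau} (number of four-way
#'   frames after \code{swap}, default 0), \code{end} (frame at which the
#'   regrowing junction reaches full length) and \code{revert} (if TRUE
#'   the original pair regrows instead, default FALSE).
#' @param nFrames number of frames (default 61: 30 min at 30 s).
#' @param nRows,nCols lattice size (default 6 x 6).
#' @param side hexagon side in micrometres (default 2).
#' @param frameIntervalS frame cadence in seconds (default 30).
#' @return an [EmbryoTracks-class] object.
#' @examples
#' tr <- generateScriptedT1Lattice(
#'   list(list(row = 2, col = 2, start = 2, swap = 10, end = 18)),
#'   nFrames = 21)
#' @export
generateScriptedT1Lattice <- function(script, nFrames = 61, nRows = 6,
                                      nCols = 6, side = 2,
                                      frameIntervalS = 30) {
  w <- sqrt(3) * side
  items <- lapply(script, function(it) {
    it <- utils::modifyList(list(plateau = 0L, revert = FALSE), it)
    for (fld in c("row", "col", "start", "swap", "end"))
      if (is.null(it[[fld]])) stop("script item missing field: ", fld)
    r <- it$row; c <- it$col
    if (r < 1 || r > nRows - 2 || c < 0 || c > nCols - 2)
      stop("script error: quartet at (", r, ",", c, ") is not interior to the lattice")
    if (!(it$start < it$swap && it$swap + it$plateau < it$end && it$end <= nFrames - 1) ||
        it$start < 0)
      stop("script error: need 0 <= start < swap, swap + plateau < end <= nFrames - 1")
    cR <- c + r %% 2
    it$cells <- c(P = .patchCellId(r, c, nCols),
                  Q = .patchCellId(r, c + 1, nCols),
                  T = .patchCellId(r + 1, cR, nCols),
                  B = .patchCellId(r - 1, cR, nCols))
    it$xe <- w * (cR + 0.5 * ((r + 1) %% 2))
    it$ym <- 1.5 * side * r
    it
  })
  allCells <- unlist(lapply(items, `[[`, "cells"))
  if (anyDuplicated(allCells))
    stop("script error: simultaneous swaps share a cell")

  base <- list(); centers <- matrix(0, nRows * nCols, 2)
  for (r in 0:(nRows - 1)) for (c in 0:(nCols - 1)) {
    id <- .patchCellId(r, c, nCols)
    base[[id]] <- .hexPatchCell(r, c, side)
    centers[id, ] <- polygonCentroid(base[[id]])
  }
  h0 <- side / 2
  gMax <- 0.25 * w

  framesOutlines <- vector("list", nFrames)
  framesIfaces <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    fr <- f - 1L
    ol <- base
    extraIfc <- NULL
    for (it in items) {
      ids <- it$cells
      phase <- if (fr < it$start) "base"
        else if (fr < it$swap) "shrink"
        else if (fr <= it$swap + it$plateau) "fourway"
        else if (fr <= it$end) "regrow"
        else "post"
      topPt0 <- c(it$xe, it$ym + h0)
      botPt0 <- c(it$xe, it$ym - h0)
      replacePt <- function(p, old, new) {
        hit <- abs(p[, 1] - old[1]) < 1e-9 & abs(p[, 2] - old[2]) < 1e-9
        if (!any(hit)) return(p)
        p[hit, ] <- matrix(new, sum(hit), 2, byrow = TRUE)
        p
      }
      if (phase == "shrink" || (it$revert && phase %in% c("regrow", "post"))) {
        h <- if (phase == "shrink")
          h0 * (it$swap - fr) / (it$swap - it$start)
        else if (phase == "regrow")
          h0 * min(1, (fr - it$swap - it$plateau) / (it$end - it$swap - it$plateau))
        else h0
        for (ci in ids) {
          ol[[ci]] <- replacePt(ol[[ci]], topPt0, c(it$xe, it$ym + h))
          ol[[ci]] <- replacePt(ol[[ci]], botPt0, c(it$xe, it$ym - h))
        }
      } else if (phase == "fourway") {
        mid <- c(it$xe, it$ym)
        for (ci in ids) {
          ol[[ci]] <- replacePt(ol[[ci]], topPt0, mid)
          ol[[ci]] <- replacePt(ol[[ci]], botPt0, mid)
          ol[[ci]] <- .dedupeOutline(ol[[ci]])
        }
        if (fr == it$swap)  # last (zero-length) contact of the losing pair
          extraIfc <- rbind(extraIfc, data.frame(
            cell_a = min(ids["P"], ids["Q"]), cell_b = max(ids["P"], ids["Q"]),
            x1 = mid[1], y1 = mid[2], x2 = mid[1], y2 = mid[2]))
      } else if (!it$revert && phase %in% c("regrow", "post")) {
        g <- if (phase == "regrow")
          gMax * (fr - it$swap - it$plateau) / (it$end - it$swap - it$plateau)
        else gMax
        vL <- c(it$xe - g, it$ym); vR <- c(it$xe + g, it$ym)
        # P keeps the left new vertex, Q the right; T and B gain both
        p <- base[[ids["P"]]]; p <- p[-c(5, 6), , drop = FALSE]
        ol[[ids["P"]]] <- rbind(p, matrix(vL, 1))
        q <- base[[ids["Q"]]]
        ol[[ids["Q"]]] <- rbind(q[1, , drop = FALSE], matrix(vR, 1),
                                q[4:6, , drop = FALSE])
        tt <- base[[ids["T"]]]
        ol[[ids["T"]]] <- rbind(tt[1:3, , drop = FALSE], matrix(vL, 1),
                                matrix(vR, 1), tt[5:6, , drop = FALSE])
        bb <- base[[ids["B"]]]
        ol[[ids["B"]]] <- rbind(matrix(vR, 1), matrix(vL, 1),
                                bb[2:6, , drop = FALSE])
        if (g == 0) {
          for (ci in ids) ol[[ci]] <- .dedupeOutline(ol[[ci]])
        }
      }
    }
    ifc <- .patchInterfaces(ol, centers, side)
    if (!is.null(extraIfc)) ifc <- rbind(ifc, extraIfc)
    framesOutlines[[f]] <- ol
    framesIfaces[[f]] <- ifc
  }
  .tracksFromOutlines(framesOutlines, framesIfaces, frameIntervalS,
                      meta = list(unit = "um", source = "synthetic scripted T1"))
}
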