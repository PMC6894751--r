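# Neighbour-exchange analysis on tracked connectivity: quartet ownership
# series with immortal interface identity, transient-swap smoothing, T1
# gain events, orientations, productive-T1 counting, rotation-corrected
# angles and resolution-phase durations.

# Canonical unordered pair key; lexicographic on the character form so the
# key is identical whether ids arrive as integers or strings.
.pairKey <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- b < a
  k1 <- ifelse(swap, b, a)
  k2 <- ifelse(swap, a, b)
  paste(k1, k2, sep = "|")
}

# Per-frame connectivity: named list (by frame) of connected pair keys.
.frameConnectivity <- function(tracks) {
  ifc <- tracks@interfaces
  keys <- .pairKey(ifc$cell_a, ifc$cell_b)
  lapply(split(keys, ifc$frame), unique)
}

# Per-frame adjacency lists: for frame f, a named list cell -> neighbours.
.frameAdjacency <- function(conn, frame) {
  keys <- conn[[as.character(frame)]]
  if (is.null(keys)) return(list())
  parts <- strsplit(keys, "|", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  adj <- split(c(b, a), c(a, b))
  lapply(adj, unique)
}

#' Smooth a quartet ownership series and extract surviving swaps
#'
#' The raw series codes, per frame, which diagonal pair of a quartet owns
#' the shared interface: 1 (first pair), 2 (second pair) or 0 (four-way
#' vertex, neither pair connected). Canonicalisation makes the interface
#' immortal: four-way frames are assigned to the most recently connected
#' pair (leading four-way frames to the first owner seen), and transient
#' swaps are smoothed by reversing interior ownership bouts shorter than
#' \code{minBoutFrames} frames, shortest bout first (ties: earliest),
#' iterating until none remain. Runs touching the series boundaries are
#' never reversed. The procedure is idempotent.
#'
#' @param series integer vector of raw ownership codes (0, 1, 2).
#' @param minBoutFrames minimum number of frames for a swap to survive
#'   (default 5, i.e. bouts shorter than 2.5 min at 30-s cadence are
#'   reversed).
#' @return list with \code{smoothed} (series of 1/2), and \code{events}, a
#'   data.frame with one row per surviving ownership change: \code{losing},
#'   \code{gaining} (codes), \code{changeIdx} (first index of the new run)
#'   and \code{gainIdx} (first index at or after the change where the
#'   gaining pair is connected in the raw series - the first-contact
#'   frame).
#' @export
canonicalizeOwnership <- function(series, minBoutFrames = 5L) {
  stopifnot(all(series %in% c(0L, 1L, 2L)))
  n <- length(series)
  filled <- series
  # leading four-way frames take the first owner seen
  nz <- which(filled != 0L)
  if (length(nz) == 0L)
    return(list(smoothed = filled,
                events = data.frame(losing = integer(), gaining = integer(),
                                    changeIdx = integer(), gainIdx = integer())))
  if (nz[1] > 1L) filled[seq_len(nz[1] - 1L)] <- filled[nz[1]]
  # assign four-way frames to the most recent owner
  for (i in seq_len(n)[-1]) if (filled[i] == 0L) filled[i] <- filled[i - 1L]

  repeat {
    r <- rle(filled)
    k <- length(r$lengths)
    if (k <= 2L) break
    interior <- seq_len(k)[-c(1L, k)]
    short <- interior[r$lengths[interior] < minBoutFrames]
    if (!length(short)) break
    j <- short[which.min(r$lengths[short])]  # shortest first, earliest on tie
    r$values[j] <- r$values[j - 1L]
    filled <- inverse.rle(r)
  }

  r <- rle(filled)
  k <- length(r$lengths)
  if (k == 1L) {
    events <- data.frame(losing = integer(), gaining = integer(),
                         changeIdx = integer(), gainIdx = integer())
  } else {
    ends <- cumsum(r$lengths)
    events <- do.call(rbind, lapply(2:k, function(i) {
      changeIdx <- ends[i - 1L] + 1L
      gainIdx <- which(series == r$values[i] & seq_len(n) >= changeIdx)[1]
      if (is.na(gainIdx)) gainIdx <- changeIdx
      data.frame(losing = r$values[i - 1L], gaining = r$values[i],
                 changeIdx = changeIdx, gainIdx = gainIdx)
    }))
  }
  list(smoothed = filled, events = events)
}

#' Canonicalize quartet connectivity over tracked data
#'
#' Identifies candidate quartets from changes in neighbour connectivity
#' (a pair of cells gaining first contact defines the gaining diagonal;
#' the losing diagonal is the pair of their common neighbours that most
#' recently shared an interface), builds each quartet's raw ownership
#' series, and smooths it with [canonicalizeOwnership()].
#'
#' @param tracks an [EmbryoTracks-class].
#' @param minBoutFrames passed to [canonicalizeOwnership()].
#' @param onBothDiagonals what to do with a candidate quartet whose two
#'   diagonal pairs are simultaneously connected at some frame: "skip"
#'   (default) drops it - in dense rearranging tissue four cells can be
#'   pairwise adjacent at two separate junctions, which is not a T1
#'   quartet - while "error" treats it as a data error.
#' @return list of quartets, each a list with \code{pair1}, \code{pair2}
#'   (character cell ids; pair1 is the initial owner), \code{frames},
#'   \code{raw}, \code{smoothed} and \code{events}; the number of skipped
#'   conflicted quartets is in attribute \code{nConflicted}.
#' @export
canonicalizeConnectivity <- function(tracks, minBoutFrames = 5L,
                                     onBothDiagonals = c("skip", "error")) {
  onBothDiagonals <- match.arg(onBothDiagonals)
  conn <- .frameConnectivity(tracks)
  frames <- trackFrames(tracks)
  nf <- length(frames)
  connSet <- lapply(as.character(frames), function(f) conn[[f]])
  names(connSet) <- as.character(frames)

  # candidate gaining pairs: connected at frame i but not at i - 1
  quartets <- list()
  seen <- character()
  for (i in 2:nf) {
    gained <- setdiff(connSet[[i]], connSet[[i - 1]])
    if (!length(gained)) next
    adjPrev <- .frameAdjacency(conn, frames[i - 1])
    for (g in gained) {
      cd <- strsplit(g, "|", fixed = TRUE)[[1]]
      common <- intersect(adjPrev[[cd[1]]], adjPrev[[cd[2]]])
      common <- setdiff(common, cd)
      if (length(common) < 2) next
      # losing-pair candidates among common neighbours: prefer the pair
      # that was connected just before the gain and loses contact at it,
      # otherwise the most recently connected pair (four-way handovers)
      cmb <- utils::combn(sort(common), 2)
      best <- NULL; bestFrame <- -Inf
      for (j in seq_len(ncol(cmb))) {
        key <- .pairKey(cmb[1, j], cmb[2, j])
        if (key %in% connSet[[i - 1]] && !(key %in% connSet[[i]])) {
          best <- cmb[, j]; bestFrame <- Inf
        }
      }
      if (is.null(best)) {
        for (j in seq_len(ncol(cmb))) {
          key <- .pairKey(cmb[1, j], cmb[2, j])
          lastConn <- rev(which(vapply(connSet[seq_len(i - 1)],
                                       function(s) key %in% s, logical(1))))[1]
          if (!is.na(lastConn) && lastConn > bestFrame) {
            bestFrame <- lastConn; best <- cmb[, j]
          }
        }
      }
      if (is.null(best)) next
      qKey <- paste(sort(c(cd, best)), collapse = "|")
      if (qKey %in% seen) next
      seen <- c(seen, qKey)
      quartets[[length(quartets) + 1L]] <- list(pairA = best, pairB = cd)
    }
  }

  out <- list()
  nConflicted <- 0L
  for (q in quartets) {
    kA <- .pairKey(q$pairA[1], q$pairA[2])
    kB <- .pairKey(q$pairB[1], q$pairB[2])
    hasA <- vapply(connSet, function(s) kA %in% s, logical(1))
    hasB <- vapply(connSet, function(s) kB %in% s, logical(1))
    if (any(hasA & hasB)) {
      if (onBothDiagonals == "error")
        stop("canonicalizeConnectivity: both diagonals of a quartet connected simultaneously (frame ",
             frames[which(hasA & hasB)[1]], ")")
      nConflicted <- nConflicted + 1L
      next
    }
    raw <- ifelse(hasA, 1L, ifelse(hasB, 2L, 0L))
    # pair1 = initial owner, so the series starts at 1
    if (raw[which(raw != 0L)[1]] == 2L) {
      tmp <- q$pairA; q$pairA <- q$pairB; q$pairB <- tmp
      raw <- ifelse(raw == 1L, 2L, ifelse(raw == 2L, 1L, 0L))
    }
    can <- canonicalizeOwnership(raw, minBoutFrames)
    out[[length(out) + 1L]] <- list(pair1 = q$pairA, pair2 = q$pairB,
                                    frames = frames, raw = raw,
                                    smoothed = can$smoothed,
                                    events = can$events)
  }
  attr(out, "nConflicted") <- nConflicted
  out
}

#' Detect T1 gain events
#'
#' One event per surviving ownership change of a canonicalized quartet,
#' timed at the frame when the gaining pair made first contact. Transient
#' swaps reversed by the smoothing produce no events.
#'
#' @param tracks an [EmbryoTracks-class].
#' @param minBoutFrames passed to the smoothing (default 5 frames).
#' @return data.frame with one row per event: losingA, losingB, gainingA,
#'   gainingB (cell ids), gainFrame, quartet (key).
#' @export
detectT1Events <- function(tracks, minBoutFrames = 5L) {
  qs <- canonicalizeConnectivity(tracks, minBoutFrames)
  rows <- list()
  for (q in qs) {
    if (!nrow(q$events)) next
    for (i in seq_len(nrow(q$events))) {
      ev <- q$events[i, ]
      losing <- if (ev$losing == 1L) q$pair1 else q$pair2
      gaining <- if (ev$gaining == 1L) q$pair1 else q$pair2
      rows[[length(rows) + 1L]] <- data.frame(
        losingA = losing[1], losingB = losing[2],
        gainingA = gaining[1], gainingB = gaining[2],
        gainFrame = q$frames[ev$gainIdx],
        quartet = paste(sort(c(q$pair1, q$pair2)), collapse = "|"))
    }
  }
  if (!length(rows))
    return(data.frame(losingA = character(), losingB = character(),
                      gainingA = character(), gainingB = character(),
                      gainFrame = integer(), quartet = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gainFrame), , drop = FALSE]
}

# Interface endpoints for a cell pair at a frame, or NULL.
.interfaceAt <- function(tracks, a, b, frame) {
  ifc <- tracks@interfaces
  hit <- ifc$frame == frame &
    ((ifc$cell_a == a & ifc$cell_b == b) | (ifc$cell_a == b & ifc$cell_b == a))
  if (!any(hit)) return(NULL)
  r <- ifc[which(hit)[1], ]
  rbind(c(r$x1, r$y1), c(r$x2, r$y2))
}

.centroidAt <- function(tracks, cell, frame) {
  cl <- tracks@cells
  i <- which(cl$frame == frame & cl$cell_id == cell)[1]
  if (is.na(i)) return(NULL)
  c(cl$x[i], cl$y[i])
}

#' Orientation of the shortening interface before a T1 swap
#'
#' Acute angle to the AP axis of the losing pair's interface, measured
#' \code{offsetMin} minutes (default 5) before the gain frame. Events for
#' which the interface is not measurable at that offset are excluded
#' (NA returned).
#'
#' @param event one row of [detectT1Events()] output.
#' @param tracks the [EmbryoTracks-class] the events came from.
#' @param offsetMin minutes before the gain frame (default 5).
#' @return angle in degrees in \[0, 90\], or NA when excluded.
#' @export
t1Orientation <- function(event, tracks, offsetMin = 5) {
  off <- round(offsetMin * 60 / tracks@frameIntervalS)
  f <- event$gainFrame - off
  if (f < min(trackFrames(tracks))) return(NA_real_)
  ep <- .interfaceAt(tracks, event$losingA, event$losingB, f)
  if (is.null(ep)) return(NA_real_)
  v <- ep[2, ] - ep[1, ]
  if (sum(v^2) == 0) return(NA_real_)
  angleToAxis(v, tracks@axisFrame$ap)
}

#' Rotation-corrected angle between lost and gained interfaces
#'
#' Angular difference between the losing pair's interface 5 minutes before
#' the swap and the gaining pair's interface 5 minutes after, corrected
#' for rigid rotation of the local four-cell domain by subtracting the
#' change in orientation of the gaining pair's centroid-centroid line over
#' the same period. For an idealised T1 between regular hexagons the angle
#' is 90 degrees.
#'
#' @inheritParams t1Orientation
#' @return corrected angle in degrees in \[0, 90\], or NA when either
#'   interface or centroid is not measurable (boundary-clipped events).
#' @export
correctedLostGainedAngle <- function(event, tracks, offsetMin = 5) {
  off <- round(offsetMin * 60 / tracks@frameIntervalS)
  fPre <- event$gainFrame - off
  fPost <- event$gainFrame + off
  frames <- trackFrames(tracks)
  if (fPre < min(frames) || fPost > max(frames)) return(NA_real_)
  lost <- .interfaceAt(tracks, event$losingA, event$losingB, fPre)
  gained <- .interfaceAt(tracks, event$gainingA, event$gainingB, fPost)
  gA1 <- .centroidAt(tracks, event$gainingA, fPre)
  gB1 <- .centroidAt(tracks, event$gainingB, fPre)
  gA2 <- .centroidAt(tracks, event$gainingA, fPost)
  gB2 <- .centroidAt(tracks, event$gainingB, fPost)
  if (is.null(lost) || is.null(gained) || is.null(gA1) || is.null(gB1) ||
      is.null(gA2) || is.null(gB2)) return(NA_real_)
  vLost <- lost[2, ] - lost[1, ]
  vGained <- gained[2, ] - gained[1, ]
  if (sum(vLost^2) == 0 || sum(vGained^2) == 0) return(NA_real_)
  aPre <- .directionAngle180(vLost)
  aPost <- .directionAngle180(vGained)
  rot <- .angleDiff180(.directionAngle180(gB2 - gA2),
                       .directionAngle180(gB1 - gA1))
  d <- (aPost - rot - aPre) %% 180
  if (d > 90) d <- 180 - d
  d
}

#' Angle between the shortening interface and the gaining centroid line
#'
#' For each lookback frame (up to \code{lookbackMin} minutes before the
#' gain frame), the acute angle between the losing pair's interface and
#' the centroid-centroid line of the cells that will gain contact. For an
#' idealised T1 between regular hexagons the angle is 0 degrees throughout.
#'
#' @inheritParams t1Orientation
#' @param lookbackMin minutes monitored before the swap (default 15).
#' @return data.frame with \code{frame}, \code{minutesBefore} and
#'   \code{angleDeg} (frames without measurable data are omitted).
#' @export
shorteningToCentroidAngle <- function(event, tracks, lookbackMin = 15) {
  lb <- round(lookbackMin * 60 / tracks@frameIntervalS)
  frames <- trackFrames(tracks)
  rows <- list()
  for (f in (event$gainFrame - lb):(event$gainFrame - 1)) {
    if (f < min(frames)) next
    ep <- .interfaceAt(tracks, event$losingA, event$losingB, f)
    cA <- .centroidAt(tracks, event$gainingA, f)
    cB <- .centroidAt(tracks, event$gainingB, f)
    if (is.null(ep) || is.null(cA) || is.null(cB)) next
    vI <- ep[2, ] - ep[1, ]
    vC <- cB - cA
    if (sum(vI^2) == 0 || sum(vC^2) == 0) next
    ang <- abs(.angleDiff180(.directionAngle180(vI), .directionAngle180(vC)))
    rows[[length(rows) + 1L]] <- data.frame(
      frame = f,
      minutesBefore = (event$gainFrame - f) * tracks@frameIntervalS / 60,
      angleDeg = ang)
  }
  if (!length(rows))
    return(data.frame(frame = integer(), minutesBefore = numeric(),
                      angleDeg = numeric()))
  do.call(rbind, rows)
}

#' Cumulative net productive T1 swaps per DV-oriented interface
#'
#' Events are classified AP- or DV-oriented by the gaining pair's
#' centroid-centroid line at the gain frame (under vs over 45 degrees from
#' AP). The net productive count per frame is the cumulative number of
#' DV-oriented gains minus AP-oriented gains, normalised by the number of
#' DV-oriented interfaces tracked at that frame.
#'
#' @param events output of [detectT1Events()].
#' @param tracks the corresponding [EmbryoTracks-class].
#' @return data.frame per frame: \code{netCumulative},
#'   \code{nDVInterfaces}, \code{normalized} (NA where no DV-oriented
#'   interface exists).
#' @export
countProductiveT1s <- function(events, tracks) {
  frames <- trackFrames(tracks)
  cls <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    cA <- .centroidAt(tracks, events$gainingA[i], events$gainFrame[i])
    cB <- .centroidAt(tracks, events$gainingB[i], events$gainFrame[i])
    ang <- angleToAxis(cB - cA, tracks@axisFrame$ap)
    cls[i] <- if (ang < 45) "AP" else "DV"
  }
  ifc <- tracks@interfaces
  len <- interfaceLengths(tracks)
  ok <- len > 0
  angI <- rep(NA_real_, nrow(ifc))
  angI[ok] <- angleToAxis(cbind(ifc$x2 - ifc$x1, ifc$y2 - ifc$y1)[ok, , drop = FALSE],
                          tracks@axisFrame$ap)
  nDV <- vapply(frames, function(f)
    sum(ifc$frame == f & !is.na(angI) & angI >= 45), integer(1))
  net <- vapply(frames, function(f)
    sum(cls == "DV" & events$gainFrame <= f) -
      sum(cls == "AP" & events$gainFrame <= f), numeric(1))
  data.frame(frame = frames, netCumulative = net, nDVInterfaces = nDV,
             normalized = ifelse(nDV > 0, net / nDV, NA_real_))
}

#' Resolution phase of a T1 swap
#'
#' The immortal-interface length series (losing pair's interface length,
#' handed over to the gaining pair's after the swap, zero while a four-way
#' vertex persists) is smoothed with a normalised Hanning window and the
#' contiguous interval below the threshold that straddles the swap is
#' returned. Phases clipped by the start or end of tracking are discarded.
#'
#' @param lengths numeric length series (one entry per frame).
#' @param swapIdx index (into \code{lengths}) of the swap, i.e. the gain
#'   frame.
#' @param frameIntervalS seconds per frame (default 30).
#' @param threshold length threshold in micrometres (default 0.75).
#' @param hanningFrames smoothing window length in frames (default 5).
#' @return list with \code{startIdx}, \code{endIdx} and \code{durationMin},
#'   or NULL when no sub-threshold phase straddles the swap or the phase
#'   touches the series boundary.
#' @export
resolutionPhaseDuration <- function(lengths, swapIdx, frameIntervalS = 30,
                                    threshold = 0.75, hanningFrames = 5L) {
  n <- length(lengths)
  stopifnot(swapIdx >= 1, swapIdx <= n)
  sm <- .hanningSmooth(lengths, hanningFrames)
  below <- sm < threshold
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # run straddling the swap: containing swapIdx, else the one just before
  cand <- which(r$values & starts <= swapIdx & ends >= swapIdx)
  if (!length(cand))
    cand <- which(r$values & ends == swapIdx - 1L)
  if (!length(cand)) return(NULL)
  j <- cand[1]
  if (starts[j] == 1L || ends[j] == n) return(NULL)  # boundary-clipped
  list(startIdx = starts[j], endIdx = ends[j],
       durationMin = r$lengths[j] * frameIntervalS / 60)
}

# Hanning-window smoothing with edge renormalisation.
.hanningSmooth <- function(x, m) {
  if (m <= 1) return(x)
  k <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1))
  n <- length(x)
  half <- (m - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    kk <- k[(lo - i + half + 1):(hi - i + half + 1)]
    out[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  out
}

#' Immortal-interface length series for a T1 event
#'
#' Per frame: the losing pair's interface length while it exists, the
#' gaining pair's length once it exists, and 0 during four-way frames.
#'
#' @param event one row of [detectT1Events()] output.
#' @param tracks the corresponding [EmbryoTracks-class].
#' @return numeric vector with one entry per tracked frame (names are the
#'   frame indices).
#' @export
immortalLengthSeries <- function(event, tracks) {
  frames <- trackFrames(tracks)
  out <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    ep <- .interfaceAt(tracks, event$losingA, event$losingB, f)
    if (is.null(ep))
      ep <- .interfaceAt(tracks, event$gainingA, event$gainingB, f)
    out[i] <- if (is.null(ep)) 0 else sqrt(sum((ep[2, ] - ep[1, ])^2))
  }
  names(out) <- frames
  out
}
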