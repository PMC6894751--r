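# Independent, deliberately naive implementations used as oracles.

# Direct scan-based implementation of the quartet canonicalization rules:
# four-way frames to the most recent owner, interior ownership bouts
# shorter than minBout reversed shortest-first (earliest on ties), then one
# event per surviving transition timed at the gaining pair's first raw
# contact at or after the transition.
oracleCanonicalize <- function(s, minBout = 5L) {
  n <- length(s)
  emptyEv <- data.frame(losing = integer(), gaining = integer(),
                        changeIdx = integer(), gainIdx = integer())
  first <- which(s != 0L)[1]
  if (is.na(first)) return(list(smoothed = s, events = emptyEv))
  filled <- integer(n)
  for (i in seq_len(n)) {
    filled[i] <- if (s[i] != 0L) s[i]
      else if (i < first) s[first]
      else filled[i - 1L]
  }
  findRuns <- function(x) {
    st <- 1L; runs <- list()
    for (i in seq_len(n)[-1]) {
      if (x[i] != x[i - 1L]) { runs[[length(runs) + 1L]] <- c(st, i - 1L); st <- i }
    }
    runs[[length(runs) + 1L]] <- c(st, n)
    runs
  }
  repeat {
    runs <- findRuns(filled)
    if (length(runs) <= 2L) break
    lens <- vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))
    interior <- seq_along(runs)[-c(1L, length(runs))]
    short <- interior[lens[interior] < minBout]
    if (!length(short)) break
    j <- short[order(lens[short], short)][1]   # shortest, earliest on tie
    prevVal <- filled[runs[[j - 1L]][2]]
    filled[runs[[j]][1]:runs[[j]][2]] <- prevVal
  }
  runs <- findRuns(filled)
  ev <- emptyEv
  if (length(runs) > 1L) {
    for (k in seq_along(runs)[-1]) {
      changeIdx <- runs[[k]][1]
      gaining <- filled[changeIdx]
      gainIdx <- NA_integer_
      for (i in changeIdx:n) if (s[i] == gaining) { gainIdx <- i; break }
      if (is.na(gainIdx)) gainIdx <- changeIdx
      ev <- rbind(ev, data.frame(losing = filled[changeIdx - 1L],
                                 gaining = gaining,
                                 changeIdx = changeIdx, gainIdx = gainIdx))
    }
  }
  list(smoothed = filled, events = ev)
}

# Random raw ownership series: a few scripted bouts/plateaus on top of a
# base owner, mimicking tracked quartet connectivity.
randomOwnershipSeries <- function(nFrames, maxBouts = 3L) {
  s <- rep(sample(1:2, 1), nFrames)
  for (b in seq_len(sample(0:maxBouts, 1))) {
    at <- sample(nFrames, 1)
    len <- sample(1:8, 1)
    idx <- at:min(nFrames, at + len - 1L)
    s[idx] <- sample(0:2, 1)
  }
  as.integer(s)
}

# Finite-difference oracle for the tissue stress: derivative of the energy
# with respect to an affine box strain, per box area.
fdStress <- function(mesh, params, h = 1e-6) {
  strainE <- function(e, dim) {
    mm <- mesh
    mm@vertices[, dim] <- mm@vertices[, dim] * (1 + e)
    mm@box[dim] <- mm@box[dim] * (1 + e)
    tissueEnergy(mm, params)
  }
  c(xx = (strainE(h, 1) - strainE(-h, 1)) / (2 * h),
    yy = (strainE(h, 2) - strainE(-h, 2)) / (2 * h)) / prod(mesh@box)
}

# Reverse the time axis of tracked data (frames renumbered, temporal links
# swapped), used for the time-reversal property of the T1 detector.
reverseTracks <- function(tracks) {
  nf <- max(tracks@cells$frame)
  cl <- tracks@cells
  cl$frame <- nf - cl$frame
  tmp <- cl$prev_id; cl$prev_id <- cl$next_id; cl$next_id <- tmp
  it <- tracks@interfaces
  it$frame <- nf - it$frame
  tmp <- it$prev_id; it$prev_id <- it$next_id; it$next_id <- tmp
  embryoTracks(cl[order(cl$frame), ], it[order(it$frame), ],
               frameIntervalS = tracks@frameIntervalS,
               axisFrame = tracks@axisFrame, meta = tracks@meta,
               validate = FALSE)
}

# Random simple convex polygon around the origin.
randomConvexPolygon <- function(nMax = 10, scale = 2) {
  n <- sample(4:nMax, 1)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.5, 1) * scale
  cbind(r * cos(ang), r * sin(ang))
}
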