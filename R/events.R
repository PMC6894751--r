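# Topology events: collapse of short junctions into higher-order vertices
# (protorosettes, rosettes) and their stochastic resolution.

# Rebuild one cell's ordered vertex loop from the edge table, oriented
# counter-clockwise (positive unwrapped area).
.cellLoopFromEdges <- function(mesh, cellId) {
  rows <- which(mesh@edgeCells[, 1] == cellId | mesh@edgeCells[, 2] == cellId)
  ev <- mesh@edges[rows, , drop = FALSE]
  n <- nrow(ev)
  used <- logical(n)
  loop <- integer(n)
  loop[1] <- ev[1, 1]
  cur <- ev[1, 2]
  used[1] <- TRUE
  for (i in 2:n) {
    loop[i] <- cur
    nxt <- which(!used & (ev[, 1] == cur | ev[, 2] == cur))[1]
    if (is.na(nxt)) stop("cell loop rebuild failed: open edge chain")
    used[nxt] <- TRUE
    cur <- if (ev[nxt, 1] == cur) ev[nxt, 2] else ev[nxt, 1]
  }
  if (cur != loop[1]) stop("cell loop rebuild failed: chain did not close")
  # orient positively using unwrapped relative coordinates
  V <- mesh@vertices
  d <- .minImage(V[c(loop[-1], loop[1]), , drop = FALSE] -
                 V[loop, , drop = FALSE], mesh@box)
  rel <- apply(rbind(0, d[-n, , drop = FALSE]), 2, cumsum)
  if (polygonSignedArea(rel) < 0) loop <- rev(loop)
  loop
}

# Cells (and the edges between consecutive ones) in cyclic order around a
# vertex, chained topologically through the incident edges.
.cyclicCellsAtVertex <- function(mesh, v) {
  rows <- which(mesh@edges[, 1] == v | mesh@edges[, 2] == v)
  r <- length(rows)
  pairs <- mesh@edgeCells[rows, , drop = FALSE]
  used <- logical(r)
  cellSeq <- integer(r)
  edgeSeq <- integer(r)
  cellSeq[1] <- pairs[1, 1]
  cur <- pairs[1, 2]
  edgeSeq[1] <- rows[1]
  used[1] <- TRUE
  for (i in seq_len(r - 1)) {
    cellSeq[i + 1] <- cur
    nxt <- which(!used & (pairs[, 1] == cur | pairs[, 2] == cur))[1]
    if (is.na(nxt)) stop("vertex fan chain failed")
    used[nxt] <- TRUE
    edgeSeq[i + 1] <- rows[nxt]
    cur <- if (pairs[nxt, 1] == cur) pairs[nxt, 2] else pairs[nxt, 1]
  }
  if (cur != cellSeq[1]) stop("vertex fan did not close")
  # edgeSeq[i] joins cellSeq[i] and cellSeq[i + 1] (cyclic)
  list(cells = cellSeq, edges = edgeSeq)
}

# Energy restricted to a set of cells and the edges they touch: candidate
# vertex splits differ only in these local terms, so they can be compared
# without recomputing the whole tissue energy.
.localEnergy <- function(mesh, cellIds, params) {
  tot <- 0
  for (cid in cellIds) {
    lp <- mesh@cells[[cid]]
    n <- length(lp)
    d <- .minImage(mesh@vertices[c(lp[-1], lp[1]), , drop = FALSE] -
                   mesh@vertices[lp, , drop = FALSE], mesh@box)
    rel <- apply(rbind(0, d[-n, , drop = FALSE]), 2, cumsum)
    A <- polygonSignedArea(rel)
    if (A <= 0) stop("localEnergy: degenerate cell")
    L <- sum(sqrt(d[, 1]^2 + d[, 2]^2))
    tot <- tot + params@K / 2 * (A - params@A0)^2 + params@gamma / 2 * L^2
  }
  rows <- which(mesh@edgeCells[, 1] %in% cellIds |
                mesh@edgeCells[, 2] %in% cellIds)
  d <- .minImage(mesh@vertices[mesh@edges[rows, 2], , drop = FALSE] -
                 mesh@vertices[mesh@edges[rows, 1], , drop = FALSE], mesh@box)
  mism <- mesh@stripe[mesh@edgeCells[rows, 1]] != mesh@stripe[mesh@edgeCells[rows, 2]]
  tot + sum((params@lambda + params@lambdaCable * mism) *
            sqrt(d[, 1]^2 + d[, 2]^2))
}

# Signed (unwrapped) area of one cell loop.
.cellSignedArea <- function(mesh, cellId) {
  lp <- mesh@cells[[cellId]]
  n <- length(lp)
  d <- .minImage(mesh@vertices[c(lp[-1], lp[1]), , drop = FALSE] -
                 mesh@vertices[lp, , drop = FALSE], mesh@box)
  rel <- apply(rbind(0, d[-n, , drop = FALSE]), 2, cumsum)
  polygonSignedArea(rel)
}

# Cell centroid positioned by minimum image relative to a reference point.
.cellCentroidNear <- function(mesh, cellId, ref) {
  lp <- mesh@cells[[cellId]]
  rel <- .minImage(mesh@vertices[lp, , drop = FALSE] -
                   matrix(ref, length(lp), 2, byrow = TRUE), mesh@box)
  ref + polygonCentroid(rel)
}

# Collapse edge row `e` to the midpoint of its endpoints. Returns NULL when
# the collapse is inadmissible (it would create a two-sided cell or a
# duplicated edge), otherwise list(mesh, record).
.collapseEdge <- function(mesh, e) {
  a <- mesh@edges[e, 1]; b <- mesh@edges[e, 2]
  L <- mesh@edgeCells[e, 1]; R <- mesh@edgeCells[e, 2]
  if (length(mesh@cells[[L]]) <= 3 || length(mesh@cells[[R]]) <= 3)
    return(NULL)
  # a vertex adjacent to both endpoints through other edges would yield a
  # duplicated edge after the collapse
  othersA <- setdiff(as.vector(mesh@edges[mesh@edges[, 1] == a | mesh@edges[, 2] == a, ]), c(a, b))
  othersB <- setdiff(as.vector(mesh@edges[mesh@edges[, 1] == b | mesh@edges[, 2] == b, ]), c(a, b))
  if (length(intersect(othersA, othersB)) > 0) return(NULL)

  mid <- mesh@vertices[a, ] + 0.5 * .minImage(mesh@vertices[b, ] - mesh@vertices[a, ], mesh@box)
  mesh@vertices[a, ] <- mid %% mesh@box

  keep <- setdiff(seq_len(nrow(mesh@edges)), e)
  edges <- mesh@edges[keep, , drop = FALSE]
  edgeCells <- mesh@edgeCells[keep, , drop = FALSE]
  edges[edges == b] <- a

  cells <- lapply(mesh@cells, function(lp) {
    lp[lp == b] <- a
    # drop consecutive duplicates (cyclic)
    dup <- lp == c(lp[-1], lp[1])
    if (any(dup)) lp <- lp[!c(dup[length(dup)], dup[-length(dup)])]
    lp
  })

  # delete vertex b and compact the indexing
  remap <- seq_len(nrow(mesh@vertices))
  remap[remap > b] <- remap[remap > b] - 1L
  mesh@vertices <- mesh@vertices[-b, , drop = FALSE]
  edges[] <- remap[edges]
  cells <- lapply(cells, function(lp) remap[lp])
  aNew <- remap[a]

  mi <- mesh@mergeInfo
  mi <- mi[!(mi$vertex %in% c(a, b)), , drop = FALSE]
  mi$vertex <- remap[mi$vertex]

  mesh@edges <- edges
  mesh@edgeCells <- edgeCells
  mesh@cells <- cells
  # reject collapses that fold a neighbouring cell inside out
  if (.cellSignedArea(mesh, L) <= 0 || .cellSignedArea(mesh, R) <= 0)
    return(NULL)
  rank <- sum(edges == aNew)
  if (rank == 4)
    mi <- rbind(mi, data.frame(vertex = aNew, losingA = L, losingB = R))
  mesh@mergeInfo <- mi
  list(mesh = mesh,
       record = data.frame(time = mesh@time, type = "merge", rank = rank,
                           cellA = L, cellB = R, vertex = aNew))
}

#' Collapse all junctions shorter than the merge threshold
#'
#' Every edge with length below \code{lMerge} is collapsed to a single
#' vertex at its midpoint, creating a rank-4 vertex (protorosette) or, when
#' an endpoint already has rank 4 or more, a rank-5+ vertex (rosette).
#' Collapses that would create a two-sided cell are skipped and logged.
#' Shortest edges are processed first and lengths are re-examined after
#' each collapse.
#'
#' @param mesh a [VertexMesh-class].
#' @param params a [VertexModelParams-class]; uses \code{lMerge}.
#' @return list with elements \code{mesh}, \code{records} (data.frame of
#'   merges performed) and \code{skipped} (number of inadmissible
#'   collapses).
#' @export
attemptEdgeMerges <- function(mesh, params) {
  records <- list()
  skipped <- 0L
  skipKeys <- character()
  repeat {
    eg <- .edgeGeometry(mesh)
    keys <- paste(pmin(mesh@edges[, 1], mesh@edges[, 2]),
                  pmax(mesh@edges[, 1], mesh@edges[, 2]))
    cand <- which(eg$len < params@lMerge & !(keys %in% skipKeys))
    if (length(cand) == 0) break
    e <- cand[which.min(eg$len[cand])]
    res <- .collapseEdge(mesh, e)
    if (is.null(res)) {
      skipped <- skipped + 1L
      skipKeys <- c(skipKeys, keys[e])
    } else {
      mesh <- res$mesh
      records[[length(records) + 1L]] <- res$record
      skipKeys <- character()  # indices changed; re-derive
    }
  }
  list(mesh = mesh,
       records = if (length(records)) do.call(rbind, records) else
         data.frame(time = numeric(), type = character(), rank = integer(),
                    cellA = integer(), cellB = integer(), vertex = integer()),
       skipped = skipped)
}

# Split vertex v by detaching the k-th cell of its cyclic fan. The two
# cells flanking the detached cell gain a new shared junction of length
# lNew; v keeps the remaining fan (rank r - 1) and the new vertex has rank
# 3. Returns list(mesh, gainingA, gainingB, splitCell).
.splitVertex <- function(mesh, v, k, ord, params) {
  r <- length(ord$cells)
  splitCell <- ord$cells[k]
  prevCell <- ord$cells[(k - 2) %% r + 1]
  nextCell <- ord$cells[k %% r + 1]
  flank1 <- ord$edges[(k - 2) %% r + 1]  # between prevCell and splitCell
  flank2 <- ord$edges[k]                 # between splitCell and nextCell

  cen <- .cellCentroidNear(mesh, splitCell, mesh@vertices[v, ])
  d <- cen - mesh@vertices[v, ]
  nd <- sqrt(sum(d^2))
  if (nd == 0) d <- c(1, 0) else d <- d / nd

  vNew <- nrow(mesh@vertices) + 1L
  p2 <- (mesh@vertices[v, ] + params@lNew / 2 * d) %% mesh@box
  p1 <- (mesh@vertices[v, ] - params@lNew / 2 * d) %% mesh@box
  mesh@vertices[v, ] <- p1
  mesh@vertices <- rbind(mesh@vertices, p2)

  for (fe in c(flank1, flank2)) {
    i <- if (mesh@edges[fe, 1] == v) 1 else 2
    mesh@edges[fe, i] <- vNew
  }
  mesh@edges <- rbind(mesh@edges, c(min(v, vNew), max(v, vNew)))
  mesh@edgeCells <- rbind(mesh@edgeCells, c(prevCell, nextCell))

  lp <- mesh@cells[[splitCell]]
  lp[lp == v] <- vNew
  mesh@cells[[splitCell]] <- lp
  for (cc in c(prevCell, nextCell))
    mesh@cells[[cc]] <- .cellLoopFromEdges(mesh, cc)

  mesh@mergeInfo <- mesh@mergeInfo[mesh@mergeInfo$vertex != v, , drop = FALSE]
  for (cc in c(splitCell, prevCell, nextCell))
    if (.cellSignedArea(mesh, cc) <= 0)
      stop("splitVertex: resolution would fold a cell inside out")
  list(mesh = mesh, gainingA = prevCell, gainingB = nextCell,
       splitCell = splitCell)
}

#' Stochastic resolution of higher-order vertices
#'
#' Every rank-4 vertex resolves during the step with probability
#' \eqn{1 - e^{-p_4 \, dt}} and every rank-5+ vertex with probability
#' \eqn{1 - e^{-p_{5+} \, dt}}. A rank-4 resolution reconnects the cell
#' pair that was not adjacent before the collapse (completing the T1 swap);
#' a rank-\eqn{r} (\eqn{r \ge 5}) resolution detaches one cell, producing
#' vertices of rank \eqn{r - 1} and 3. Among admissible detachments the one
#' that lowers the energy most is chosen; ties are broken uniformly at
#' random. Vertices are visited in ascending index order and one uniform
#' draw is consumed per candidate vertex, so runs are reproducible given
#' the seed.
#'
#' @param mesh a [VertexMesh-class].
#' @param params a [VertexModelParams-class]; uses \code{p4Rate},
#'   \code{p5plusRate}, \code{dt}, \code{lNew}.
#' @return list with \code{mesh} and \code{records} (data.frame of
#'   resolutions: time, rank, gaining pair, detached cell).
#' @export
resolveVertices <- function(mesh, params) {
  rank <- vertexRank(mesh)
  high <- which(rank >= 4)
  records <- list()
  for (v in high) {
    r <- sum(mesh@edges == v)  # rank may have changed by earlier splits
    if (r < 4) next
    rate <- if (r == 4) params@p4Rate else params@p5plusRate
    u <- stats::runif(1)
    if (u >= .ratePerStep(rate, params@dt)) next
    ord <- .cyclicCellsAtVertex(mesh, v)
    mi <- mesh@mergeInfo[mesh@mergeInfo$vertex == v, , drop = FALSE]
    if (r == 4 && nrow(mi) == 1) {
      cand <- which(ord$cells %in% c(mi$losingA, mi$losingB))
    } else {
      cand <- seq_along(ord$cells)
    }
    en <- vapply(cand, function(k)
      tryCatch(.localEnergy(.splitVertex(mesh, v, k, ord, params)$mesh,
                            ord$cells, params),
               error = function(e) Inf),
      numeric(1))
    cand <- cand[is.finite(en)]; en <- en[is.finite(en)]
    if (!length(cand)) next  # no geometrically admissible split this step
    best <- cand[en <= min(en) + 1e-12]
    k <- if (length(best) > 1) best[floor(stats::runif(1) * length(best)) + 1] else best
    res <- .splitVertex(mesh, v, k, ord, params)
    mesh <- res$mesh
    records[[length(records) + 1L]] <- data.frame(
      time = mesh@time, type = "resolve", rank = r,
      cellA = res$gainingA, cellB = res$gainingB, vertex = res$splitCell)
  }
  list(mesh = mesh,
       records = if (length(records)) do.call(rbind, records) else
         data.frame(time = numeric(), type = character(), rank = integer(),
                    cellA = integer(), cellB = integer(), vertex = integer()))
}

#' Census of cells by their maximum vertex rank
#'
#' A cell's class is the maximum number of cells sharing any of its
#' vertices: 3 for ordinary cells, 4 for protorosette members, 5+ for
#' rosette members.
#'
#' @param mesh a [VertexMesh-class].
#' @return list with \code{perCell} (integer max rank per cell) and
#'   \code{counts} (named counts for classes "3", "4", "5+"; they sum to
#'   the number of cells).
#' @examples
#' censusVertexRanks(hexTissue(4, 4))$counts
#' @export
censusVertexRanks <- function(mesh) {
  rank <- vertexRank(mesh)
  perCell <- vapply(mesh@cells, function(lp) max(rank[lp]), integer(1))
  counts <- c("3" = sum(perCell <= 3), "4" = sum(perCell == 4),
              "5+" = sum(perCell >= 5))
  list(perCell = perCell, counts = counts)
}
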