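# Vertex-model mechanics: geometry of the periodic tiling, the energy
# functional, its gradient (overdamped dynamics), and the tissue-level
# stress tensor.

# Flattened loop geometry, recomputed per step; the flattening indices are
# cheap relative to the arithmetic so no cache is kept across topology
# changes.
#
# Returns per-entry quantities on the flattened (cell, slot) loops:
#   vid, cid      vertex / cell index of each entry
#   dNext         minimum-image vector to the next loop vertex
#   dPrev         minimum-image vector from the previous loop vertex
#   area, perim   per-cell area and perimeter (length nCells)
.meshGeometry <- function(mesh) {
  V <- mesh@vertices
  box <- mesh@box
  lens <- lengths(mesh@cells)
  vid <- unlist(mesh@cells, use.names = FALSE)
  cid <- rep.int(seq_along(mesh@cells), lens)
  n <- length(vid)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  nxt <- seq_len(n) + 1L; nxt[ends] <- starts
  prv <- seq_len(n) - 1L; prv[starts] <- ends

  dNext <- .minImage(V[vid[nxt], , drop = FALSE] - V[vid, , drop = FALSE], box)
  dPrev <- dNext[prv, , drop = FALSE]

  # positions relative to each cell's first loop vertex (unwrapped)
  shift <- dNext[prv, , drop = FALSE]
  shift[starts, ] <- 0
  relx <- .groupedCumsum(shift[, 1], lens)
  rely <- .groupedCumsum(shift[, 2], lens)

  crossTerm <- relx * dNext[, 2] - dNext[, 1] * rely
  area <- as.numeric(rowsum(crossTerm, cid, reorder = TRUE)) / 2
  segLen <- sqrt(dNext[, 1]^2 + dNext[, 2]^2)
  perim <- as.numeric(rowsum(segLen, cid, reorder = TRUE))

  list(vid = vid, cid = cid, dNext = dNext, dPrev = dPrev,
       segLen = segLen, area = area, perim = perim,
       relx = relx, rely = rely, starts = starts, lens = lens)
}

# Per-edge minimum-image vectors and lengths.
.edgeGeometry <- function(mesh) {
  V <- mesh@vertices
  d <- .minImage(V[mesh@edges[, 2], , drop = FALSE] -
                 V[mesh@edges[, 1], , drop = FALSE], mesh@box)
  list(vec = d, len = sqrt(d[, 1]^2 + d[, 2]^2))
}

# Per-edge line tension: Lambda plus the cable term on stripe-mismatch
# interfaces.
.edgeTension <- function(mesh, params) {
  mism <- mesh@stripe[mesh@edgeCells[, 1]] != mesh@stripe[mesh@edgeCells[, 2]]
  params@lambda + params@lambdaCable * mism
}

#' Total mechanical energy of a tissue
#'
#' \eqn{E = \sum_c K/2 (A_c - A_0)^2 + \sum_e \Lambda_e \ell_e +
#' \sum_c \Gamma/2 L_c^2}, with \eqn{\Lambda_e} including the cable tension
#' on interfaces between cells of different stripe identity.
#'
#' @param mesh a [VertexMesh-class].
#' @param params a [VertexModelParams-class].
#' @return scalar energy (model units).
#' @examples
#' m <- hexTissue(4, 4)
#' tissueEnergy(m, vertexModelParams())
#' @export
tissueEnergy <- function(mesh, params) {
  g <- .meshGeometry(mesh)
  if (any(g$area <= 0))
    stop("tissueEnergy: degenerate cell with non-positive area")
  eg <- .edgeGeometry(mesh)
  lam <- .edgeTension(mesh, params)
  sum(params@K / 2 * (g$area - params@A0)^2) +
    sum(lam * eg$len) +
    sum(params@gamma / 2 * g$perim^2)
}

# Energy gradient with respect to every vertex position (nV x 2).
.tissueGradient <- function(mesh, params) {
  g <- .meshGeometry(mesh)
  nV <- nrow(mesh@vertices)
  K <- params@K; A0 <- params@A0; gam <- params@gamma

  # area term: dA_c/dr_v = ((yNext - yPrev)/2, (xPrev - xNext)/2)
  coefA <- K * (g$area - A0)[g$cid]
  gax <- coefA * (g$dNext[, 2] + g$dPrev[, 2]) / 2
  gay <- coefA * (-(g$dNext[, 1] + g$dPrev[, 1])) / 2

  # perimeter term: dL_c/dr_v = unit(dPrev) - unit(dNext)
  lenPrev <- sqrt(g$dPrev[, 1]^2 + g$dPrev[, 2]^2)
  coefP <- gam * g$perim[g$cid]
  gpx <- coefP * (g$dPrev[, 1] / lenPrev - g$dNext[, 1] / g$segLen)
  gpy <- coefP * (g$dPrev[, 2] / lenPrev - g$dNext[, 2] / g$segLen)

  grad <- matrix(0, nV, 2)
  acc <- rowsum(cbind(gax + gpx, gay + gpy), g$vid, reorder = FALSE)
  grad[as.integer(rownames(acc)), ] <- acc

  # line-tension term on edges
  eg <- .edgeGeometry(mesh)
  lam <- .edgeTension(mesh, params)
  ux <- lam * eg$vec[, 1] / eg$len
  uy <- lam * eg$vec[, 2] / eg$len
  te <- rowsum(cbind(c(-ux, ux), c(-uy, uy)),
               c(mesh@edges[, 1], mesh@edges[, 2]), reorder = FALSE)
  ids <- as.integer(rownames(te))
  grad[ids, ] <- grad[ids, ] + te
  grad
}

#' One overdamped relaxation step
#'
#' Moves every vertex by \code{-dt * dE/dr} (unit friction) and wraps the
#' positions back into the periodic box. With no topology events in the
#' step, the energy is non-increasing for a stable \code{dt}.
#'
#' @param mesh a [VertexMesh-class].
#' @param params a [VertexModelParams-class]; uses \code{dt}.
#' @param checkEnergy if TRUE, recompute the energy and stop with a
#'   step-size diagnostic when it increased beyond \code{tol}.
#' @param tol tolerance on energy increase (default 1e-10).
#' @return the updated mesh (time advanced by \code{dt}).
#' @export
relaxStep <- function(mesh, params, checkEnergy = FALSE, tol = 1e-10) {
  e0 <- if (checkEnergy) tissueEnergy(mesh, params) else NULL
  grad <- .tissueGradient(mesh, params)
  v <- mesh@vertices - params@dt * grad
  v[, 1] <- v[, 1] %% mesh@box[1]
  v[, 2] <- v[, 2] %% mesh@box[2]
  mesh@vertices <- v
  mesh@time <- mesh@time + params@dt
  if (checkEnergy) {
    e1 <- tissueEnergy(mesh, params)
    if (e1 > e0 + tol)
      stop(sprintf(
        "relaxStep: energy increased by %.3g at t = %.3f min; dt too large",
        e1 - e0, mesh@time))
  }
  mesh
}

#' One overdamped relaxation step of the DV box length
#'
#' The dorsoventral box length is a slow degree of freedom of the periodic
#' tissue: it moves down the energy gradient,
#' \eqn{\dot L_y / L_y = -\mu\,\sigma_{yy}}, with all y-coordinates
#' rescaled affinely. A positive DV normal stress (net tissue tension)
#' therefore converges the tissue along DV, which is what lets the
#' planar-polarised junctions shorten to the merge threshold; like
#' [relaxStep()] this never increases the energy for a stable step. The
#' anteroposterior box length is left to the posterior pull.
#'
#' @param mesh a [VertexMesh-class].
#' @param params a [VertexModelParams-class]; uses \code{boxFriction} and
#'   \code{dt}.
#' @return the updated mesh (time unchanged).
#' @export
boxRelaxStep <- function(mesh, params) {
  if (params@boxFriction <= 0) return(mesh)
  syy <- tissueStress(mesh, params)[2, 2]
  fac <- 1 - params@dt * params@boxFriction * syy
  if (fac < 0.5 || fac > 2)
    stop("boxRelaxStep: box strain step too large; reduce dt or boxFriction")
  mesh@vertices[, 2] <- mesh@vertices[, 2] * fac
  mesh@box[2] <- mesh@box[2] * fac
  mesh
}

#' Tissue-level stress tensor
#'
#' Virial (Batchelor) expression for the global 2D stress of the tiling:
#' isotropic cell-pressure part plus line-tension dyads, normalised by the
#' box area,
#' \deqn{\sigma_{\alpha\beta} = \frac{1}{L_x L_y}\Big[\sum_c K (A_c - A_0)
#'   A_c \delta_{\alpha\beta} + \sum_e T_e
#'   \frac{\ell_\alpha \ell_\beta}{\ell_e}\Big]}
#' where the effective edge tension \eqn{T_e = \Lambda_e + \Gamma (L_{c_1} +
#' L_{c_2})} includes the perimeter elasticity of both incident cells. The
#' expression equals the derivative of the energy with respect to an affine
#' box strain divided by the box area (checked against a finite-difference
#' oracle in the test suite).
#'
#' @param mesh a [VertexMesh-class].
#' @param params a [VertexModelParams-class].
#' @return 2 x 2 symmetric stress matrix.
#' @export
tissueStress <- function(mesh, params) {
  g <- .meshGeometry(mesh)
  if (any(g$area <= 0) || any(g$segLen <= 0))
    stop("tissueStress: degenerate mesh geometry")
  eg <- .edgeGeometry(mesh)
  lam <- .edgeTension(mesh, params)
  tEff <- lam + params@gamma * (g$perim[mesh@edgeCells[, 1]] +
                                g$perim[mesh@edgeCells[, 2]])
  iso <- sum(params@K * (g$area - params@A0) * g$area)
  sxx <- iso + sum(tEff * eg$vec[, 1]^2 / eg$len)
  syy <- iso + sum(tEff * eg$vec[, 2]^2 / eg$len)
  sxy <- sum(tEff * eg$vec[, 1] * eg$vec[, 2] / eg$len)
  matrix(c(sxx, sxy, sxy, syy), 2, 2) / prod(mesh@box)
}
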