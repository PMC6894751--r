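# Extrinsic posterior pull: the applied stress is converted to a strain by
# probing the tissue's anteroposterior stiffness in its current
# configuration, so the imposed deformation adapts to the evolving
# mechanics (softer tissue strains more under the same pull).

# The pulled region is the x-band spanned by the posterior cells' vertices.
# Returns list(x0, w): band start (anchor) and width, handling wrap-around
# by cutting the band at the largest cyclic gap between member vertices.
.posteriorBand <- function(mesh, posteriorCells) {
  vset <- unique(unlist(mesh@cells[posteriorCells]))
  xs <- sort(mesh@vertices[vset, 1])
  Lx <- mesh@box[1]
  gaps <- c(diff(xs), xs[1] + Lx - xs[length(xs)])
  i <- which.max(gaps)
  x0 <- if (i == length(xs)) xs[1] else xs[i + 1]
  w <- (max((xs - x0) %% Lx))
  list(x0 = x0, w = w)
}

# Affine x-stretch of the band [x0, x0 + w] by strain E; everything outside
# the band is translated by E * w and the box grows by the same amount, so
# the periodic tiling stays consistent.
.stretchBand <- function(mesh, band, E) {
  Lx <- mesh@box[1]
  u <- (mesh@vertices[, 1] - band$x0) %% Lx
  inBand <- u <= band$w
  u[inBand] <- u[inBand] * (1 + E)
  u[!inBand] <- u[!inBand] + E * band$w
  LxNew <- Lx + E * band$w
  mesh@vertices[, 1] <- (band$x0 + u) %% LxNew
  mesh@box[1] <- LxNew
  mesh
}

#' Apply the posterior pulling stress to a tissue
#'
#' A small probe strain \code{probeStrain} is first applied to the
#' posterior region (mapping x-coordinates as \eqn{x \to x + E_x x} within
#' the band, with the box rescaled consistently); the anteroposterior
#' stiffness is estimated as \eqn{C_{xx} = \Delta\sigma_{xx} / E_x} and the
#' tissue is reverted exactly to its stored configuration. The true
#' posterior strain \eqn{E^{post} = \sigma^{post} / C_{xx}} is then applied
#' with the same map. With \code{sigma = 0} the input mesh is returned
#' unchanged.
#'
#' @param mesh a [VertexMesh-class].
#' @param params a [VertexModelParams-class] (mechanical coefficients for
#'   the stress evaluation).
#' @param sigma applied posterior stress (>= 0).
#' @param posteriorCells integer ids of the cells forming the posterior
#'   region (conventionally the posterior-most two columns).
#' @param probeStrain probe strain magnitude (default 1e-3).
#' @return list with \code{mesh} (updated) and \code{probe}, a list with
#'   fields \code{Ex}, \code{sigmaXxBefore}, \code{sigmaXxAfter},
#'   \code{Cxx} and \code{Eposterior}.
#' @export
applyPosteriorPull <- function(mesh, params, sigma, posteriorCells,
                               probeStrain = 1e-3) {
  if (sigma < 0) stop("applyPosteriorPull: sigma must be >= 0")
  band <- .posteriorBand(mesh, posteriorCells)
  before <- tissueStress(mesh, params)[1, 1]

  saveV <- mesh@vertices
  saveBox <- mesh@box
  probed <- .stretchBand(mesh, band, probeStrain)
  after <- tissueStress(probed, params)[1, 1]
  # exact revert: restore the stored configuration
  mesh@vertices <- saveV
  mesh@box <- saveBox

  Cxx <- (after - before) / probeStrain
  if (Cxx <= 0)
    stop(sprintf("applyPosteriorPull: non-positive stiffness estimate (Cxx = %.3g)", Cxx))
  Epost <- sigma / Cxx
  if (sigma > 0) mesh <- .stretchBand(mesh, band, Epost)
  list(mesh = mesh,
       probe = list(Ex = probeStrain, sigmaXxBefore = before,
                    sigmaXxAfter = after, Cxx = Cxx, Eposterior = Epost))
}
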