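#' Construct a vertex-model parameter set
#'
#' All arguments are in dimensionless model units (length unit = the side of
#' a unit-area regular hexagon times \eqn{1/s}, see the unit map in
#' [simulationTracks()]) and minutes. Defaults correspond to the wild-type
#' germband simulation; see [gbePreset()] for the named presets.
#'
#' @param lambda line tension \eqn{\Lambda} (default 0.05).
#' @param gamma perimeter contractility \eqn{\Gamma} (default 0.04).
#' @param K area elastic modulus (default 1).
#' @param A0 preferred cell area (default 1).
#' @param lambdaCable supplementary tension on interfaces between cells of
#'   different stripe identity (default \code{8 * lambda} = 0.4), mimicking
#'   the planar-polarised actomyosin cables at parasegment-type boundaries.
#'   The default is the smallest value at which the cable tension makes
#'   DV-oriented junctions locally unstable, so that they collapse to the
#'   merge threshold and sustain intercalation during a 30-minute run.
#' @param p4Rate resolution rate of rank-4 vertices, per minute.
#' @param p5plusRate resolution rate of rank-5+ vertices, per minute.
#' @param sigmaPosterior plateau posterior stress magnitude. The stress is
#'   converted to an applied strain at every step via the probed tissue
#'   stiffness (see [applyPosteriorPull()]); the default is calibrated so
#'   that the wild-type preset extends at roughly 0.02-0.03 per minute
#'   initially.
#' @param pullPlateauMins minutes of constant posterior stress (default 15).
#' @param pullEndMins minute at which the linear ramp reaches zero (30).
#' @param lMerge edge-collapse threshold (default 0.2, about a third of
#'   the unit-area hexagon side; chosen inside the range the passive
#'   dynamics actually reach).
#' @param lNew length of the junction created on resolution (default
#'   \code{1.5 * lMerge}).
#' @param boxFriction mobility of the DV box length under the tissue
#'   normal stress (default 0.1; see [boxRelaxStep()]). The dorsoventral
#'   box length relaxes down the energy gradient, supplying the DV
#'   convergence that accompanies AP extension.
#' @param dt time step in minutes (default 0.01).
#' @param tEnd simulated minutes (default 30).
#' @param seed RNG seed.
#' @return a [VertexModelParams-class] object.
#' @examples
#' p <- vertexModelParams()
#' p
#' @export
vertexModelParams <- function(lambda = 0.05, gamma = 0.04, K = 1, A0 = 1,
                              lambdaCable = 8 * lambda,
                              p4Rate = 1, p5plusRate = 0.1,
                              sigmaPosterior = 4e-4,
                              pullPlateauMins = 15, pullEndMins = 30,
                              lMerge = 0.2, lNew = 1.5 * lMerge,
                              boxFriction = 0.1,
                              dt = 0.01, tEnd = 30, seed = 1L) {
  new("VertexModelParams",
      lambda = lambda, gamma = gamma, K = K, A0 = A0,
      lambdaCable = lambdaCable, p4Rate = p4Rate, p5plusRate = p5plusRate,
      sigmaPosterior = sigmaPosterior, pullPlateauMins = pullPlateauMins,
      pullEndMins = pullEndMins, lMerge = lMerge, lNew = lNew,
      boxFriction = boxFriction, dt = dt, tEnd = tEnd, seed = seed)
}

#' Named germband-extension parameter presets
#'
#' \describe{
#'   \item{WT}{wild type: \eqn{(\Lambda, \Gamma) = (0.05, 0.04)},
#'     \eqn{p_4 = 1}/min, \eqn{p_{5+} = 0.1}/min.}
#'   \item{sdk}{\emph{sdk} mutant: resolution slowed, \eqn{p_4 = 0.1}/min,
#'     \eqn{p_{5+} = 0}/min; mechanics as WT.}
#'   \item{sdk_soft}{\emph{sdk} mutant with reduced shear modulus:
#'     additionally \eqn{\Gamma = 0.01}.}
#' }
#'
#' @param preset one of "WT", "sdk", "sdk_soft".
#' @param ... overrides passed on to [vertexModelParams()] (e.g. seed, tEnd).
#' @return a [VertexModelParams-class] object.
#' @examples
#' gbePreset("sdk", seed = 7)
#' @export
gbePreset <- function(preset = c("WT", "sdk", "sdk_soft"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    WT = list(),
    sdk = list(p4Rate = 0.1, p5plusRate = 0),
    sdk_soft = list(p4Rate = 0.1, p5plusRate = 0, gamma = 0.01))
  args <- utils::modifyList(base, list(...))
  do.call(vertexModelParams, args)
}

#' Posterior stress schedule
#'
#' Constant at \code{sigmaPosterior} for the plateau, then a linear ramp to
#' zero at \code{pullEndMins}, zero afterwards.
#'
#' @param params a [VertexModelParams-class].
#' @param t time in minutes.
#' @return stress magnitude at time \code{t}.
#' @export
posteriorStress <- function(params, t) {
  s0 <- params@sigmaPosterior
  t1 <- params@pullPlateauMins
  t2 <- params@pullEndMins
  ifelse(t < t1, s0,
         ifelse(t < t2, s0 * (t2 - t) / (t2 - t1), 0))
}

# Rate (per minute) -> per-step probability, invariant under dt refinement.
.ratePerStep <- function(rate, dt) 1 - exp(-rate * dt)
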