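#' @import methods
NULL

#' Vertex-model tissue state on a periodic box
#'
#' A polygonal tiling of a torus: cells are ordered vertex loops, edges are
#' unordered vertex pairs with their two incident cells, and positions live
#' in a rectangular periodic box. Coordinates and parameters are in
#' dimensionless model units (the preferred cell area is 1 by default) and
#' time is in minutes.
#'
#' @slot vertices numeric matrix (nV x 2) of vertex positions, wrapped into
#'   the box.
#' @slot edges integer matrix (nE x 2) of vertex indices.
#' @slot edgeCells integer matrix (nE x 2) of the two cells incident to each
#'   edge.
#' @slot cells list of integer vectors: ordered (counter-clockwise) vertex
#'   loops, one per cell.
#' @slot stripe integer vector of anteroposterior stripe identities (1..4),
#'   one per cell.
#' @slot cellData data.frame of per-cell metadata (lattice row/column at
#'   construction time), used e.g. to define the posterior region.
#' @slot box numeric length-2: box lengths (Lx, Ly).
#' @slot time simulation time in minutes.
#' @slot mergeInfo data.frame recording, for unresolved rank-4 vertices, the
#'   cell pair that lost its shared junction in the collapse (columns
#'   vertex, losingA, losingB). Used to complete the T1 on resolution.
#'
#' @seealso [hexTissue()], [simulateGBE()]
#' @export
setClass("VertexMesh", representation(
  vertices = "matrix",
  edges = "matrix",
  edgeCells = "matrix",
  cells = "list",
  stripe = "integer",
  cellData = "data.frame",
  box = "numeric",
  time = "numeric",
  mergeInfo = "data.frame"
))

setValidity("VertexMesh", function(object) {
  msg <- character()
  nV <- nrow(object@vertices)
  nE <- nrow(object@edges)
  nF <- length(object@cells)
  if (ncol(object@vertices) != 2) msg <- c(msg, "vertices must be an n x 2 matrix")
  if (nE > 0 && (max(object@edges) > nV || min(object@edges) < 1))
    msg <- c(msg, "edge vertex index out of range")
  if (nF > 0 && length(object@stripe) != nF)
    msg <- c(msg, "stripe must have one entry per cell")
  if (nV - nE + nF != 0)
    msg <- c(msg, sprintf("Euler characteristic violated on torus: V-E+F = %d", nV - nE + nF))
  rk <- tabulate(object@edges, nbins = nV)
  if (nV > 0 && any(rk < 3))
    msg <- c(msg, "all vertices must have rank >= 3")
  if (nE > 0 && any(object@edgeCells[, 1] == object@edgeCells[, 2]))
    msg <- c(msg, "an edge must border two distinct cells")
  if (length(object@box) != 2 || any(object@box <= 0))
    msg <- c(msg, "box must be two positive lengths")
  if (length(msg)) msg else TRUE
})

#' @describeIn VertexMesh compact description of the tissue
#' @param object a \code{VertexMesh}
#' @export
setMethod("show", "VertexMesh", function(object) {
  cen <- censusVertexRanks(object)
  cat(sprintf(
    "VertexMesh: %d cells, %d vertices, %d edges | box %.3f x %.3f | t = %.2f min\n",
    length(object@cells), nrow(object@vertices), nrow(object@edges),
    object@box[1], object@box[2], object@time))
  cat(sprintf("  cell classes (max vertex rank): 3: %d, 4: %d, 5+: %d\n",
              cen$counts[["3"]], cen$counts[["4"]], cen$counts[["5+"]]))
})

#' Number of cells, vertices and edges of a mesh
#' @param mesh a \code{VertexMesh}
#' @return integer count.
#' @export
nCells <- function(mesh) length(mesh@cells)

#' @rdname nCells
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @rdname nCells
#' @export
nEdges <- function(mesh) nrow(mesh@edges)

#' Mesh accessors
#'
#' Read-only access to the slots of a [VertexMesh-class].
#'
#' @param mesh a \code{VertexMesh}
#' @return \code{meshVertices}: nV x 2 matrix; \code{meshEdges}: nE x 2
#'   integer matrix; \code{meshEdgeCells}: nE x 2 integer matrix;
#'   \code{meshCells}: list of integer loops; \code{meshBox}: numeric
#'   length 2; \code{stripeIds}: integer per cell; \code{meshTime}: minutes.
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @rdname meshVertices
#' @export
meshEdges <- function(mesh) mesh@edges

#' @rdname meshVertices
#' @export
meshEdgeCells <- function(mesh) mesh@edgeCells

#' @rdname meshVertices
#' @export
meshCells <- function(mesh) mesh@cells

#' @rdname meshVertices
#' @export
meshBox <- function(mesh) mesh@box

#' @rdname meshVertices
#' @export
stripeIds <- function(mesh) mesh@stripe

#' @rdname meshVertices
#' @export
meshTime <- function(mesh) mesh@time

#' Per-vertex rank (number of incident cells)
#'
#' On a torus tiling the number of cells around a vertex equals the number
#' of incident edges.
#'
#' @param mesh a \code{VertexMesh}
#' @return integer vector of length \code{nVertices(mesh)}.
#' @export
vertexRank <- function(mesh) tabulate(mesh@edges, nbins = nrow(mesh@vertices))

#' Parameters of the germband vertex model
#'
#' Mechanical and kinetic parameters of the simulation. The energy is the
#' standard vertex-model functional
#' \deqn{E = \sum_c \frac{K}{2}(A_c - A_0)^2 + \sum_e \Lambda_e \ell_e +
#'       \sum_c \frac{\Gamma}{2} L_c^2}
#' with a supplementary cable tension \code{lambdaCable} added to
#' \eqn{\Lambda} on interfaces between cells of different stripe identity.
#'
#' @slot lambda line-tension coefficient \eqn{\Lambda}.
#' @slot gamma perimeter contractility \eqn{\Gamma}.
#' @slot K area elastic modulus (default 1).
#' @slot A0 preferred cell area (default 1).
#' @slot lambdaCable supplementary tension on stripe-mismatch interfaces.
#' @slot p4Rate resolution rate of rank-4 vertices, per minute.
#' @slot p5plusRate resolution rate of rank-5+ vertices, per minute.
#' @slot sigmaPosterior plateau magnitude of the posterior stress schedule.
#' @slot pullPlateauMins minutes during which the posterior stress is held
#'   at its plateau before ramping linearly to zero at \code{pullEndMins}.
#' @slot pullEndMins minute at which the posterior stress reaches zero.
#' @slot lMerge edge-collapse threshold length.
#' @slot lNew length of the junction created on resolution.
#' @slot boxFriction mobility of the DV box length under the tissue normal
#'   stress (per minute per stress unit); 0 freezes the box.
#' @slot dt time step in minutes.
#' @slot tEnd total simulated minutes.
#' @slot seed RNG seed for the run.
#' @seealso [vertexModelParams()], [gbePreset()]
#' @export
setClass("VertexModelParams", representation(
  lambda = "numeric", gamma = "numeric", K = "numeric", A0 = "numeric",
  lambdaCable = "numeric", p4Rate = "numeric", p5plusRate = "numeric",
  sigmaPosterior = "numeric", pullPlateauMins = "numeric",
  pullEndMins = "numeric", lMerge = "numeric", lNew = "numeric",
  boxFriction = "numeric", dt = "numeric", tEnd = "numeric", seed = "numeric"
))

setValidity("VertexModelParams", function(object) {
  msg <- character()
  pos <- c(K = object@K, A0 = object@A0, lMerge = object@lMerge,
           lNew = object@lNew, dt = object@dt)
  if (any(pos <= 0))
    msg <- c(msg, paste("must be > 0:", paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@p4Rate < 0 || object@p5plusRate < 0)
    msg <- c(msg, "resolution rates must be >= 0")
  if (object@sigmaPosterior < 0)
    msg <- c(msg, "sigmaPosterior must be >= 0")
  if (object@lNew <= object@lMerge)
    msg <- c(msg, "lNew must exceed lMerge (new edges would re-collapse immediately)")
  if (length(msg)) msg else TRUE
})

#' @describeIn VertexModelParams print the parameter set
#' @param object a \code{VertexModelParams}
#' @export
setMethod("show", "VertexModelParams", function(object) {
  cat(sprintf(
    paste0("VertexModelParams: Lambda=%.3g Gamma=%.3g cable=%.3g K=%.3g A0=%.3g\n",
           "  p4=%.3g/min p5+=%.3g/min sigmaPost=%.3g (plateau %g min, end %g min)\n",
           "  lMerge=%.3g lNew=%.3g dt=%.3g min tEnd=%g min seed=%d\n"),
    object@lambda, object@gamma, object@lambdaCable, object@K, object@A0,
    object@p4Rate, object@p5plusRate, object@sigmaPosterior,
    object@pullPlateauMins, object@pullEndMins,
    object@lMerge, object@lNew, object@dt, object@tEnd, as.integer(object@seed)))
})

#' Tracked-cell data for one embryo or simulation export
#'
#' Per-frame cells (stable id, polygon outline, centroid, type, temporal
#' links) and cell-cell interfaces (id, incident cell pair, endpoints,
#' links), with the embryonic axis frame and the frame cadence. Coordinates
#' are in micrometres; frames are indexed from 0.
#'
#' @slot frameIntervalS seconds between frames (default 30).
#' @slot axisFrame list with unit vectors \code{ap} and \code{dv} and the
#'   \code{midlineY} position (micrometres).
#' @slot cells data.frame with columns frame, cell_id, x, y, outline,
#'   cell_type, prev_id, next_id. \code{outline} is a comma-separated
#'   "x y" vertex list in loop order.
#' @slot interfaces data.frame with columns frame, interface_id, cell_a,
#'   cell_b, x1, y1, x2, y2, prev_id, next_id.
#' @slot meta list of free-form metadata (units, provenance).
#' @seealso [readTracks()], [writeTracks()], [generateAffineFlowTracks()],
#'   [generateScriptedT1Lattice()]
#' @export
setClass("EmbryoTracks", representation(
  frameIntervalS = "numeric",
  axisFrame = "list",
  cells = "data.frame",
  interfaces = "data.frame",
  meta = "list"
))

setValidity("EmbryoTracks", function(object) {
  msg <- validateTracksTables(object@cells, object@interfaces, object@axisFrame,
                              object@frameIntervalS)
  if (length(msg)) msg else TRUE
})

#' @describeIn EmbryoTracks summary of frames, cells and interfaces
#' @param object an \code{EmbryoTracks}
#' @export
setMethod("show", "EmbryoTracks", function(object) {
  fr <- sort(unique(object@cells$frame))
  cat(sprintf(
    "EmbryoTracks: %d frames (%.0f s apart), %d cell records (%d cells), %d interface records\n",
    length(fr), object@frameIntervalS, nrow(object@cells),
    length(unique(object@cells$cell_id)), nrow(object@interfaces)))
  cat(sprintf("  axis frame: AP = (%.2f, %.2f), DV = (%.2f, %.2f), midline y = %.2f um\n",
              object@axisFrame$ap[1], object@axisFrame$ap[2],
              object@axisFrame$dv[1], object@axisFrame$dv[2],
              object@axisFrame$midlineY))
})

#' Tracks accessors
#' @param tracks an \code{EmbryoTracks}
#' @return \code{trackCells} / \code{trackInterfaces}: the underlying
#'   data.frames; \code{frameInterval}: seconds between frames;
#'   \code{axisFrame}: list(ap, dv, midlineY); \code{trackFrames}: sorted
#'   frame indices.
#' @export
trackCells <- function(tracks) tracks@cells

#' @rdname trackCells
#' @export
trackInterfaces <- function(tracks) tracks@interfaces

#' @rdname trackCells
#' @export
frameInterval <- function(tracks) tracks@frameIntervalS

#' @rdname trackCells
#' @export
axisFrame <- function(tracks) tracks@axisFrame

#' @rdname trackCells
#' @export
trackFrames <- function(tracks) sort(unique(tracks@cells$frame))

#' A completed germband-extension simulation
#'
#' Holds the mesh snapshots (one per output frame), the event log of edge
#' merges and vertex resolutions, per-snapshot diagnostics, and the
#' parameters of the run.
#'
#' @slot snapshots list of [VertexMesh-class] states at the output cadence.
#' @slot snapshotMins minutes between snapshots.
#' @slot events data.frame: time, type ("merge"/"resolve"), rank, cells.
#' @slot diagnostics data.frame per snapshot: time, energy, boxLx, counts of
#'   rank-4 and rank-5+ vertices.
#' @slot params the [VertexModelParams-class] used.
#' @slot posteriorCells integer ids of the cells forming the pulled region.
#' @seealso [simulateGBE()], [simulationTracks()]
#' @export
setClass("GbeSimulation", representation(
  snapshots = "list",
  snapshotMins = "numeric",
  events = "data.frame",
  diagnostics = "data.frame",
  params = "VertexModelParams",
  posteriorCells = "integer"
))

#' @describeIn GbeSimulation run summary
#' @param object a \code{GbeSimulation}
#' @export
setMethod("show", "GbeSimulation", function(object) {
  nm <- length(object@snapshots)
  last <- object@snapshots[[nm]]
  cat(sprintf("GbeSimulation: %d snapshots every %.2f min, %d cells, %d events\n",
              nm, object@snapshotMins, length(last@cells), nrow(object@events)))
  cat(sprintf("  final box Lx = %.3f (initial %.3f); final rank-4: %d, rank-5+: %d\n",
              last@box[1], object@snapshots[[1]]@box[1],
              sum(vertexRank(last) == 4), sum(vertexRank(last) >= 5)))
})
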