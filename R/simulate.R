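#' Simulate germband extension
#'
#' Runs the vertex model from a fresh periodic hexagonal tissue: each time
#' step relaxes the vertices down the energy gradient, collapses junctions
#' shorter than the merge threshold into higher-order vertices, resolves
#' rank-4 and rank-5+ vertices stochastically at their prescribed rates,
#' and applies the posterior pulling stress through the stiffness-probed
#' strain. Snapshots are stored at a fixed cadence (default 0.5 min,
#' mimicking 30-s movie frames). Runs are deterministic given the seed.
#'
#' @param params a [VertexModelParams-class], e.g. from [gbePreset()].
#' @param nx,ny tissue dimensions in columns x rows (default 14 x 20,
#'   i.e. 280 cells).
#' @param snapshotMins minutes between stored snapshots (default 0.5).
#' @param posteriorCols how many posterior-most columns form the pulled
#'   region (default 2).
#' @param initJitter standard deviation (model units) of the Gaussian
#'   displacement applied to the initial vertex positions (default 0.05).
#'   A perfectly regular lattice shrinks all its polarised junctions in
#'   lock-step; the jitter seeds the heterogeneity that lets individual
#'   junctions reach the merge threshold first, as in a real epithelium.
#' @param checkInvariants verify the torus topology (V - E + F = 0,
#'   constant cell count) after every step (default TRUE; cheap).
#' @return a [GbeSimulation-class].
#' @examples
#' sim <- simulateGBE(gbePreset("WT", tEnd = 1), nx = 4, ny = 4)
#' sim
#' @export
simulateGBE <- function(params, nx = 14, ny = 20, snapshotMins = 0.5,
                        posteriorCols = 2, initJitter = 0.05,
                        checkInvariants = TRUE) {
  mesh <- hexTissue(nx, ny, A0 = params@A0)
  posteriorCells <- which(mesh@cellData$col >= nx - posteriorCols)
  nF <- length(mesh@cells)

  # seed a run-local RNG stream, restoring the caller's state on exit
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(params@seed))
  if (initJitter > 0) {
    jit <- matrix(stats::rnorm(2L * nrow(mesh@vertices), sd = initJitter),
                  ncol = 2)
    mesh@vertices <- (mesh@vertices + jit) %%
      matrix(mesh@box, nrow(mesh@vertices), 2, byrow = TRUE)
  }

  nSteps <- round(params@tEnd / params@dt)
  snapEvery <- max(1L, round(snapshotMins / params@dt))
  events <- list()
  snapshots <- list(mesh)
  diag <- list(.simDiagnostics(mesh, params))

  for (step in seq_len(nSteps)) {
    mesh <- relaxStep(mesh, params)
    mesh <- boxRelaxStep(mesh, params)
    mg <- attemptEdgeMerges(mesh, params)
    mesh <- mg$mesh
    if (nrow(mg$records)) events[[length(events) + 1L]] <- mg$records
    rs <- resolveVertices(mesh, params)
    mesh <- rs$mesh
    if (nrow(rs$records)) events[[length(events) + 1L]] <- rs$records
    sig <- posteriorStress(params, mesh@time)
    if (sig > 0)
      mesh <- applyPosteriorPull(mesh, params, sig, posteriorCells)$mesh
    if (checkInvariants) {
      if (nrow(mesh@vertices) - nrow(mesh@edges) + length(mesh@cells) != 0)
        stop(sprintf("simulateGBE: Euler characteristic violated at step %d (t = %.3f min)",
                     step, mesh@time))
      if (length(mesh@cells) != nF)
        stop(sprintf("simulateGBE: cell count changed at step %d", step))
    }
    if (step %% snapEvery == 0) {
      snapshots[[length(snapshots) + 1L]] <- mesh
      diag[[length(diag) + 1L]] <- .simDiagnostics(mesh, params)
    }
  }
  new("GbeSimulation",
      snapshots = snapshots, snapshotMins = snapEvery * params@dt,
      events = if (length(events)) do.call(rbind, events) else
        data.frame(time = numeric(), type = character(), rank = integer(),
                   cellA = integer(), cellB = integer(), vertex = integer()),
      diagnostics = do.call(rbind, diag),
      params = params, posteriorCells = as.integer(posteriorCells))
}

.simDiagnostics <- function(mesh, params) {
  rk <- vertexRank(mesh)
  data.frame(time = mesh@time, energy = tissueEnergy(mesh, params),
             boxLx = mesh@box[1], rank4 = sum(rk == 4), rank5plus = sum(rk >= 5))
}

#' Export a simulation as tracked-cell tables
#'
#' Converts the mesh snapshots into an [EmbryoTracks-class] object in the
#' schema used for segmented embryo movies: per-frame cell centroids and
#' outlines in micrometres with temporal links, and cell-cell interfaces
#' identified by the incident cell pair. Centroids are unwrapped
#' continuously in time (a cell crossing the periodic seam keeps a smooth
#' trajectory). Unit map: 1 model length unit = \code{umPerUnit}
#' micrometres (default 3.4, one hexagon-side equivalent), 1 model time
#' unit = 1 minute.
#'
#' @param sim a [GbeSimulation-class].
#' @param umPerUnit micrometres per model length unit (default 3.4).
#' @param validate run the tracks schema validation on the export
#'   (default TRUE).
#' @return an [EmbryoTracks-class].
#' @export
simulationTracks <- function(sim, umPerUnit = 3.4, validate = TRUE) {
  snaps <- sim@snapshots
  nFrames <- length(snaps)
  prevCentroid <- NULL
  cellRows <- vector("list", nFrames)
  ifaceRows <- vector("list", nFrames)
  prevIfaceIds <- character()

  for (f in seq_len(nFrames)) {
    mesh <- snaps[[f]]
    box <- mesh@box
    nC <- length(mesh@cells)
    cen <- matrix(0, nC, 2)
    outlines <- character(nC)
    # adjusted absolute vertex positions per cell (unwrapped around the
    # continuity-corrected centroid)
    vpos <- vector("list", nC)
    for (ci in seq_len(nC)) {
      lp <- mesh@cells[[ci]]
      anchor <- mesh@vertices[lp[1], ]
      d <- .minImage(mesh@vertices[c(lp[-1], lp[1]), , drop = FALSE] -
                     mesh@vertices[lp, , drop = FALSE], box)
      rel <- apply(rbind(0, d[-length(lp), , drop = FALSE]), 2, cumsum)
      cRel <- polygonCentroid(rel)
      cRaw <- anchor + cRel
      if (!is.null(prevCentroid)) {
        k <- round((prevCentroid[ci, ] - cRaw) / box)
        cAdj <- cRaw + k * box
      } else cAdj <- cRaw
      cen[ci, ] <- cAdj
      pts <- sweep(rel, 2, cRel) + matrix(cAdj, length(lp), 2, byrow = TRUE)
      vpos[[ci]] <- pts * umPerUnit
      rownames(vpos[[ci]]) <- as.character(lp)
      outlines[ci] <- .formatOutline(pts * umPerUnit)
    }
    prevCentroid <- cen
    cenUm <- cen * umPerUnit
    cellRows[[f]] <- data.frame(
      frame = f - 1L, cell_id = seq_len(nC),
      x = cenUm[, 1], y = cenUm[, 2], outline = outlines,
      cell_type = "germband",
      prev_id = if (f == 1) -1L else seq_len(nC),
      next_id = if (f == nFrames) -1L else seq_len(nC))

    ca <- pmin(mesh@edgeCells[, 1], mesh@edgeCells[, 2])
    cb <- pmax(mesh@edgeCells[, 1], mesh@edgeCells[, 2])
    ids <- paste0("i", ca, "_", cb)
    e1 <- matrix(0, nrow(mesh@edges), 2)
    e2 <- matrix(0, nrow(mesh@edges), 2)
    for (ei in seq_len(nrow(mesh@edges))) {
      pm <- vpos[[ca[ei]]]
      e1[ei, ] <- pm[as.character(mesh@edges[ei, 1]), ]
      e2[ei, ] <- pm[as.character(mesh@edges[ei, 2]), ]
    }
    ifaceRows[[f]] <- data.frame(
      frame = f - 1L, interface_id = ids, cell_a = ca, cell_b = cb,
      x1 = e1[, 1], y1 = e1[, 2], x2 = e2[, 1], y2 = e2[, 2],
      prev_id = ifelse(ids %in% prevIfaceIds, ids, "-1"),
      next_id = "-1")
    if (f > 1) {
      keep <- ifaceRows[[f - 1]]$interface_id %in% ids
      ifaceRows[[f - 1]]$next_id[keep] <- ifaceRows[[f - 1]]$interface_id[keep]
    }
    prevIfaceIds <- ids
  }

  embryoTracks(
    cells = do.call(rbind, cellRows),
    interfaces = do.call(rbind, ifaceRows),
    frameIntervalS = sim@snapshotMins * 60,
    axisFrame = list(ap = c(1, 0), dv = c(0, 1), midlineY = 0),
    meta = list(unit = "um", umPerUnit = umPerUnit,
                source = "vertexGBE simulation",
                seed = sim@params@seed),
    validate = validate)
}
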