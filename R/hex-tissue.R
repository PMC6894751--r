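# Periodic hexagonal initial condition. The lattice uses "pointy-top"
# hexagons in brick-staggered columns: same-row neighbours in adjacent
# columns meet at vertical (DV-oriented) interfaces. Those interfaces
# always separate different stripe identities and carry the supplementary
# cable tension, so they shorten preferentially; the cells that gain
# contact when one collapses belong to the same column (same stripe), so
# the new AP-oriented junction is cable-free and stable - the T1 is
# productive rather than reversible.

# Derive edges (vertex pairs + incident cell pairs) from the cell loops.
.buildEdgesFromCells <- function(cells, nV) {
  from <- unlist(lapply(cells, function(lp) lp))
  to <- unlist(lapply(cells, function(lp) c(lp[-1], lp[1])))
  cid <- rep(seq_along(cells), lengths(cells))
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b)
  sp <- split(seq_along(key), key)
  bad <- lengths(sp) != 2
  if (any(bad)) stop("mesh construction: each edge must be shared by exactly two cells")
  idx1 <- vapply(sp, `[`, integer(1), 1)
  idx2 <- vapply(sp, `[`, integer(1), 2)
  if (any(cid[idx1] == cid[idx2]))
    stop("mesh construction: edge bordered twice by the same cell")
  list(edges = cbind(a[idx1], b[idx1]),
       edgeCells = cbind(cid[idx1], cid[idx2]))
}

#' Build a periodic hexagonal tissue
#'
#' Tiles a torus with \code{nx} columns by \code{ny} rows of regular
#' hexagons of area \code{A0}, assigns each column one of four repeating
#' anteroposterior stripe identities, and returns the mesh with all
#' vertices of rank 3. The anteroposterior (AP) axis is x and the
#' dorsoventral (DV) axis is y. Cells are stacked in vertical columns, so
#' interfaces within a column are AP-oriented and same-stripe while
#' interfaces between columns are DV-oriented and stripe-mismatched (these
#' carry the cable tension).
#'
#' @param nx number of columns (must be even, >= 2).
#' @param ny number of rows (must be even, >= 2, for the periodic offset
#'   pattern to close).
#' @param A0 cell area (default 1, model units).
#' @param stripePeriod number of stripe identities repeating along AP
#'   (default 4).
#' @return a [VertexMesh-class] with \code{nx * ny} cells.
#' @examples
#' mesh <- hexTissue(4, 4)
#' nCells(mesh)
#' @export
hexTissue <- function(nx, ny, A0 = 1, stripePeriod = 4L) {
  if (nx < 2 || ny < 2 || nx %% 2 != 0 || ny %% 2 != 0)
    stop("hexTissue: nx and ny must be even and >= 2 for a periodic hexagonal wrap")
  s <- sqrt(A0 * 2 / (3 * sqrt(3)))   # hexagon side
  w <- sqrt(3) * s                    # column width
  Lx <- nx * w
  Ly <- ny * 1.5 * s

  # each cell owns its top (T) and bottom (B) vertex
  idxT <- function(r, c) {
    r <- r %% ny; c <- c %% nx
    r * nx + c + 1L
  }
  idxB <- function(r, c) {
    r <- r %% ny; c <- c %% nx
    nx * ny + r * nx + c + 1L
  }
  nV <- 2L * nx * ny
  verts <- matrix(0, nV, 2)
  for (r in 0:(ny - 1)) {
    for (c in 0:(nx - 1)) {
      cx <- w * (c + 0.5 * (r %% 2))
      cy <- 1.5 * s * r
      verts[idxT(r, c), ] <- c(cx, cy + s) %% c(Lx, Ly)
      verts[idxB(r, c), ] <- c(cx, cy - s) %% c(Lx, Ly)
    }
  }
  cells <- vector("list", nx * ny)
  cellRow <- integer(nx * ny); cellCol <- integer(nx * ny)
  k <- 0L
  for (r in 0:(ny - 1)) {
    for (c in 0:(nx - 1)) {
      k <- k + 1L
      par <- r %% 2
      cL <- c - 1L + par       # column of the left diagonal neighbours
      cR <- c + par            # column of the right diagonal neighbours
      # counter-clockwise from the top vertex
      cells[[k]] <- c(idxT(r, c), idxB(r + 1, cL), idxT(r - 1, cL),
                      idxB(r, c), idxT(r - 1, cR), idxB(r + 1, cR))
      cellRow[k] <- r; cellCol[k] <- c
    }
  }
  ed <- .buildEdgesFromCells(cells, nV)
  new("VertexMesh",
      vertices = verts, edges = ed$edges, edgeCells = ed$edgeCells,
      cells = cells,
      stripe = as.integer(cellCol %% stripePeriod + 1L),
      cellData = data.frame(row = cellRow, col = cellCol),
      box = c(Lx, Ly), time = 0,
      mergeInfo = data.frame(vertex = integer(), losingA = integer(),
                             losingB = integer()))
}
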