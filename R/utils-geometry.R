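# Low-level planar geometry helpers shared by the mesh, tracks and shape code.
# Polygons are n x 2 matrices of vertex coordinates in loop order (no repeat
# of the first vertex).

#' Signed area of a polygon
#'
#' Shoelace formula; positive for counter-clockwise loops.
#'
#' @param p numeric matrix (n x 2) of vertices in loop order.
#' @return signed area (scalar).
#' @keywords internal
polygonSignedArea <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

#' Area-weighted centroid of a simple polygon
#' @param p numeric matrix (n x 2).
#' @return numeric length-2 centroid.
#' @keywords internal
polygonCentroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

# Proper segment intersection test (excluding shared endpoints), used by
# the polygon simplicity check.
.segmentsCross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Checks all non-adjacent boundary segment pairs for proper crossings
#' (vectorised over pairs).
#'
#' @param p numeric matrix (n x 2).
#' @return logical.
#' @keywords internal
polygonIsSimple <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1)
  pr <- expand.grid(a = seq_len(n), b = seq_len(n))
  pr <- pr[pr$b > pr$a + 1 & !(pr$a == 1 & pr$b == n), , drop = FALSE]
  if (nrow(pr) == 0) return(TRUE)
  cr <- function(o1, o2, q)
    (o2[, 1] - o1[, 1]) * (q[, 2] - o1[, 2]) -
    (o2[, 2] - o1[, 2]) * (q[, 1] - o1[, 1])
  p1 <- p[pr$a, , drop = FALSE]; p2 <- p[j[pr$a], , drop = FALSE]
  q1 <- p[pr$b, , drop = FALSE]; q2 <- p[j[pr$b], , drop = FALSE]
  d1 <- cr(q1, q2, p1); d2 <- cr(q1, q2, p2)
  d3 <- cr(p1, p2, q1); d4 <- cr(p1, p2, q2)
  !any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
       ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

# Minimum-image displacement on a periodic box (component-wise).
.minImage <- function(d, box) {
  if (is.null(dim(d))) {
    d - box * round(d / box)
  } else {
    d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
    d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
    d
  }
}

# Group-wise cumulative sum for ragged loops flattened into one vector.
# `lens` gives the run length of each group.
.groupedCumsum <- function(x, lens) {
  cs <- cumsum(x)
  starts <- cumsum(lens) - lens + 1
  base <- c(0, cs)[starts]
  cs - rep(base, lens)
}

#' Fold an angle in degrees into [0, 180)
#' @keywords internal
foldAngle180 <- function(deg) {
  out <- deg %% 180
  out[out < 0] <- out[out < 0] + 180
  out
}

#' Acute angle (degrees, in [0, 90]) between a direction and an axis
#'
#' @param v numeric length-2 direction vector (or n x 2 matrix).
#' @param axis unit vector of the reference axis (default AP = x).
#' @return angle(s) in degrees in \[0, 90\].
#' @keywords internal
angleToAxis <- function(v, axis = c(1, 0)) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 2)
  nv <- sqrt(rowSums(v^2))
  if (any(nv == 0)) stop("angleToAxis: zero-length direction")
  cosang <- abs(v %*% axis) / nv
  cosang[cosang > 1] <- 1
  as.numeric(acos(cosang) * 180 / pi)
}

# Signed direction angle of a vector in degrees mod 180, in [0, 180).
.directionAngle180 <- function(v) {
  foldAngle180(atan2(v[2], v[1]) * 180 / pi)
}

# Smallest signed difference between two direction angles (mod 180),
# result in (-90, 90].
.angleDiff180 <- function(a, b) {
  d <- (a - b) %% 180
  d[d > 90] <- d[d > 90] - 180
  d
}

# Resample a closed polygon to n points equally spaced by arc length,
# starting from the first vertex.
.resampleClosed <- function(p, n) {
  m <- nrow(p)
  pc <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pc)^2))
  s <- c(0, cumsum(seg))
  tot <- s[m + 1]
  if (tot <= 0) stop("degenerate outline: zero perimeter")
  tgt <- seq(0, tot, length.out = n + 1)[seq_len(n)]
  idx <- findInterval(tgt, s, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (tgt - s[idx]) / pmax(seg[idx], .Machine$double.xmin)
  pc[idx, , drop = FALSE] + (pc[idx + 1, , drop = FALSE] - pc[idx, , drop = FALSE]) * frac
}
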