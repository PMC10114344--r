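# Internal vector-geometry layer.
#
# All geometry is carried as a "polyset": a list of rings, each ring a
# list(x = numeric, y = numeric) in micrometers, interpreted under the
# even-odd fill rule (holes are rings nested inside outer rings).
# Boolean operations and Minkowski offsets go through polyclip (Clipper);
# results come back with Clipper's consistent ring orientations so that the
# signed shoelace sum is the net enclosed area.

# Snap tolerance for boolean operations, in micrometers.
.GEOM_EPS <- 1e-3

ring_signed_area <- function(ring) {
  x <- ring$x
  y <- ring$y
  n <- length(x)
  if (n < 3) return(0)
  sum(x * (y[c(2:n, 1)]) - y * (x[c(2:n, 1)])) / 2
}

#' Net area of a polyset
#'
#' Signed shoelace sum over rings. For polysets normalized through
#' [poly_normalize()] or any polyclip operation, hole rings carry opposite
#' orientation so the sum is the net enclosed area.
#' @param ps polyset (list of rings, each `list(x, y)`)
#' @return area in square micrometers
#' @keywords internal
poly_area <- function(ps) {
  if (length(ps) == 0) return(0)
  abs(sum(vapply(ps, ring_signed_area, numeric(1))))
}

# Resolve an arbitrary even-odd ring soup into Clipper-normalized rings.
poly_normalize <- function(ps) {
  if (length(ps) == 0) return(list())
  polyclip::polyclip(ps, ps, op = "union",
                     fillA = "evenodd", fillB = "evenodd", eps = .GEOM_EPS)
}

poly_union <- function(a, b) {
  if (length(a) == 0) return(poly_normalize(b))
  if (length(b) == 0) return(poly_normalize(a))
  polyclip::polyclip(a, b, op = "union",
                     fillA = "evenodd", fillB = "evenodd", eps = .GEOM_EPS)
}

poly_minus <- function(a, b) {
  if (length(a) == 0) return(list())
  if (length(b) == 0) return(poly_normalize(a))
  polyclip::polyclip(a, b, op = "minus",
                     fillA = "evenodd", fillB = "evenodd", eps = .GEOM_EPS)
}

poly_intersect <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(list())
  polyclip::polyclip(a, b, op = "intersection",
                     fillA = "evenodd", fillB = "evenodd", eps = .GEOM_EPS)
}

poly_intersects <- function(a, b) {
  ab <- poly_intersect(a, b)
  length(ab) > 0 && poly_area(ab) > .GEOM_EPS
}

# Minkowski offset by a disk of radius |delta| (outward for delta > 0,
# inward for delta < 0), round joins. arctol bounds the sagitta of the arc
# approximation in micrometers.
poly_offset <- function(ps, delta, arctol = 0.25) {
  if (length(ps) == 0) return(list())
  ps <- poly_normalize(ps)
  if (delta == 0) return(ps)
  polyclip::polyoffset(ps, delta, jointype = "round",
                       arctol = arctol, eps = .GEOM_EPS)
}

# Morphological closing with a disk of diameter `diameter`: dilate by the
# radius, then erode by the same radius. Fills corridors between components
# whose gap is at most one diameter, and concavities narrower than that.
# The final union with the input enforces closing(A) >= A exactly, which
# the polygonal arc approximation of the offsets would otherwise violate
# by sub-micrometer slivers at convex corners.
poly_close <- function(ps, diameter, arctol = 0.25) {
  ps <- poly_normalize(ps)
  if (length(ps) == 0 || diameter <= 0) return(ps)
  r <- diameter / 2
  closed <- poly_offset(poly_offset(ps, r, arctol = arctol), -r,
                        arctol = arctol)
  poly_union(closed, ps)
}

#' Even-odd point-in-polyset test
#'
#' Crossing-number test against every ring; a point inside an odd number of
#' rings (e.g. an outer ring but not its hole) is inside the set.
#' @param x,y point coordinates (micrometers)
#' @param ps polyset
#' @return logical vector
#' @keywords internal
points_in_polyset <- function(x, y, ps) {
  inside <- rep(FALSE, length(x))
  if (length(ps) == 0) return(inside)
  crossings <- integer(length(x))
  for (ring in ps) {
    rx <- ring$x; ry <- ring$y
    n <- length(rx)
    j <- c(n, seq_len(n - 1))
    for (k in seq_len(n)) {
      xi <- rx[k]; yi <- ry[k]; xj <- rx[j[k]]; yj <- ry[j[k]]
      if (yi == yj) next
      straddles <- (yi > y) != (yj > y)
      if (any(straddles)) {
        xint <- xi + (y - yi) * (xj - xi) / (yj - yi)
        crossings <- crossings + as.integer(straddles & (x < xint))
      }
    }
  }
  crossings %% 2L == 1L
}

# Segment-pair intersection test for ring simplicity (shared endpoints of
# adjacent edges allowed). O(n^2); annotation rings are small.
ring_is_simple <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  segs <- cbind(x, y, x[nxt], y[nxt])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share an endpoint)
      if (j == i + 1 || (i == 1 && j == n)) next
      a <- segs[i, ]; b <- segs[j, ]
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4) return(FALSE)
    }
  }
  TRUE
}

poly_bbox <- function(ps) {
  xs <- unlist(lapply(ps, `[[`, "x"))
  ys <- unlist(lapply(ps, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Ring constructors used by the generator and tests ---------------------------

rect_ring <- function(x0, y0, x1, y1) {
  list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

circle_ring <- function(cx, cy, r, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

ring_centroid <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Scale a ring about its centroid.
ring_scale <- function(ring, s) {
  cc <- ring_centroid(ring)
  list(x = cc[1] + s * (ring$x - cc[1]), y = cc[2] + s * (ring$y - cc[2]))
}

ring_perimeter <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}
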