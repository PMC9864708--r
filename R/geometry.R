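#' @importFrom stats approx rnorm runif rlnorm median quantile sd setNames uniroot
#' @importFrom utils combn head tail
NULL

# Polygons are n x 2 numeric matrices, implicitly closed (last vertex joins
# the first); duplicate closing vertices are stripped on input.

as_polygon <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("polygon must have two columns (x, y)")
  if (nrow(p) >= 2L && isTRUE(all.equal(p[1L, ], p[nrow(p), ],
                                        check.attributes = FALSE))) {
    p <- p[-nrow(p), , drop = FALSE]
  }
  if (!all(is.finite(p))) stop("polygon coordinates must be finite")
  dimnames(p) <- NULL
  p
}

polygon_signed_area <- function(poly) {
  p <- as_polygon(poly)
  if (nrow(p) < 3L) stop("polygon needs at least 3 vertices")
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area by the shoelace formula
#'
#' Area of a simple closed polyline in mm^2, positive regardless of vertex
#' orientation.
#'
#' @param poly n x 2 matrix of vertices (mm); closure is implicit.
#' @return Scalar area (mm^2).
#' @export
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # 1
polygon_area <- function(poly) abs(polygon_signed_area(poly))

#' Polygon centroid (area-weighted)
#'
#' @param poly n x 2 vertex matrix.
#' @return Length-2 numeric (x, y).
#' @export
polygon_centroid <- function(poly) {
  p <- as_polygon(poly)
  if (nrow(p) < 3L) stop("polygon needs at least 3 vertices")
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_perimeter <- function(poly) {
  p <- as_polygon(poly)
  d <- sqrt(rowSums((p[c(2:nrow(p), 1L), ] - p)^2))
  sum(d)
}

ensure_ccw <- function(poly) {
  p <- as_polygon(poly)
  if (polygon_signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  p
}

# O(n^2) segment-crossing test; adequate for contour sizes used here.
polygon_is_simple <- function(poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip edges sharing a vertex with edge i (adjacent in the cycle)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

# vectorised proper/improper intersection of segment (p1,p2) with rows of (q1,q2)
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, sweep(-q1, 2L, -p1))      # orient of p1 wrt q
  d2 <- cross2(q2 - q1, sweep(-q1, 2L, -p2))
  r <- p2 - p1
  d3 <- cross2_mat(r, q1 - matrix(p1, nrow(q1), 2L, byrow = TRUE))
  d4 <- cross2_mat(r, q2 - matrix(p1, nrow(q1), 2L, byrow = TRUE))
  (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
}

cross2 <- function(u, v) u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
cross2_mat <- function(r, m) r[1L] * m[, 2L] - r[2L] * m[, 1L]

points_in_polygon <- function(pts, poly) {
  p <- as_polygon(poly)
  pts <- matrix(as.numeric(pts), ncol = 2L)
  as.logical(pracma::inpolygon(pts[, 1L], pts[, 2L], p[, 1L], p[, 2L],
                               boundary = TRUE))
}

polygon_inside_polygon <- function(inner, outer) {
  inner <- as_polygon(inner); outer <- as_polygon(outer)
  if (!all(points_in_polygon(inner, outer))) return(FALSE)
  n <- nrow(inner)
  a <- inner; b <- inner[c(2:n, 1L), , drop = FALSE]
  m <- nrow(outer)
  oa <- outer; ob <- outer[c(2:m, 1L), , drop = FALSE]
  for (i in seq_len(n)) {
    if (any(segments_intersect(a[i, ], b[i, ], oa, ob))) return(FALSE)
  }
  TRUE
}

#' Resample a closed contour at even arc-length spacing
#'
#' Returns `n` points spaced perimeter/n apart along the contour, traversed
#' counter-clockwise. The first point is the vertex with the largest x
#' coordinate (ties broken by the smaller y), a fixed convention so that
#' downstream quarter labels are reproducible.
#'
#' @param poly closed polyline, n x 2 (mm).
#' @param n number of samples, >= 4.
#' @return n x 2 matrix of points.
#' @export
resample_even <- function(poly, n) {
  if (n < 4L) stop("n must be >= 4")
  p <- ensure_ccw(poly)
  per <- polygon_perimeter(p)
  if (per <= 0) stop("degenerate polyline: zero perimeter")
  start <- order(-p[, 1L], p[, 2L])[1L]
  idx <- c(start:nrow(p), seq_len(start - 1L))
  p <- p[idx, , drop = FALSE]
  pc <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(pc)^2))
  s <- c(0, cumsum(seg))
  target <- per * (seq_len(n) - 1L) / n
  xs <- approx(s, pc[, 1L], xout = target, rule = 2)$y
  ys <- approx(s, pc[, 2L], xout = target, rule = 2)$y
  cbind(xs, ys, deparse.level = 0L)
}

# Radius of a star-shaped polygon boundary about `center`, evaluated at
# angles `theta` by linear interpolation in the angular parametrisation.
polar_boundary_radius <- function(poly, center, theta) {
  p <- ensure_ccw(poly)
  d <- sweep(p, 2L, center)
  ang <- atan2(d[, 2L], d[, 1L])
  r <- sqrt(rowSums(d^2))
  o <- order(ang)
  ang <- ang[o]; r <- r[o]
  ang <- c(ang[length(ang)] - 2 * pi, ang, ang[1L] + 2 * pi)
  r <- c(r[length(r)], r, r[1L])
  th <- ((theta + pi) %% (2 * pi)) - pi
  approx(ang, r, xout = th)$y
}
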