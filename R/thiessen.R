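# Sutherland-Hodgman clip of a convex-or-simple polygon ring against the
# half-plane a*x + b*y <= c. ring: matrix with columns x, y, open (no
# repeated first vertex).
.clip_halfplane <- function(ring, a, b, c) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  out <- matrix(numeric(0), ncol = 2)
  val <- a * ring[, 1] + b * ring[, 2] - c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- val[i] <= 1e-9
    pj_in <- val[j] <= 1e-9
    if (pi_in) out <- rbind(out, ring[i, ])
    if (pi_in != pj_in) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  out
}

#' Thiessen (Voronoi) polygons within a boundary
#'
#' Partitions a boundary polygon into one catchment per seed point: the
#' locations nearer to that seed than to any other. Each cell is obtained
#' by clipping the boundary against the perpendicular-bisector half-plane
#' of every other seed. Used to extend a travel time computed at a
#' neighborhood center point to the whole neighborhood.
#'
#' @param points data frame of distinct seed points (`x`, `y`).
#' @param boundary boundary polygon ring: matrix or data frame with columns
#'   x, y, vertices in order, not closed (first vertex not repeated). Must
#'   be convex for exact partitioning (e.g. a bounding rectangle).
#' @return list of polygon rings (two-column matrices), one per seed, in
#'   seed order.
#' @export
thiessen_polygons <- function(points, boundary) {
  pts <- cbind(points$x, points$y)
  if (anyDuplicated(round(pts, 9)) > 0) {
    stop_ra("duplicate seed points", "ra_thiessen_error")
  }
  boundary <- as.matrix(boundary[, 1:2])
  n <- nrow(pts)
  lapply(seq_len(n), function(i) {
    ring <- boundary
    for (j in seq_len(n)[-i]) {
      # keep the side of the bisector nearer to seed i:
      # 2 (pj - pi) . x <= |pj|^2 - |pi|^2
      a <- 2 * (pts[j, 1] - pts[i, 1])
      b <- 2 * (pts[j, 2] - pts[i, 2])
      c <- sum(pts[j, ]^2) - sum(pts[i, ]^2)
      ring <- .clip_halfplane(ring, a, b, c)
      if (nrow(ring) == 0) break
    }
    colnames(ring) <- c("x", "y")
    ring
  })
}

#' Polygon area (shoelace formula)
#' @param ring two-column matrix of vertices, open ring.
#' @return area in square units of the coordinates.
#' @export
polygon_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(ring[, 1] * ring[j, 2] - ring[j, 1] * ring[, 2])) / 2
}

#' Point-in-polygon test (even-odd rule)
#' @param x,y point coordinates (vectors).
#' @param ring two-column vertex matrix, open ring.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, ring) {
  n <- nrow(ring)
  vapply(seq_along(x), function(k) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((ring[i, 2] > y[k]) != (ring[j, 2] > y[k])) {
        xint <- ring[i, 1] + (y[k] - ring[i, 2]) /
          (ring[j, 2] - ring[i, 2]) * (ring[j, 1] - ring[i, 1])
        if (x[k] < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}
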