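#' Circumradius of a triangle
#'
#' Radius of the unique circle through three non-collinear points.  This is
#' the critical alpha at which a Delaunay triangle enters the alpha-shape:
#' a disc of radius alpha can only "fall into" a triangle whose circumcircle
#' it fits inside.
#'
#' @param p1,p2,p3 numeric length-2 coordinate vectors (pixels).
#' @return circumradius in pixels.
#' @examples
#' circumradius(c(0, 0), c(3, 0), c(0, 4))  # right triangle: 2.5
#' @export
circumradius <- function(p1, p2, p3) {
  r <- unname(circumradius_many(rbind(p1), rbind(p2), rbind(p3)))
  if (!is.finite(r) || r <= 0)
    stop("degenerate triangle: points are collinear or coincident")
  r
}

# Vectorised circumradius for row-paired coordinate matrices.
# Returns Inf for (near-)collinear rows.
circumradius_many <- function(P1, P2, P3) {
  a <- sqrt(rowSums((P2 - P3)^2))
  b <- sqrt(rowSums((P1 - P3)^2))
  cc <- sqrt(rowSums((P1 - P2)^2))
  cross <- (P2[, 1] - P1[, 1]) * (P3[, 2] - P1[, 2]) -
    (P2[, 2] - P1[, 2]) * (P3[, 1] - P1[, 1])
  area2 <- abs(cross)                     # twice the triangle area
  r <- a * b * cc / (2 * area2)
  r[area2 <= .Machine$double.eps * (a * b + b * cc + a * cc)] <- Inf
  r
}

# Circumcenters of every triangle of a "delaunay" object (internal).
tri_circumcenters <- function(tri) {
  A <- tri$points[tri$triangles[, 1], , drop = FALSE]
  B <- tri$points[tri$triangles[, 2], , drop = FALSE]
  C <- tri$points[tri$triangles[, 3], , drop = FALSE]
  d <- 2 * (A[, 1] * (B[, 2] - C[, 2]) + B[, 1] * (C[, 2] - A[, 2]) +
              C[, 1] * (A[, 2] - B[, 2]))
  a2 <- rowSums(A^2); b2 <- rowSums(B^2); c2 <- rowSums(C^2)
  cbind((a2 * (B[, 2] - C[, 2]) + b2 * (C[, 2] - A[, 2]) +
           c2 * (A[, 2] - B[, 2])) / d,
        (a2 * (C[, 1] - B[, 1]) + b2 * (A[, 1] - C[, 1]) +
           c2 * (B[, 1] - A[, 1])) / d)
}

#' Delaunay triangulation of a planar point set
#'
#' Deduplicates the points, triangulates them, and attaches per-triangle
#' circumradii, areas and edge-adjacency — everything the alpha-shape
#' filtration needs.  The result is deterministic for a given input.
#'
#' @param points two-column matrix of (x, y) coordinates, or anything
#'   [as_point_matrix()] accepts.  Skeleton rasters should be converted with
#'   [skeleton_points()].
#' @return an object of class `"delaunay"`: list with `points` (deduplicated,
#'   n x 2), `triangles` (T x 3 vertex indices), `circumradius`, `tri_area`
#'   (per-triangle), `adjacency` (E x 2 triangle indices sharing a full edge)
#'   and `n_duplicates_removed`.
#' @export
triangulate <- function(points) {
  pts <- as_point_matrix(points)
  dup <- duplicated(pts)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(sprintf("triangulate: removed %d duplicate point(s)", n_dup))
    pts <- pts[!dup, , drop = FALSE]
  }
  if (nrow(pts) < 3L)
    stop("degenerate input: fewer than 3 distinct points")
  if (is_collinear(pts))
    stop("degenerate input: points are all collinear")
  tm <- tryCatch(
    interp::triangles(interp::tri.mesh(pts[, 1], pts[, 2], duplicate = "error")),
    error = function(e) stop("degenerate input: triangulation failed (",
                             conditionMessage(e), ")")
  )
  tri <- unname(tm[, c("node1", "node2", "node3"), drop = FALSE])
  P1 <- pts[tri[, 1], , drop = FALSE]
  P2 <- pts[tri[, 2], , drop = FALSE]
  P3 <- pts[tri[, 3], , drop = FALSE]
  cr <- circumradius_many(P1, P2, P3)
  area <- 0.5 * abs((P2[, 1] - P1[, 1]) * (P3[, 2] - P1[, 2]) -
                      (P2[, 2] - P1[, 2]) * (P3[, 1] - P1[, 1]))
  # edge adjacency from the triangulation's neighbour pointers
  nb <- unname(tm[, c("tr1", "tr2", "tr3"), drop = FALSE])
  self <- rep(seq_len(nrow(tri)), 3L)
  other <- as.vector(nb)
  ok <- other > 0 & self < other          # each shared edge once
  structure(list(
    points = pts,
    triangles = tri,
    circumradius = as.numeric(cr),
    tri_area = as.numeric(area),
    adjacency = cbind(self[ok], other[ok]),
    n_duplicates_removed = n_dup
  ), class = "delaunay")
}

#' @export
print.delaunay <- function(x, ...) {
  cat("Delaunay triangulation:", nrow(x$points), "points,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Alpha-shape of a triangulated point set
#'
#' Keeps exactly the Delaunay triangles whose circumradius is `<= alpha`
#' (boundary inclusive, so the optimal alpha search lands exactly on a
#' spectrum value).  Regions are edge-connected components of the kept
#' triangles; vertex-only contact does not connect.
#'
#' @param tri a `"delaunay"` object from [triangulate()].
#' @param alpha non-negative refinement radius (pixels).
#' @return object of class `"alpha_shape"`: list with `source`, `alpha`,
#'   `kept` (triangle indices), `region_id` (per-triangle label, 0 =
#'   dropped), `n_regions`, `area` (squared pixels) and `covered_points`
#'   (vertex indices of kept triangles).
#' @export
build_alpha_shape <- function(tri, alpha) {
  stopifnot(inherits(tri, "delaunay"))
  if (!is.finite(alpha) || alpha < 0)
    stop("alpha must be a non-negative finite length")
  keep <- tri$circumradius <= alpha
  comp <- uf_components(nrow(tri$triangles),
                        tri$adjacency[, 1], tri$adjacency[, 2], keep)
  kept <- which(keep)
  covered <- if (length(kept)) sort(unique(as.vector(tri$triangles[kept, ])))
             else integer(0)
  structure(list(
    source = tri,
    alpha = alpha,
    kept = kept,
    region_id = comp$labels,
    n_regions = comp$n_components,
    area = sum(tri$tri_area[kept]),
    covered_points = covered
  ), class = "alpha_shape")
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf("alpha-shape (alpha = %g): %d/%d triangles, %d region(s), area %g\n",
              x$alpha, length(x$kept), nrow(x$source$triangles),
              x$n_regions, x$area))
  invisible(x)
}

#' Number of edge-connected regions of an alpha-shape
#' @param shape an `"alpha_shape"` object.
#' @return region count (0 for the empty shape).
#' @export
count_regions <- function(shape) {
  stopifnot(inherits(shape, "alpha_shape"))
  shape$n_regions
}

#' Does an alpha-shape cover every point of its triangulation?
#'
#' TRUE iff every vertex of the source triangulation appears in at least one
#' kept triangle.
#'
#' @param shape an `"alpha_shape"` object.
#' @return logical scalar.
#' @export
covers_all_points <- function(shape) {
  stopifnot(inherits(shape, "alpha_shape"))
  length(shape$covered_points) == nrow(shape$source$points)
}

#' Critical-alpha spectrum of a triangulation
#'
#' The sorted distinct circumradii: the alpha-shape is constant between
#' consecutive spectrum values, so any search over alpha need only visit
#' these.
#'
#' @param tri a `"delaunay"` object.
#' @return strictly increasing numeric vector.
#' @export
alpha_spectrum <- function(tri) {
  stopifnot(inherits(tri, "delaunay"))
  sort(unique(tri$circumradius))
}
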