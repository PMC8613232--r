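#' Optimal alpha-shape of a skeleton point set
#'
#' Finds the minimum alpha at which the alpha-shape is a single
#' edge-connected region covering every point — the "optimum" shape whose
#' refinement radius (complexity, smaller = more complex) and area (spread)
#' are the two base morphology descriptors.  Both criteria are monotone in
#' alpha (the full triangulation is one covering region), so the search is a
#' discrete binary search over the critical-alpha spectrum and is exact.
#'
#' @param x a two-column point matrix, a `"delaunay"` object, or a skeleton
#'   (class `"av_skeleton"`), in which case its foreground coordinates are
#'   used.
#' @return object of class `"optimal_alpha"`: list with `op_alpha_min`
#'   (pixels), `op_area` (squared pixels) and `shape` (the alpha-shape at the
#'   optimum).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' find_optimal_alpha(sq)$op_alpha_min  # sqrt(2)/2
#' @export
find_optimal_alpha <- function(x) {
  tri <- if (inherits(x, "delaunay")) x
         else if (inherits(x, "av_skeleton")) triangulate(skeleton_points(x))
         else triangulate(x)
  spectrum <- alpha_spectrum(tri)
  ok <- function(a) {
    s <- build_alpha_shape(tri, a)
    s$n_regions == 1L && covers_all_points(s)
  }
  hi <- length(spectrum)
  if (!ok(spectrum[hi]))
    stop("internal consistency error: full triangulation is not a single covering region")
  lo <- 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (ok(spectrum[mid])) hi <- mid else lo <- mid + 1L
  }
  shape <- build_alpha_shape(tri, spectrum[lo])
  structure(list(
    op_alpha_min = spectrum[lo],
    op_area = shape$area,
    shape = shape
  ), class = "optimal_alpha")
}

#' @export
print.optimal_alpha <- function(x, ...) {
  cat(sprintf("optimal alpha-shape: Op_alpha_min = %g px, OpA = %g px^2\n",
              x$op_alpha_min, x$op_area))
  invisible(x)
}
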