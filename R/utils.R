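#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so that seeded generators never leak global RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Coerce input to a two-column coordinate matrix
#' @param points matrix/data.frame with two columns, or an object with a
#'   `points` element.
#' @return numeric matrix with columns (x, y).
#' @keywords internal
as_point_matrix <- function(points) {
  if (is.list(points) && !is.data.frame(points) && !is.null(points$points))
    points <- points$points
  pts <- as.matrix(points)
  if (ncol(pts) != 2L)
    stop("points must have exactly two columns")
  storage.mode(pts) <- "double"
  if (nrow(pts) > 0 && !all(is.finite(pts)))
    stop("point coordinates must be finite")
  dimnames(pts) <- NULL
  pts
}

# TRUE when all points lie (numerically) on one line.
is_collinear <- function(pts) {
  if (nrow(pts) < 3L) return(TRUE)
  ctr <- sweep(pts, 2, colMeans(pts))
  d <- svd(ctr, nu = 0, nv = 0)$d
  d[2] <= 1e-9 * max(d[1], 1)
}
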