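#' Box-counting fractal dimension
#'
#' Counts occupied boxes on grids anchored at the raster origin for a series
#' of box sizes and estimates FD as minus the least-squares slope of
#' log(count) against log(scale).  A comparator to the alpha-shape
#' descriptors, not a replication of any particular multifractal pipeline.
#'
#' @param skel skeleton / mask / binary matrix with foreground.
#' @param scales strictly increasing box sizes in pixels; default powers of
#'   2 from 2 to min(height, width)/4 (at least 4 scales required).
#' @return object of class `"fd_result"`: `fd`, `method`, `scales`,
#'   `counts_or_masses`, `fit_r2`.
#' @export
box_counting_fd <- function(skel, scales = NULL) {
  g <- as_binary_grid(skel)
  if (!any(g)) stop("empty skeleton")
  if (is.null(scales)) {
    # cap at min(h, w)/8: larger boxes are dominated by partial-box end
    # effects; floor of 16 keeps >= 4 scales on small rasters
    smax <- max(min(dim(g)) / 8, 16)
    scales <- 2^(1:floor(log2(smax)))
  }
  scales <- sort(unique(as.numeric(scales)))
  if (length(scales) < 4L) stop("need at least 4 scales")
  rc <- which(g, arr.ind = TRUE)
  counts <- vapply(scales, function(s) {
    bx <- (rc[, 1] - 1) %/% s
    by <- (rc[, 2] - 1) %/% s
    length(unique(bx * (max(by) + 1 + 1) + by))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(scales))
  structure(list(fd = -unname(coef(fit)[2]), method = "box_counting",
                 scales = scales, counts_or_masses = counts,
                 fit_r2 = summary(fit)$r.squared, q_values = NULL),
            class = "fd_result")
}

#' Generalised sandbox fractal dimension
#'
#' Seeds `n_centers` sandbox centres on foreground pixels and measures the
#' mass M(r) (foreground count) inside discs of increasing radius.  The
#' generalised dimension D_q is the slope of
#' log mean((M/M0)^(q-1)) over valid centres against log r, divided by
#' (q - 1); the reported `fd` is D_0.  Centres whose disc leaves the raster
#' at a given radius are excluded at that radius to avoid edge-mass bias.
#'
#' @param skel skeleton / mask / binary matrix.
#' @param radii strictly increasing radii (pixels); default geometric from 4
#'   to min(height, width)/4, 8 values.
#' @param q_values moment orders (q = 1 excluded); default -5..5 without 1.
#' @param n_centers number of sandbox centres (default 100).
#' @param seed RNG seed for centre sampling.
#' @return `"fd_result"` with `fd` (= D_0), `d_q` (named by q), `scales`
#'   (radii), `counts_or_masses` (mean mass per radius), `fit_r2` (for D_0),
#'   `q_values`.
#' @export
sandbox_fd <- function(skel, radii = NULL, q_values = setdiff(-5:5, 1),
                       n_centers = 100L, seed = 1L) {
  g <- as_binary_grid(skel)
  rc <- which(g, arr.ind = TRUE)
  if (nrow(rc) < n_centers)
    stop(sprintf("only %d foreground pixels for %d requested centers",
                 nrow(rc), n_centers))
  if (is.null(radii)) {
    rmax <- min(dim(g)) / 4
    radii <- exp(seq(log(4), log(rmax), length.out = 8))
  }
  radii <- sort(unique(as.numeric(radii)))
  if (any(q_values == 1)) stop("q = 1 is not defined for this estimator")
  M0 <- nrow(rc)
  centers <- with_seed(seed, rc[sample.int(nrow(rc), n_centers), , drop = FALSE])
  nr <- nrow(g); nc <- ncol(g)
  # mass[i, j]: foreground count within radii[j] of center i (NA if disc
  # exits the raster)
  mass <- matrix(NA_real_, n_centers, length(radii))
  for (i in seq_len(n_centers)) {
    d2 <- (rc[, 1] - centers[i, 1])^2 + (rc[, 2] - centers[i, 2])^2
    border <- min(centers[i, 1] - 1, nr - centers[i, 1],
                  centers[i, 2] - 1, nc - centers[i, 2])
    for (j in seq_along(radii)) {
      if (radii[j] <= border) mass[i, j] <- sum(d2 <= radii[j]^2)
    }
  }
  valid_r <- colSums(!is.na(mass)) >= 5L
  if (sum(valid_r) < 4L)
    stop("fewer than 4 usable radii (raster too small for requested radii)")
  lr <- log(radii[valid_r])
  d_q <- vapply(q_values, function(q) {
    y <- log(colMeans((mass[, valid_r, drop = FALSE] / M0)^(q - 1),
                      na.rm = TRUE))
    unname(coef(stats::lm(y ~ lr))[2]) / (q - 1)
  }, numeric(1))
  names(d_q) <- q_values
  y0 <- log(colMeans((mass[, valid_r, drop = FALSE] / M0)^(-1), na.rm = TRUE))
  fit0 <- stats::lm(y0 ~ lr)
  fd <- if (0 %in% q_values) unname(d_q[as.character(0)]) else -unname(coef(fit0)[2])
  structure(list(fd = fd, method = "sandbox", scales = radii[valid_r],
                 counts_or_masses = colMeans(mass[, valid_r, drop = FALSE],
                                             na.rm = TRUE),
                 fit_r2 = summary(fit0)$r.squared,
                 q_values = q_values, d_q = d_q),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("FD (%s): %.4f over %d scales (R^2 = %.3f)\n",
              x$method, x$fd, length(x$scales), x$fit_r2))
  invisible(x)
}
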