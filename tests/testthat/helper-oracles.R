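# Independent brute-force oracles and in-code fixtures.
# These deliberately avoid the package's own code paths.

canon_tris <- function(tri) {
  if (!nrow(tri)) return(tri)
  m <- t(apply(tri, 1, sort))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Brute-force Delaunay: every triple with an empty circumcircle.
bf_delaunay <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  cmb <- t(utils::combn(n, 3))
  A <- pts[cmb[, 1], , drop = FALSE]
  B <- pts[cmb[, 2], , drop = FALSE]
  C <- pts[cmb[, 3], , drop = FALSE]
  d <- 2 * (A[, 1] * (B[, 2] - C[, 2]) + B[, 1] * (C[, 2] - A[, 2]) +
              C[, 1] * (A[, 2] - B[, 2]))
  ok <- abs(d) > 1e-12
  a2 <- A[, 1]^2 + A[, 2]^2
  b2 <- B[, 1]^2 + B[, 2]^2
  c2 <- C[, 1]^2 + C[, 2]^2
  ux <- (a2 * (B[, 2] - C[, 2]) + b2 * (C[, 2] - A[, 2]) + c2 * (A[, 2] - B[, 2])) / d
  uy <- (a2 * (C[, 1] - B[, 1]) + b2 * (A[, 1] - C[, 1]) + c2 * (B[, 1] - A[, 1])) / d
  r <- sqrt((A[, 1] - ux)^2 + (A[, 2] - uy)^2)
  inside <- (outer(ux, pts[, 1], "-")^2 + outer(uy, pts[, 2], "-")^2) <
    (r * (1 - tol))^2
  inside[cbind(rep(seq_len(nrow(cmb)), 3), as.vector(cmb))] <- FALSE
  keep <- ok & rowSums(inside) == 0
  list(tri = cmb[keep, , drop = FALSE], cr = r[keep])
}

# Exhaustive adjacency region count: two triangles connect iff they share
# exactly two vertices (a full edge); flood fill.
bf_regions <- function(tri) {
  m <- nrow(tri)
  if (m == 0L) return(0L)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i < j && length(intersect(tri[i, ], tri[j, ])) == 2L)
      adj[i, j] <- adj[j, i] <- TRUE
  }
  seen <- rep(FALSE, m)
  nreg <- 0L
  for (i in seq_len(m)) {
    if (seen[i]) next
    nreg <- nreg + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[1]
      stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ] & !seen))
    }
  }
  nreg
}

tri_area_shoelace <- function(pts, tri) {
  if (!nrow(tri)) return(0)
  A <- pts[tri[, 1], , drop = FALSE]
  B <- pts[tri[, 2], , drop = FALSE]
  C <- pts[tri[, 3], , drop = FALSE]
  sum(0.5 * abs((B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) -
                  (B[, 2] - A[, 2]) * (C[, 1] - A[, 1])))
}

# Independent circumcircle via the linear system of perpendicular bisectors.
solve_circumcircle <- function(p1, p2, p3) {
  M <- rbind(2 * (p2 - p1), 2 * (p3 - p1))
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2))
  ctr <- solve(M, b)
  list(center = ctr, r = sqrt(sum((p1 - ctr)^2)))
}

# Linear-sweep oracle for the optimal alpha search.
sweep_optimal_oracle <- function(tri) {
  for (a in alpha_spectrum(tri)) {
    s <- build_alpha_shape(tri, a)
    if (count_regions(s) == 1L && covers_all_points(s))
      return(list(op_alpha_min = a, op_area = s$area))
  }
  stop("no admissible alpha")
}

# ---- raster fixtures ----

line_raster <- function(len, size = len + 6L) {
  g <- matrix(FALSE, size, size)
  r <- size %/% 2L
  g[r, 3:(len + 2L)] <- TRUE
  g
}

ring_raster <- function(radius = 10L, size = 2L * radius + 8L) {
  ctr <- size / 2
  th <- seq(0, 2 * pi, length.out = 16L * radius)
  g <- matrix(FALSE, size, size)
  g[cbind(round(ctr + radius * sin(th)), round(ctr + radius * cos(th)))] <- TRUE
  g
}

annulus_raster <- function(r_in = 8, r_out = 14, size = 2 * r_out + 8) {
  ctr <- size / 2
  d <- sqrt(outer((1:size - ctr)^2, (1:size - ctr)^2, "+"))
  d >= r_in & d <= r_out
}

# Y: three straight arms meeting at one junction pixel.
y_raster <- function(up = 12L, left = 5L, right = 5L, size = 64L) {
  g <- matrix(FALSE, size, size)
  jr <- size %/% 2L; jc <- size %/% 2L
  g[(jr - up):jr, jc] <- TRUE
  for (k in 1:left) g[jr + k, jc - k] <- TRUE
  for (k in 1:right) g[jr + k, jc + k] <- TRUE
  g[jr, jc] <- TRUE
  g
}

sierpinski_raster <- function(depth = 9L) {
  n <- 2L^depth
  i <- matrix(0:(n - 1L), n, n)
  matrix(bitwAnd(i, t(i)) == 0L, n, n)
}

filled_square_raster <- function(size = 512L) matrix(TRUE, size, size)

rand_cluster_points <- function(n, center, sd = 3) {
  cbind(stats::rnorm(n, center[1], sd), stats::rnorm(n, center[2], sd))
}
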