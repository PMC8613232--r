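test_that("circumradius matches closed forms and an algebraic solve", {
  expect_equal(circumradius(c(0, 0), c(3, 0), c(0, 4)), 2.5)
  expect_equal(circumradius(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
               1 / sqrt(3), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    p <- matrix(runif(6, -50, 50), 3, 2)
    sol <- solve_circumcircle(p[1, ], p[2, ], p[3, ])
    expect_equal(circumradius(p[1, ], p[2, ], p[3, ]), sol$r,
                 tolerance = 1e-9)
  }
  expect_error(circumradius(c(0, 0), c(1, 1), c(2, 2)), "collinear")
})

test_that("triangulate handles minimal and degenerate inputs", {
  expect_equal(nrow(triangulate(rbind(c(0, 0), c(1, 0), c(0, 1)))$triangles), 1L)
  sq <- triangulate(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(nrow(sq$triangles), 2L)
  # the two triangles share a diagonal: one adjacency pair
  expect_equal(nrow(sq$adjacency), 1L)
  expect_error(triangulate(rbind(c(0, 0), c(1, 1))), "fewer than 3")
  expect_error(triangulate(cbind(0:5, 0:5)), "collinear")
  expect_message(
    t3 <- triangulate(rbind(c(0, 0), c(1, 0), c(0, 1), c(0, 0))),
    "duplicate")
  expect_equal(nrow(t3$points), 3L)
  expect_equal(t3$n_duplicates_removed, 1L)
})

test_that("triangulation satisfies Euler relation and matches brute force", {
  set.seed(7)
  pts <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  tri <- triangulate(pts)
  bf <- bf_delaunay(pts)
  expect_equal(canon_tris(tri$triangles), canon_tris(bf$tri))
  # planar Euler: V - E + F = 2 with F = triangles + outer face
  Tn <- nrow(tri$triangles)
  e <- rbind(tri$triangles[, 1:2], tri$triangles[, 2:3],
             tri$triangles[, c(1, 3)])
  edges <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_equal(30L - nrow(edges) + (Tn + 1L), 2L)
})

test_that("alpha-shape filtering, regions and coverage behave on the unit square", {
  tri <- triangulate(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_equal(alpha_spectrum(tri), sqrt(2) / 2, tolerance = 1e-12)
  s <- build_alpha_shape(tri, 0.8)
  expect_length(s$kept, 2L)
  expect_equal(s$area, 1.0, tolerance = 1e-12)
  expect_equal(count_regions(s), 1L)
  expect_true(covers_all_points(s))
  # below the single spectrum value: empty shape
  s0 <- build_alpha_shape(tri, 0.5)
  expect_length(s0$kept, 0L)
  expect_equal(s0$area, 0)
  expect_equal(count_regions(s0), 0L)
  expect_false(covers_all_points(s0))
})

test_that("full-alpha shape equals the triangulation and the convex hull area", {
  set.seed(11)
  pts <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  tri <- triangulate(pts)
  s <- build_alpha_shape(tri, max(tri$circumradius))
  expect_equal(length(s$kept), nrow(tri$triangles))
  expect_equal(count_regions(s), 1L)
  expect_true(covers_all_points(s))
  hull <- chull(pts)
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  expect_equal(s$area, hull_area, tolerance = 1e-9)
})

test_that("two distant clusters at small alpha give two regions (flood-fill oracle)", {
  set.seed(3)
  pts <- rbind(rand_cluster_points(10, c(0, 0)),
               rand_cluster_points(10, c(100, 0)))
  tri <- triangulate(pts)
  s <- build_alpha_shape(tri, 5)
  expect_equal(count_regions(s), 2L)
  expect_equal(count_regions(s),
               bf_regions(tri$triangles[s$kept, , drop = FALSE]))
})

test_that("coverage detects isolated vertices (per-vertex incidence scan)", {
  set.seed(5)
  pts <- rbind(rand_cluster_points(12, c(0, 0), sd = 2), c(60, 0))
  tri <- triangulate(pts)
  s <- build_alpha_shape(tri, 6)
  covered_scan <- vapply(seq_len(nrow(pts)), function(v)
    any(tri$triangles[s$kept, , drop = FALSE] == v), logical(1))
  expect_false(covers_all_points(s))
  expect_equal(sort(s$covered_points), which(covered_scan))
})

test_that("shape is piecewise constant between spectrum values", {
  set.seed(9)
  pts <- cbind(runif(30), runif(30)) * 50
  tri <- triangulate(pts)
  spec <- alpha_spectrum(tri)
  expect_true(all(diff(spec) > 0))
  mids <- (spec[-1] + spec[-length(spec)]) / 2
  for (k in sample(seq_along(mids), 10)) {
    expect_identical(build_alpha_shape(tri, mids[k])$kept,
                     build_alpha_shape(tri, spec[k])$kept)
  }
})

test_that("kept sets and areas are monotone in alpha", {
  set.seed(13)
  pts <- cbind(runif(35), runif(35)) * 80
  tri <- triangulate(pts)
  spec <- alpha_spectrum(tri)
  alphas <- quantile(spec, c(0.1, 0.3, 0.5, 0.7, 0.9, 1))
  prev <- NULL
  prev_area <- -1
  for (a in alphas) {
    s <- build_alpha_shape(tri, a)
    if (!is.null(prev)) expect_true(all(prev %in% s$kept))
    expect_gte(s$area, prev_area)
    prev <- s$kept
    prev_area <- s$area
  }
})

test_that("rigid motions preserve the shape; scaling is covariant", {
  set.seed(17)
  pts <- cbind(runif(30), runif(30)) * 40
  tri <- triangulate(pts)
  th <- 0.73
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- pts %*% R + matrix(c(13, -7), nrow(pts), 2, byrow = TRUE)
  tri_r <- triangulate(rot)
  expect_equal(sort(tri_r$circumradius), sort(tri$circumradius),
               tolerance = 1e-9)
  a <- median(tri$circumradius)
  s1 <- build_alpha_shape(tri, a)
  s2 <- build_alpha_shape(tri_r, a)
  expect_equal(length(s2$kept), length(s1$kept))
  expect_equal(count_regions(s2), count_regions(s1))
  expect_equal(s2$area, s1$area, tolerance = 1e-9)
  s_scale <- 3
  tri_s <- triangulate(pts * s_scale)
  expect_equal(alpha_spectrum(tri_s), s_scale * alpha_spectrum(tri),
               tolerance = 1e-9)
  s3 <- build_alpha_shape(tri_s, s_scale * a)
  expect_equal(s3$area, s_scale^2 * s1$area, tolerance = 1e-9)
})
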