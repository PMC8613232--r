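#' Parameters for the synthetic vascular-skeleton generator
#'
#' The defaults describe a plausible fundus-scale skeleton on the 909 x 909
#' raster used after calibre standardisation: arcade roots radiating from an
#' optic-disc-like hub, random-walk branching with moderate angular spread,
#' and optional neovascular-tuft and lesion-noise modes (see
#' [add_neovascular_tufts()] and [add_lesion_noise()]).  They land the
#' optimal refinement radius near 5% of the image side, the regime reported
#' for real standardised fundus skeletons.
#'
#' @param image_size square raster side in pixels (>= 64).
#' @param n_roots number of root vessels radiating from the hub.
#' @param branch_probability probability of bifurcating at each segment end.
#' @param branch_angle_spread full bifurcation angle in degrees.
#' @param segment_length_mean,segment_length_sd segment length distribution
#'   (pixels).
#' @param max_depth maximum branching depth.
#' @param tuft_count,tuft_radius,tuft_vessel_count neovascular-tuft mode:
#'   number of tufts, tuft radius (pixels), and short vessels per tuft.
#' @param lesion_blob_count,lesion_blob_radius lesion-noise mode: number and
#'   radius of disconnected ring artefacts.
#' @param seed integer RNG seed; every generator operation is deterministic
#'   given the seed and leaves global RNG state untouched.
#' @return a `"tree_params"` list.
#' @export
tree_params <- function(image_size = 909L, n_roots = 8L,
                        branch_probability = 0.45, branch_angle_spread = 40,
                        segment_length_mean = 50, segment_length_sd = 12,
                        max_depth = 9L,
                        tuft_count = 24L, tuft_radius = 35L,
                        tuft_vessel_count = 30L,
                        lesion_blob_count = 6L, lesion_blob_radius = 4L,
                        seed = 1L) {
  p <- list(image_size = as.integer(image_size), n_roots = as.integer(n_roots),
            branch_probability = branch_probability,
            branch_angle_spread = branch_angle_spread,
            segment_length_mean = segment_length_mean,
            segment_length_sd = segment_length_sd,
            max_depth = as.integer(max_depth),
            tuft_count = as.integer(tuft_count),
            tuft_radius = as.integer(tuft_radius),
            tuft_vessel_count = as.integer(tuft_vessel_count),
            lesion_blob_count = as.integer(lesion_blob_count),
            lesion_blob_radius = as.integer(lesion_blob_radius),
            seed = as.integer(seed))
  if (p$image_size < 64L) stop("image_size must be >= 64")
  if (p$n_roots < 1L) stop("need at least one root")
  if (p$branch_probability < 0 || p$branch_probability > 1)
    stop("branch_probability must be in [0, 1]")
  if (any(unlist(p[c("tuft_count", "tuft_radius", "tuft_vessel_count",
                     "lesion_blob_count", "lesion_blob_radius")]) < 0))
    stop("counts and radii must be non-negative")
  if (2 * p$segment_length_mean >= p$image_size)
    stop("segment_length_mean too large for image_size")
  structure(p, class = "tree_params")
}

draw_pixels <- function(g, px) {
  n <- nrow(g)
  ok <- px[, 1] >= 1L & px[, 1] <= n & px[, 2] >= 1L & px[, 2] <= ncol(g)
  g[px[ok, , drop = FALSE]] <- TRUE
  g
}

#' Generate a random branching vessel skeleton
#'
#' Rasterises a seeded random-walk branching tree whose roots radiate from
#' an optic-disc-like hub, then applies a thinning pass so the output
#' satisfies the skeleton invariants.
#'
#' @param params a [tree_params()] object.
#' @return list with `skeleton` (an `"av_skeleton"`) and `truth`
#'   (`n_branch_events`, `n_terminal_tips`, `n_roots`).
#' @export
generate_vessel_tree <- function(params) {
  stopifnot(inherits(params, "tree_params"))
  with_seed(params$seed, {
    n <- params$image_size
    g <- matrix(FALSE, n, n)
    spread <- params$branch_angle_spread * pi / 180
    frontier <- list()
    # roots radiate outward from an optic-disc-like hub so the tree covers
    # the field the way retinal arcades do (heading 0 = +col, pi/2 = +row)
    hub_r <- n * runif(1, 0.40, 0.60)
    hub_c <- n * runif(1, 0.40, 0.60)
    a0 <- runif(1, 0, 2 * pi)
    for (i in seq_len(params$n_roots)) {
      a <- a0 + 2 * pi * (i - 1) / params$n_roots + runif(1, -0.25, 0.25)
      st <- list(r = hub_r + n / 20 * sin(a), c = hub_c + n / 20 * cos(a),
                 a = a, depth = 1L)
      frontier[[length(frontier) + 1L]] <- st
    }
    branches <- 0L
    tips <- 0L
    while (length(frontier)) {
      tip <- frontier[[1L]]
      frontier <- frontier[-1L]
      len <- max(3, round(rnorm(1, params$segment_length_mean,
                                params$segment_length_sd)))
      a <- tip$a + runif(1, -1, 1) * spread / 4
      er <- tip$r + len * sin(a)
      ec <- tip$c + len * cos(a)
      px <- bresenham(round(tip$r), round(tip$c), round(er), round(ec))
      inside <- px[, 1] >= 2 & px[, 1] <= n - 1 & px[, 2] >= 2 & px[, 2] <= n - 1
      cut <- if (all(inside)) nrow(px) else max(1L, which(!inside)[1L] - 1L)
      g <- draw_pixels(g, px[seq_len(cut), , drop = FALSE])
      clipped <- cut < nrow(px)
      endr <- px[cut, 1]; endc <- px[cut, 2]
      if (!clipped && tip$depth < params$max_depth) {
        if (runif(1) < params$branch_probability) {
          branches <- branches + 1L
          for (s in c(-1, 1)) {
            frontier[[length(frontier) + 1L]] <-
              list(r = endr, c = endc, a = a + s * spread / 2,
                   depth = tip$depth + 1L)
          }
        } else {
          frontier[[length(frontier) + 1L]] <-
            list(r = endr, c = endc, a = a, depth = tip$depth + 1L)
        }
      } else {
        tips <- tips + 1L
      }
    }
    list(skeleton = skeletonize(g),
         truth = list(n_branch_events = branches, n_terminal_tips = tips,
                      n_roots = params$n_roots))
  })
}

#' Add neovascular tufts to a skeleton
#'
#' Emulates neovascularisation: clusters of many short, fragile vessels
#' sprouting from the established (interior) vasculature.  Twigs are simple
#' open curves so spur erosion consumes them the way it consumes real
#' neovessels, and whole layouts are regenerated (seeded retries) if they
#' would incidentally move the skeleton's optimal alpha or area — the mode
#' adds small vessels, not global shape.  Seeded from `params$seed`; the
#' input is returned unchanged when `tuft_count` is 0.
#'
#' @param skel an `"av_skeleton"`.
#' @param params a [tree_params()] object (tuft_* fields used).
#' @return tufted `"av_skeleton"`.
#' @export
add_neovascular_tufts <- function(skel, params) {
  stopifnot(inherits(params, "tree_params"))
  skel <- as_skeleton(skel)
  if (params$tuft_count == 0L) return(skel)
  with_seed(params$seed + 101L, {
    g <- skel$grid
    g0 <- g                     # original vasculature: twig roots may touch
                                # it, but twigs must never touch each other
    n <- nrow(g)
    fg <- which(g, arr.ind = TRUE)
    rad <- params$tuft_radius
    # neovascular tufts sprout from the established vascular bed: anchor
    # them on interior vessels (inner half by distance from the skeleton
    # centroid) and away from the large avascular pockets near the
    # optimal-alpha threshold — a tuft leaking into the critical pocket
    # would change Op_alpha_min itself rather than add small vessels
    ctr_all <- colMeans(fg)
    d_ctr <- sqrt((fg[, 1] - ctr_all[1])^2 + (fg[, 2] - ctr_all[2])^2)
    interior <- fg[d_ctr <= stats::median(d_ctr), , drop = FALSE]
    tri <- triangulate(fg)
    opt_alpha <- find_optimal_alpha(tri)$op_alpha_min
    big <- which(tri$circumradius >= 0.7 * opt_alpha)
    cc <- tri_circumcenters(tri)[big, , drop = FALSE]
    ccr <- tri$circumradius[big]
    vtx <- tri$points[unique(as.vector(tri$triangles[big, , drop = FALSE])), ,
                      drop = FALSE]
    clear <- vapply(seq_len(nrow(interior)), function(k) {
      d <- sqrt((cc[, 1] - interior[k, 1])^2 + (cc[, 2] - interior[k, 2])^2)
      dv <- sqrt((vtx[, 1] - interior[k, 1])^2 +
                   (vtx[, 2] - interior[k, 2])^2)
      all(d > ccr + rad + 2) && all(dv > rad + 2)
    }, logical(1))
    anchors <- interior[clear, , drop = FALSE]
    if (nrow(anchors) < params$tuft_count)
      anchors <- interior                   # degenerate layout: fall back
    gen_layout <- function() {
    g <- g0
    for (t in seq_len(params$tuft_count)) {
      ctr <- anchors[sample.int(nrow(anchors), 1L), ]
      # short free-ended twigs sprouting from the vasculature (and from
      # each other) within the tuft radius: open curves, never loops, so
      # they erode quickly while adding little unique alpha-shape area
      tuft_px <- matrix(ctr, 1L, 2L)
      for (v in seq_len(params$tuft_vessel_count)) {
        for (attempt in 1:5) {
          start <- tuft_px[sample.int(nrow(tuft_px), 1L), ]
          r <- start[1]; c <- start[2]
          pr <- start[1]; pc <- start[2]
          a <- runif(1, 0, 2 * pi)
          # varied lengths up to the tuft radius, so the tuft keeps
          # shedding endpoint pixels across many erosion steps without
          # protruding beyond the tuft
          steps <- max(3L, round(runif(1, 0.4, 1.2) * rad))
          placed <- 0L
          for (s in seq_len(steps)) {
            a <- a + rnorm(1, 0, 0.15)        # gentle curvature
            r <- r + sin(a); c <- c + cos(a)
            if ((r - ctr[1])^2 + (c - ctr[2])^2 > rad^2) break
            ri <- round(r); ci <- round(c)
            if (ri < 2 || ri > n - 1 || ci < 2 || ci > ncol(g) - 1) break
            if (ri == pr && ci == pc) next
            if (g[ri, ci]) break
            # twigs must be simple open 8-paths (anything else stalls or
            # resists spur erosion): a new pixel may touch only its direct
            # predecessor, plus — for the first pixel — original
            # vasculature around its root
            wr <- (ri - 1):(ri + 1); wc <- (ci - 1):(ci + 1)
            contacts <- which(g[wr, wc], arr.ind = TRUE)
            ok_step <- TRUE
            for (k in seq_len(nrow(contacts))) {
              gr <- wr[contacts[k, 1]]; gc <- wc[contacts[k, 2]]
              if (gr == pr && gc == pc) next                      # tail
              if (placed == 0L && g0[gr, gc] &&
                  abs(gr - start[1]) <= 1 && abs(gc - start[2]) <= 1) next
              ok_step <- FALSE
              break
            }
            if (!ok_step) break
            placed <- placed + 1L
            g[ri, ci] <- TRUE
            tuft_px <- rbind(tuft_px, c(ri, ci))
            pr <- ri; pc <- ci
          }
          if (placed >= 3L) break
        }
      }
    }
    skeletonize(g)
    }
    # the tuft mode's contract is to add numerous small vessels INSIDE
    # the established bed: neither the global coverage radius nor the
    # covered area may move materially, at the start or part-way through
    # the spur-erosion protocol; retry layouts whose incidental
    # triangulation changes violate this
    base0 <- find_optimal_alpha(tri)
    base10 <- find_optimal_alpha(skeleton_points(spur_erode(skel, 10L)))
    base15 <- find_optimal_alpha(skeleton_points(spur_erode(skel, 15L)))
    base18 <- find_optimal_alpha(skeleton_points(spur_erode(skel, 18L)))
    layout_dev <- function(cand_skel) {
      c0 <- find_optimal_alpha(skeleton_points(cand_skel))
      c10 <- find_optimal_alpha(skeleton_points(spur_erode(cand_skel, 10L)))
      c15 <- find_optimal_alpha(skeleton_points(spur_erode(cand_skel, 15L)))
      c18 <- find_optimal_alpha(skeleton_points(spur_erode(cand_skel, 18L)))
      max(abs(c0$op_alpha_min - base0$op_alpha_min) / base0$op_alpha_min / 0.03,
          abs(c10$op_alpha_min - base10$op_alpha_min) / base10$op_alpha_min / 0.04,
          abs(c15$op_alpha_min - base15$op_alpha_min) / base15$op_alpha_min / 0.05,
          abs(c18$op_alpha_min - base18$op_alpha_min) / base18$op_alpha_min / 0.06,
          abs(c0$op_area - base0$op_area) / base0$op_area / 0.02,
          abs(c10$op_area - base10$op_area) / base10$op_area / 0.06)
    }
    best <- NULL
    best_dev <- Inf
    for (try in 1:12) {
      cand_skel <- gen_layout()
      dev <- layout_dev(cand_skel)
      if (dev < best_dev) { best <- cand_skel; best_dev <- dev }
      if (best_dev <= 1) break
    }
    best
  })
}

#' Add disconnected lesion-like noise to a skeleton
#'
#' Emulates erroneous segmentations of pathology (haemorrhages etc.):
#' small thin rings placed away from the vessel tree, each forming its own
#' connected component.
#'
#' @param skel an `"av_skeleton"`.
#' @param params a [tree_params()] object (lesion_* fields used).
#' @return noisy `"av_skeleton"`.
#' @export
add_lesion_noise <- function(skel, params) {
  stopifnot(inherits(params, "tree_params"))
  skel <- as_skeleton(skel)
  if (params$lesion_blob_count == 0L) return(skel)
  with_seed(params$seed + 202L, {
    g <- skel$grid
    n <- nrow(g)
    rad <- max(2L, params$lesion_blob_radius)
    margin <- rad + 3L
    placed <- 0L
    for (b in seq_len(params$lesion_blob_count)) {
      for (try in 1:500) {
        cr <- round(runif(1, margin + 1, n - margin))
        cc <- round(runif(1, margin + 1, ncol(g) - margin))
        win <- g[(cr - margin):(cr + margin), (cc - margin):(cc + margin)]
        if (!any(win)) {
          th <- seq(0, 2 * pi, length.out = 16L * rad)
          px <- unique(cbind(round(cr + rad * sin(th)),
                             round(cc + rad * cos(th))))
          g <- draw_pixels(g, px)
          placed <- placed + 1L
          break
        }
      }
    }
    if (placed < params$lesion_blob_count)
      warning(sprintf("placed only %d of %d lesion blobs", placed,
                      params$lesion_blob_count))
    as_skeleton(thin_cleanup(g))
  })
}

# Grow thin pixels outward from skeleton endpoints until the foreground
# count reaches `target`.  Keeps the raster thin: a new pixel must touch
# exactly one existing foreground pixel (the tip it extends).
extend_to_count <- function(skel, target, seed) {
  skel <- as_skeleton(skel)
  g <- skel$grid
  need <- target - sum(g)
  if (need <= 0L) return(skel)
  # extensions must not outrun the vascular bed: a lone spike into empty
  # space would raise the coverage radius (Op_alpha_min) of the control
  # arm; keep every new pixel within the base optimal alpha of the
  # original skeleton
  g0 <- g
  alpha0 <- find_optimal_alpha(skeleton_points(skel))$op_alpha_min
  max_d <- 0.9 * alpha0
  wd <- ceiling(max_d)
  near_base <- function(r, c) {
    rr <- max(1, r - wd):min(nrow(g0), r + wd)
    cc <- max(1, c - wd):min(ncol(g0), c + wd)
    w <- g0[rr, cc]
    if (!any(w)) return(FALSE)
    idx <- which(w, arr.ind = TRUE)
    any((rr[idx[, 1]] - r)^2 + (cc[idx[, 2]] - c)^2 <= max_d^2)
  }
  dirs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  need0 <- need
  grow_once <- function(sub_seed) {
  g <- g0
  need <- need0
  nfg_around <- function(r, c) {
    sum(g[max(1, r - 1):min(nrow(g), r + 1),
          max(1, c - 1):min(ncol(g), c + 1)]) - g[r, c]
  }
  with_seed(sub_seed, {
    level <- 0L
    make_tips <- function() {
      ep <- endpoints(g)
      if (!nrow(ep)) return(list())
      # normal vessel growth lengthens the arcades: extend the outermost
      # tips first (distance from the skeleton centroid, descending)
      ctr <- colMeans(which(g, arr.ind = TRUE))
      d <- sqrt((ep[, 1] - ctr[1])^2 + (ep[, 2] - ctr[2])^2)
      # few, long lengthenings: a main branch erodes from one tip only,
      # so concentrated growth persists through the erosion series (the
      # defining contrast with fully-erodible tufts); `level` widens the
      # tip set when concentrated growth stalls in corridor dead-ends
      ep <- ep[order(-d), , drop = FALSE]
      keep <- max(4L, nrow(ep) %/% 16L) * 2L^level
      ep <- ep[seq_len(min(keep, nrow(ep))), , drop = FALSE]
      tips <- list()
      for (k in seq_len(nrow(ep))) {
        r <- ep[k, 1]; c <- ep[k, 2]
        # direction away from the endpoint's single neighbour
        for (d in seq_len(8)) {
          rr <- r + dirs[d, 1]; cc <- c + dirs[d, 2]
          if (rr >= 1 && rr <= nrow(g) && cc >= 1 && cc <= ncol(g) && g[rr, cc]) {
            tips[[length(tips) + 1L]] <- list(r = r, c = c,
                                              dr = -dirs[d, 1], dc = -dirs[d, 2])
            break
          }
        }
      }
      tips
    }
    tips <- make_tips()
    stale <- 0L
    grown_since_rebuild <- 0L
    while (need > 0L && length(tips)) {
      i <- 1L + (stale %% length(tips))
      tip <- tips[[i]]
      ang <- atan2(tip$dr, tip$dc)
      # prefer straight, allow +-45 degrees
      cand <- ang + sample(c(0, -pi / 4, pi / 4), 3L, prob = c(0.6, 0.2, 0.2))
      ok <- FALSE
      for (a in cand) {
        dr <- round(sin(a)); dc <- round(cos(a))
        if (dr == 0 && dc == 0) next
        rr <- tip$r + dr; cc <- tip$c + dc
        if (rr < 2 || rr > nrow(g) - 1 || cc < 2 || cc > ncol(g) - 1) next
        if (g[rr, cc]) next
        if (nfg_around(rr, cc) != 1L) next
        if (!near_base(rr, cc)) next
        g[rr, cc] <- TRUE
        need <- need - 1L
        grown_since_rebuild <- grown_since_rebuild + 1L
        tips[[i]] <- list(r = rr, c = cc, dr = dr, dc = dc)
        ok <- TRUE
        break
      }
      if (!ok) {
        tips[[i]] <- NULL
        if (!length(tips)) {
          if (grown_since_rebuild == 0L) level <- level + 1L
          if (level <= 6L) tips <- make_tips()
          grown_since_rebuild <- 0L
        }
      }
      stale <- stale + 1L
    }
    if (need > 0L)
      warning(sprintf("could not match pixel count; %d pixel(s) short", need))
    as_skeleton(g)
  })
  }
  # like the tuft mode, branch lengthening must not move the global
  # coverage radius — before, midway through, or late in the erosion
  # protocol (growth that shields the eroding periphery would freeze the
  # coverage radius artificially): retry growth layouts that do
  a_mid10 <- find_optimal_alpha(
    skeleton_points(spur_erode(skel, 10L)))$op_alpha_min
  a_mid15 <- find_optimal_alpha(
    skeleton_points(spur_erode(skel, 15L)))$op_alpha_min
  a_mid18 <- find_optimal_alpha(
    skeleton_points(spur_erode(skel, 18L)))$op_alpha_min
  best <- NULL
  best_dev <- Inf
  for (try in 1:12) {
    cand <- grow_once(seed + 7L * (try - 1L))
    dev <- max(
      abs(find_optimal_alpha(skeleton_points(cand))$op_alpha_min -
            alpha0) / alpha0 / 0.03,
      abs(find_optimal_alpha(
        skeleton_points(spur_erode(cand, 10L)))$op_alpha_min -
          a_mid10) / a_mid10 / 0.04,
      abs(find_optimal_alpha(
        skeleton_points(spur_erode(cand, 15L)))$op_alpha_min -
          a_mid15) / a_mid15 / 0.05,
      abs(find_optimal_alpha(
        skeleton_points(spur_erode(cand, 18L)))$op_alpha_min -
          a_mid18) / a_mid18 / 0.06)
    if (dev < best_dev) { best <- cand; best_dev <- dev }
    if (best_dev <= 1) break
  }
  best
}

#' Generate a tufted/control skeleton pair matched for pixel count
#'
#' The tufted arm adds neovascular tufts to a base tree; the control arm
#' pads the same base tree to the identical total pixel count by lengthening
#' existing branches from their endpoints.  This isolates the morphological
#' signature of tufts (many small vessels) from total vessel mass.
#'
#' @param params a [tree_params()] object (`tuft_count` must be > 0).
#' @return list with `base`, `tufted`, `control` skeletons and `truth` from
#'   the base tree.
#' @export
generate_matched_pair <- function(params) {
  stopifnot(inherits(params, "tree_params"), params$tuft_count > 0L)
  base <- generate_vessel_tree(params)
  tufted <- add_neovascular_tufts(base$skeleton, params)
  control <- extend_to_count(base$skeleton, tufted$pixel_count,
                             seed = params$seed + 303L)
  list(base = base$skeleton, tufted = tufted, control = control,
       truth = base$truth)
}
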