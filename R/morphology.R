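#' Binary mask and skeleton containers
#'
#' Thin wrappers around logical rasters.  A mask is any binary segmentation;
#' a skeleton is a 1-pixel-wide centreline raster (no fully-foreground 2x2
#' block).  Coordinates are (row, col), 1-based, row increasing downward.
#'
#' @param grid logical (or 0/1 numeric) matrix.
#' @return an `"av_mask"` / `"av_skeleton"` object.
#' @export
as_mask <- function(grid) {
  g <- as_binary_grid(grid)
  structure(list(grid = g, height = nrow(g), width = ncol(g)),
            class = "av_mask")
}

#' @rdname as_mask
#' @export
as_skeleton <- function(grid) {
  g <- as_binary_grid(grid)
  structure(list(grid = g, pixel_count = sum(g)), class = "av_skeleton")
}

as_binary_grid <- function(grid) {
  if (inherits(grid, c("av_mask", "av_skeleton"))) grid <- grid$grid
  g <- as.matrix(grid)
  if (is.numeric(g)) g <- g != 0
  if (!is.logical(g)) stop("grid must be logical or numeric")
  g[is.na(g)] <- FALSE
  dimnames(g) <- NULL
  g
}

#' @export
print.av_mask <- function(x, ...) {
  cat(sprintf("mask: %d x %d, %d foreground px\n", x$height, x$width,
              sum(x$grid)))
  invisible(x)
}

#' @export
print.av_skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d x %d, %d px\n", nrow(x$grid), ncol(x$grid),
              x$pixel_count))
  invisible(x)
}

#' Foreground coordinates of a skeleton
#' @param skel an `"av_skeleton"` (or mask/matrix).
#' @return two-column matrix (row, col) of foreground pixel centres.
#' @export
skeleton_points <- function(skel) {
  g <- as_binary_grid(skel)
  unname(which(g, arr.ind = TRUE))
}

# Eight neighbour planes of g in the clockwise order N, NE, E, SE, S, SW, W,
# NW (the classic P2..P9), padded with background.
neighbour_planes <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1), 2:(nc + 1)] <- g
  list(
    p[1:nr, 2:(nc + 1)],        # N
    p[1:nr, 3:(nc + 2)],        # NE
    p[2:(nr + 1), 3:(nc + 2)],  # E
    p[3:(nr + 2), 3:(nc + 2)],  # SE
    p[3:(nr + 2), 2:(nc + 1)],  # S
    p[3:(nr + 2), 1:nc],        # SW
    p[2:(nr + 1), 1:nc],        # W
    p[1:nr, 1:nc]               # NW
  )
}

neighbour_count <- function(g) {
  Reduce(`+`, lapply(neighbour_planes(g), function(m) m * 1L))
}

# Crossing number: 0->1 transitions around the 8-neighbourhood (cyclic).
crossing_number <- function(np) {
  tr <- matrix(0L, nrow(np[[1]]), ncol(np[[1]]))
  for (i in 1:8) {
    a <- np[[i]]
    b <- np[[if (i == 8) 1 else i + 1]]
    tr <- tr + (!a & b)
  }
  tr
}

#' Skeletonize a binary mask by iterative thinning
#'
#' Topology-preserving two-subiteration thinning to 1-pixel-wide
#' centrelines, followed by a staircase cleanup that removes redundant
#' pixels from any remaining fully-foreground 2x2 block.  Idempotent on
#' already-thin input.
#'
#' @param mask an `"av_mask"`, skeleton, or logical matrix with at least one
#'   foreground pixel.
#' @return an `"av_skeleton"`.
#' @export
skeletonize <- function(mask) {
  g <- as_binary_grid(mask)
  if (!any(g)) stop("cannot skeletonize an empty mask")
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      np <- neighbour_planes(g)
      B <- Reduce(`+`, lapply(np, function(m) m * 1L))
      A <- crossing_number(np)
      if (pass == 1) {
        cond <- !(np[[1]] & np[[3]] & np[[5]]) & !(np[[3]] & np[[5]] & np[[7]])
      } else {
        cond <- !(np[[1]] & np[[3]] & np[[7]]) & !(np[[1]] & np[[5]] & np[[7]])
      }
      del <- g & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        g[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  as_skeleton(thin_cleanup(g))
}

# Remove pixels from fully-foreground 2x2 blocks one at a time so the
# thinness invariant (no full 2x2 block) holds without breaking topology.
# A pixel is removable when its remaining neighbours stay 8-connected
# within the surrounding 5x5 window (covers junction thickenings whose
# crossing number alone would forbid any deletion).
thin_cleanup <- function(g) {
  locally_safe <- function(r, c) {
    rr <- max(1, r - 2):min(nrow(g), r + 2)
    cc <- max(1, c - 2):min(ncol(g), c + 2)
    w <- g[rr, cc]
    w[match(r, rr), match(c, cc)] <- FALSE
    nb <- which(w, arr.ind = TRUE)
    nb <- nb[abs(nb[, 1] - match(r, rr)) <= 1 &
               abs(nb[, 2] - match(c, cc)) <= 1, , drop = FALSE]
    if (nrow(nb) <= 1L) return(nrow(nb) == 1L)  # never strand a pixel
    # flood fill the window from one neighbour; all neighbours must be hit
    lab <- matrix(FALSE, nrow(w), ncol(w))
    stack <- list(nb[1, ])
    lab[nb[1, 1], nb[1, 2]] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1 && r2 <= nrow(w) && c2 >= 1 && c2 <= ncol(w) &&
            w[r2, c2] && !lab[r2, c2]) {
          lab[r2, c2] <- TRUE
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
    all(lab[nb])
  }
  repeat {
    blk <- g[-nrow(g), -ncol(g)] & g[-1, -ncol(g)] &
      g[-nrow(g), -1] & g[-1, -1]
    if (!any(blk)) return(g)
    np <- neighbour_planes(g)
    A <- crossing_number(np)
    B <- neighbour_count(g)
    inblk <- matrix(FALSE, nrow(g), ncol(g))
    idx <- which(blk, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c <- idx[k, 2]
      inblk[r:(r + 1), c:(c + 1)] <- TRUE
    }
    cand <- which(g & inblk & B > 1)
    cand <- cand[order(A[cand])]              # simplest pixels first
    removed <- FALSE
    for (cd in cand) {
      rc <- arrayInd(cd, dim(g))
      if (A[cd] == 1L || locally_safe(rc[1], rc[2])) {
        g[cd] <- FALSE
        removed <- TRUE
        break
      }
    }
    if (!removed) return(g)    # nothing safely removable
  }
}

#' Skeleton endpoints
#'
#' Foreground pixels with exactly one foreground 8-neighbour — the free ends
#' of vessels that spur erosion removes.
#'
#' @param skel an `"av_skeleton"` (or binary matrix).
#' @return two-column matrix (row, col); zero rows if none.
#' @export
endpoints <- function(skel) {
  g <- as_binary_grid(skel)
  unname(which(g & neighbour_count(g) == 1L, arr.ind = TRUE))
}

#' Spur erosion of a skeleton
#'
#' Each iteration simultaneously deletes every current endpoint pixel,
#' shortening each free vessel end by one pixel; closed loops and isolated
#' pixels are untouched.
#'
#' @param skel an `"av_skeleton"` (or binary matrix).
#' @param iterations non-negative iteration count.
#' @return eroded `"av_skeleton"` (possibly empty).
#' @export
spur_erode <- function(skel, iterations) {
  stopifnot(length(iterations) == 1L, iterations >= 0)
  g <- as_binary_grid(skel)
  for (i in seq_len(iterations)) {
    ep <- g & neighbour_count(g) == 1L
    if (!any(ep)) break               # fixed point
    g[ep] <- FALSE
  }
  as_skeleton(g)
}

#' Incremental spur-erosion series
#'
#' Iteration 0 is the input skeleton at 100%; iteration k is k applications
#' of [spur_erode()].  If the skeleton empties before `n_iterations`, the
#' series is truncated at the last nonempty iteration with a warning.
#'
#' @param skel input skeleton.
#' @param n_iterations number of erosion iterations (default 20).
#' @return object of class `"erosion_series"`: list with `iterations`
#'   (list of `list(iteration, skeleton, percent_remaining)`) and
#'   `n_iterations` (performed count).
#' @export
erosion_series <- function(skel, n_iterations = 20L) {
  stopifnot(n_iterations >= 1L)
  s0 <- as_skeleton(skel)
  if (s0$pixel_count == 0L) stop("input skeleton is empty")
  base <- s0$pixel_count
  out <- vector("list", n_iterations + 1L)
  out[[1L]] <- list(iteration = 0L, skeleton = s0, percent_remaining = 100)
  cur <- s0
  done <- 0L
  for (k in seq_len(n_iterations)) {
    cur <- spur_erode(cur, 1L)
    if (cur$pixel_count == 0L) {
      warning(sprintf("skeleton emptied at iteration %d; series truncated", k))
      break
    }
    out[[k + 1L]] <- list(iteration = k, skeleton = cur,
                          percent_remaining = 100 * cur$pixel_count / base)
    done <- k
  }
  structure(list(iterations = out[seq_len(done + 1L)], n_iterations = done),
            class = "erosion_series")
}

#' @export
print.erosion_series <- function(x, ...) {
  pr <- vapply(x$iterations, `[[`, numeric(1), "percent_remaining")
  cat(sprintf("erosion series: %d iteration(s), %% remaining %s\n",
              x$n_iterations,
              paste(sprintf("%.0f", pr), collapse = " ")))
  invisible(x)
}
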