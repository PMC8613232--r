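#' Vessel shape (VS): spread over complexity
#'
#' VS = OpA / Op_alpha_min, the area of the optimum alpha-shape divided by
#' its refinement radius.  Units: pixels (area / length).
#'
#' @param op_area area of the optimum alpha-shape (squared pixels).
#' @param op_alpha_min optimal refinement radius (pixels), > 0.
#' @return VS value.
#' @export
vessel_shape <- function(op_area, op_alpha_min) {
  if (!is.finite(op_alpha_min) || op_alpha_min <= 0)
    stop("op_alpha_min must be positive")
  op_area / op_alpha_min
}

#' Robust straight-line fit (IRLS, Tukey bisquare)
#'
#' Iteratively reweighted least squares with the bisquare influence
#' function: tuning constant 4.685, scale re-estimated each iteration as
#' MAD(residuals)/0.6745, at most 50 iterations, coefficient-change
#' tolerance 1e-8.  Reduces to ordinary least squares on clean data.
#'
#' @param x,y numeric vectors (>= 2 observations, >= 2 distinct x).
#' @param c_tuning bisquare tuning constant.
#' @param max_iter,tol iteration controls.
#' @return object of class `"robust_line"`: `slope`, `intercept`, `weights`,
#'   `converged`, `n_iterations`.
#' @export
robust_line_fit <- function(x, y, c_tuning = 4.685, max_iter = 50L,
                            tol = 1e-8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (length(unique(x)) < 2L)
    stop("all x values identical: slope undefined")
  X <- cbind(1, x)
  beta <- qr.coef(qr(X), y)
  w <- rep(1, length(x))
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    r <- y - X %*% beta
    s <- median(abs(r)) / 0.6745
    if (s <= 1e-12 * max(1, median(abs(y)))) {   # (near-)exact fit
      w <- rep(1, length(x)); converged <- TRUE; break
    }
    u <- r / (c_tuning * s)
    w <- as.numeric(ifelse(abs(u) < 1, (1 - u^2)^2, 0))
    if (sum(w > 0) < 2L) break                   # degenerate weighting
    fit <- lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol * max(1, max(abs(beta)))) {
      converged <- TRUE; break
    }
  }
  structure(list(slope = unname(beta[2]), intercept = unname(beta[1]),
                 weights = pmin(pmax(w, 0), 1), converged = converged,
                 n_iterations = iters),
            class = "robust_line")
}

#' @export
print.robust_line <- function(x, ...) {
  cat(sprintf("robust line: y = %g + %g x (%s, %d iterations)\n",
              x$intercept, x$slope,
              if (x$converged) "converged" else "not converged",
              x$n_iterations))
  invisible(x)
}

#' Grad_alpha: erosion-series gradient of VS
#'
#' For each iteration of a spur-erosion series, the optimal alpha-shape of
#' the eroded skeleton is recomputed and VS formed; Grad_alpha is the slope
#' of the robust regression of VS on the percentage of pixels remaining
#' (0–100 scale, iteration 0 included).  A low Grad_alpha means VS decays
#' slowly under erosion — the signature of many small branches
#' (neovascularisation-like fragmentation).  Units: VS per percentage point.
#'
#' @param series an `"erosion_series"`.
#' @param return_fit return the full fit and per-iteration table instead of
#'   the bare slope.
#' @return slope (numeric), or when `return_fit = TRUE` a list with `slope`,
#'   `fit`, and `table` (iteration, percent_remaining, op_alpha_min,
#'   op_area, vs).
#' @export
grad_alpha <- function(series, return_fit = FALSE) {
  stopifnot(inherits(series, "erosion_series"))
  its <- series$iterations
  pct <- numeric(0); vs <- numeric(0)
  oam <- numeric(0); oa <- numeric(0); itn <- integer(0)
  for (it in its) {
    pts <- skeleton_points(it$skeleton)
    if (nrow(pts) < 3L || is_collinear(as_point_matrix(pts))) {
      warning(sprintf(
        "iteration %d skeleton degenerate (<3 non-collinear points); series truncated",
        it$iteration))
      break
    }
    opt <- find_optimal_alpha(pts)
    itn <- c(itn, it$iteration)
    pct <- c(pct, it$percent_remaining)
    oam <- c(oam, opt$op_alpha_min)
    oa <- c(oa, opt$op_area)
    vs <- c(vs, vessel_shape(opt$op_area, opt$op_alpha_min))
  }
  if (length(pct) < 3L)
    stop("fewer than 3 usable erosion iterations")
  fit <- robust_line_fit(pct, vs)
  if (!return_fit) return(fit$slope)
  list(slope = fit$slope, fit = fit,
       table = data.frame(iteration = itn, percent_remaining = pct,
                          op_alpha_min = oam, op_area = oa, vs = vs))
}

#' Compute all alpha-shape descriptors for one image
#'
#' Runs the full per-image pipeline: thinning (if given a mask), the optimal
#' alpha-shape (Op_alpha_min, OpA), VS, the spur-erosion series and
#' Grad_alpha, and optionally a comparator fractal dimension.  Deterministic
#' for fixed input and configuration.
#'
#' @param input an `"av_mask"`, `"av_skeleton"`, or binary matrix (treated
#'   as a mask and thinned; thinning is idempotent so passing a skeleton is
#'   equivalent).
#' @param image_id identifier attached to the record and to error messages.
#' @param iterations erosion iterations for Grad_alpha (default 20).
#' @param fd compute a fractal dimension? (`FALSE`, `"box_counting"` or
#'   `"sandbox"`; `TRUE` means box counting).
#' @param group_label optional group tag (e.g. DR grade) carried through to
#'   the statistics stage.
#' @param fd_seed seed for the sandbox estimator (ignored otherwise).
#' @return object of class `"descriptor_record"`: `image_id`,
#'   `op_alpha_min`, `op_area`, `vs`, `grad_alpha`, `fd` (NA if disabled),
#'   `group_label`.
#' @export
compute_descriptors <- function(input, image_id = "image", iterations = 20L,
                                fd = FALSE, group_label = NA_character_,
                                fd_seed = 1L) {
  rec <- tryCatch({
    skel <- if (inherits(input, "av_skeleton")) input else skeletonize(input)
    opt <- find_optimal_alpha(skeleton_points(skel))
    vs <- vessel_shape(opt$op_area, opt$op_alpha_min)
    series <- erosion_series(skel, iterations)
    ga <- grad_alpha(series)
    fdval <- NA_real_
    if (!identical(fd, FALSE)) {
      method <- if (isTRUE(fd)) "box_counting" else match.arg(fd, c("box_counting", "sandbox"))
      fdval <- if (method == "box_counting") box_counting_fd(skel)$fd
               else sandbox_fd(skel, seed = fd_seed)$fd
    }
    list(image_id = image_id, op_alpha_min = opt$op_alpha_min,
         op_area = opt$op_area, vs = vs, grad_alpha = ga, fd = fdval,
         group_label = group_label)
  }, error = function(e) {
    stop(sprintf("[%s] %s", image_id, conditionMessage(e)), call. = FALSE)
  })
  structure(rec, class = "descriptor_record")
}

#' @export
print.descriptor_record <- function(x, ...) {
  cat(sprintf(
    "%s: Op_alpha_min = %.4g, OpA = %.6g, VS = %.6g, Grad_alpha = %.4g%s\n",
    x$image_id, x$op_alpha_min, x$op_area, x$vs, x$grad_alpha,
    if (is.na(x$fd)) "" else sprintf(", FD = %.3f", x$fd)))
  invisible(x)
}

#' @export
as.data.frame.descriptor_record <- function(x, ...) {
  data.frame(image_id = x$image_id, op_alpha_min = x$op_alpha_min,
             op_area = x$op_area, vs = x$vs, grad_alpha = x$grad_alpha,
             fd = x$fd, group_label = x$group_label,
             stringsAsFactors = FALSE)
}

#' Bind descriptor records into a data frame
#' @param records list of `"descriptor_record"` objects.
#' @return data.frame, one row per record.
#' @export
records_to_frame <- function(records) {
  if (inherits(records, "descriptor_record")) records <- list(records)
  do.call(rbind, lapply(records, as.data.frame))
}
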