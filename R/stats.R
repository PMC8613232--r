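#' Group comparison of descriptors across DR grades
#'
#' Per descriptor: group means and SDs, a Kruskal-Wallis omnibus test
#' (tie-corrected), Benjamini-Hochberg adjustment of the omnibus p-values
#' across the family of descriptors, and — where the adjusted omnibus
#' p-value survives `alpha_level` — Dunn pairwise post-hoc z tests with
#' Bonferroni correction over all group pairs.
#'
#' @param table data.frame with a `group_label` column and one numeric
#'   column per descriptor, or a list of `"descriptor_record"` objects.
#' @param parameters descriptor column names to analyse; default all
#'   numeric columns except identifiers.
#' @param alpha_level significance level (default 0.05).
#' @return object of class `"group_comparison"`: `summary` data.frame
#'   (parameter, per-group mean/sd, statistic, df, p, p_adjusted,
#'   significant) and `posthoc` data.frame (parameter, group1, group2, z,
#'   p, p_bonferroni, significant).
#' @export
group_comparison <- function(table, parameters = NULL, alpha_level = 0.05) {
  df <- if (is.data.frame(table)) table else records_to_frame(table)
  if (!"group_label" %in% names(df)) stop("table needs a group_label column")
  groups <- unique(df$group_label)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(parameters)) {
    parameters <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          c("image_id"))
  }
  res <- list(); ph <- list()
  for (p in parameters) {
    v <- df[[p]]; gl <- df$group_label
    keep <- !is.na(v)
    v <- v[keep]; gl <- gl[keep]
    sizes <- table(gl)
    if (length(sizes) < 2L || any(sizes < 2L)) {
      warning(sprintf("parameter '%s' skipped: a group has < 2 observations", p))
      next
    }
    kw <- kruskal.test(v, factor(gl))
    means <- tapply(v, gl, mean)
    sds <- tapply(v, gl, sd)
    res[[p]] <- list(parameter = p, means = means, sds = sds,
                     statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p = kw$p.value)
    ph[[p]] <- dunn_posthoc(v, gl)
  }
  if (!length(res)) stop("no analysable parameters")
  praw <- vapply(res, `[[`, numeric(1), "p")
  padj <- p.adjust(praw, method = "BH")
  summ <- do.call(rbind, lapply(seq_along(res), function(i) {
    r <- res[[i]]
    row <- data.frame(parameter = r$parameter, statistic = r$statistic,
                      df = r$df, p = r$p, p_adjusted = padj[i],
                      significant = padj[i] < alpha_level)
    for (gname in names(r$means)) {
      row[[paste0("mean_", gname)]] <- unname(r$means[gname])
      row[[paste0("sd_", gname)]] <- unname(r$sds[gname])
    }
    row
  }))
  posthoc <- do.call(rbind, lapply(seq_along(res), function(i) {
    if (padj[i] >= alpha_level) return(NULL)
    cbind(parameter = res[[i]]$parameter, ph[[names(res)[i]]])
  }))
  structure(list(summary = summ, posthoc = posthoc,
                 alpha_level = alpha_level),
            class = "group_comparison")
}

# Dunn's pairwise rank post-hoc with midranks, tie-corrected variance, and
# Bonferroni correction over all group pairs.
dunn_posthoc <- function(values, group_labels) {
  gl <- as.character(group_labels)
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(values)
  C <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - C
  groups <- sort(unique(gl))
  rbar <- tapply(r, gl, mean)
  ns <- tapply(r, gl, length)
  pairs <- utils::combn(groups, 2L)
  npairs <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p = NA_real_)
  for (k in seq_len(npairs)) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt(sigma2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    out$z[k] <- (rbar[[g1]] - rbar[[g2]]) / se
    out$p[k] <- 2 * pnorm(-abs(out$z[k]))
  }
  out$p_bonferroni <- pmin(1, out$p * npairs)
  out$significant <- out$p_bonferroni < 0.05
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (Kruskal-Wallis + BH; Dunn + Bonferroni)\n")
  print(x$summary[, c("parameter", "statistic", "p", "p_adjusted",
                      "significant")], row.names = FALSE)
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    cat("Post-hoc (only parameters surviving BH):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores for a binary outcome.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels logical/0-1 outcomes.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrapped regularised-logistic-regression feature importance
#'
#' The PDR-vs-rest protocol: per bootstrap trial, a class-balanced resample
#' (with replacement within class), then for each regulariser (lasso,
#' mixing 1; ridge, 0; elastic-net, 0.5) a regularised logistic regression
#' along a lambda path with fivefold cross-validated AUC selecting
#' lambda_min (highest CV AUC) and lambda_1se (largest lambda within one
#' standard error of it).  Importance is the number of trials in which each
#' feature's coefficient is non-zero at each lambda rule; performance is
#' the mean CV AUC at lambda_min over trials with a normal-approximation
#' 95% CI.
#'
#' @param features numeric matrix or data.frame (rows = images).
#' @param labels binary vector (TRUE/1 = positive class, e.g. PDR).
#' @param n_trials bootstrap trials (default protocol: 500).
#' @param per_class resample size per class (default protocol: 40).
#' @param n_folds cross-validation folds (default protocol: 5).
#' @param regularisers subset of `c("lasso", "ridge", "elastic_net")`.
#' @param seed master RNG seed.
#' @return object of class `"importance_report"`: `counts` (data.frame:
#'   regulariser, lambda_rule, one column per feature), `auc` (data.frame:
#'   regulariser, mean_auc, ci_low, ci_high), `config`.
#' @export
bootstrap_feature_importance <- function(features, labels, n_trials = 500L,
                                         per_class = 40L, n_folds = 5L,
                                         regularisers = c("lasso", "ridge",
                                                          "elastic_net"),
                                         seed = 1L) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.logical(labels)
  if (length(y) != nrow(X)) stop("labels length must match feature rows")
  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("excluding degenerate single-valued feature(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 1L) stop("no usable features")
  pos <- which(y); neg <- which(!y)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("both classes need at least 2 members")
  regularisers <- match.arg(regularisers, several.ok = TRUE)
  mix <- c(lasso = 1, ridge = 0, elastic_net = 0.5)[regularisers]
  nf <- ncol(X)
  counts <- array(0L, dim = c(length(regularisers), 2L, nf),
                  dimnames = list(regularisers, c("lambda_min", "lambda_1se"),
                                  colnames(X)))
  aucs <- matrix(NA_real_, n_trials, length(regularisers),
                 dimnames = list(NULL, regularisers))
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      idx <- c(sample(neg, per_class, replace = TRUE),
               sample(pos, per_class, replace = TRUE))
      Xt <- X[idx, , drop = FALSE]
      yt <- y[idx]
      # stratified fold assignment so every fold sees both classes
      foldid <- integer(length(idx))
      foldid[!yt] <- sample(rep_len(seq_len(n_folds), per_class))
      foldid[yt] <- sample(rep_len(seq_len(n_folds), per_class))
      for (ri in seq_along(regularisers)) {
        cvfit <- cv_glmnet_auc(Xt, yt, alpha_mix = mix[ri], foldid = foldid)
        aucs[t, ri] <- cvfit$auc_min
        for (rule in c("lambda_min", "lambda_1se")) {
          s <- if (rule == "lambda_min") cvfit$lambda_min else cvfit$lambda_1se
          co <- as.numeric(coef(cvfit$fit, s = s, exact = FALSE))[-1]
          counts[ri, rule, ] <- counts[ri, rule, ] + (co != 0)
        }
      }
    }
  })
  count_df <- do.call(rbind, lapply(seq_along(regularisers), function(ri) {
    do.call(rbind, lapply(c("lambda_min", "lambda_1se"), function(rule) {
      row <- data.frame(regulariser = regularisers[ri], lambda_rule = rule)
      for (f in colnames(X)) row[[f]] <- counts[ri, rule, f]
      row
    }))
  }))
  auc_df <- do.call(rbind, lapply(seq_along(regularisers), function(ri) {
    m <- mean(aucs[, ri]); se <- sd(aucs[, ri]) / sqrt(n_trials)
    data.frame(regulariser = regularisers[ri], mean_auc = m,
               ci_low = m - qnorm(0.975) * se, ci_high = m + qnorm(0.975) * se)
  }))
  structure(list(counts = count_df, auc = auc_df,
                 config = list(n_trials = n_trials, per_class = per_class,
                               n_folds = n_folds, seed = seed,
                               regularisers = regularisers)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("Feature importance over %d bootstrap trials (%d/%d per class, %d-fold CV)\n",
              x$config$n_trials, x$config$per_class, x$config$per_class,
              x$config$n_folds))
  print(x$counts, row.names = FALSE)
  print(x$auc, row.names = FALSE)
  invisible(x)
}

# Cross-validated AUC over a regularised logistic path.  A lean
# reimplementation of the cv.glmnet(type.measure = "auc") protocol: the
# lambda path comes from the full-sample fit, each fold refits along that
# path (glmnet standardises internally per fit), performance is the
# per-fold-mean AUC, lambda_min maximises it and lambda_1se is the largest
# lambda within one standard error of the maximum.
cv_glmnet_auc <- function(X, y, alpha_mix, foldid) {
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha_mix,
                        standardize = TRUE)
  lam <- fit$lambda
  nf <- max(foldid)
  fold_auc <- matrix(NA_real_, nf, length(lam))
  pooled <- matrix(NA_real_, length(y), length(lam))
  for (k in seq_len(nf)) {
    tr <- foldid != k
    fk <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                         alpha = alpha_mix, lambda = lam, standardize = TRUE)
    pred <- stats::predict(fk, X[!tr, , drop = FALSE], s = lam)
    pooled[!tr, ] <- pred
    yv <- y[!tr]
    n1 <- sum(yv); n0 <- sum(!yv)
    r <- apply(pred, 2, rank)
    fold_auc[k, seq_len(ncol(pred))] <-
      (colSums(r[yv, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  # selection and reporting use the AUC of the pooled held-out
  # predictions (less path-selection optimism than the per-fold mean);
  # the 1-SE band comes from the fold-to-fold spread
  n1 <- sum(y); n0 <- sum(!y)
  rp <- apply(pooled, 2, rank)
  cvm <- (colSums(rp[y, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cvsd <- apply(fold_auc, 2, sd) / sqrt(nf)
  imin <- which.max(cvm)
  ok1se <- which(cvm >= cvm[imin] - cvsd[imin])
  list(fit = fit, lambda = lam, cvm = cvm, cvsd = cvsd,
       lambda_min = lam[imin], auc_min = cvm[imin],
       lambda_1se = lam[min(ok1se)])   # lambdas are decreasing: min index = largest
}

#' Dice similarity coefficient of two binary masks
#'
#' @param a,b masks or logical matrices of identical dimensions, not both
#'   empty.
#' @return 2|A n B| / (|A| + |B|) in [0, 1].
#' @export
dice <- function(a, b) {
  ga <- as_binary_grid(a); gb <- as_binary_grid(b)
  if (!identical(dim(ga), dim(gb))) stop("mask dimensions differ")
  sa <- sum(ga); sb <- sum(gb)
  if (sa + sb == 0L) stop("both masks are empty")
  2 * sum(ga & gb) / (sa + sb)
}

#' Relative error with a reference value
#'
#' |AV - MV| / |AV| with the manual (reference) value AV; vectorised.
#'
#' @param reference_value non-zero reference value(s).
#' @param measured_value measured value(s).
#' @return relative error fraction(s).
#' @export
relative_error <- function(reference_value, measured_value) {
  if (any(reference_value == 0)) stop("zero reference value")
  abs(reference_value - measured_value) / abs(reference_value)
}

#' Manual-vs-automatic agreement analysis
#'
#' For descriptor records paired by `image_id`: mean and max relative error
#' (manual as reference), a Pearson correlation test manual-vs-automatic
#' per parameter, two-group Wilcoxon rank-sum comparisons within the manual
#' and within the automatic measurements (when `group_labels` has two
#' levels), and per-image plus group-mean Dice coefficients when mask pairs
#' are supplied.
#'
#' @param manual,automatic data.frames (or record lists) with `image_id`
#'   and descriptor columns.
#' @param manual_masks,automatic_masks optional named lists of masks keyed
#'   by image_id.
#' @param group_labels optional named vector (by image_id) with two levels,
#'   e.g. healthy/DR.
#' @param parameters descriptor columns to compare; default the shared
#'   numeric columns.
#' @return object of class `"agreement_report"`: `parameters` data.frame
#'   (parameter, mean_relative_error, max_relative_error, pearson_r,
#'   pearson_p, wilcoxon_p_manual, wilcoxon_p_automatic), `dsc` data.frame
#'   per image, and `dsc_groups` (mean +- sd per group).
#' @export
agreement_analysis <- function(manual, automatic, manual_masks = NULL,
                               automatic_masks = NULL, group_labels = NULL,
                               parameters = NULL) {
  m <- if (is.data.frame(manual)) manual else records_to_frame(manual)
  a <- if (is.data.frame(automatic)) automatic else records_to_frame(automatic)
  unpaired <- c(setdiff(m$image_id, a$image_id), setdiff(a$image_id, m$image_id))
  if (length(unpaired))
    stop("unpaired image ids: ", paste(unique(unpaired), collapse = ", "))
  if (nrow(m) < 3L) stop("need at least 3 paired images")
  a <- a[match(m$image_id, a$image_id), , drop = FALSE]
  if (is.null(parameters)) {
    num <- intersect(names(m)[vapply(m, is.numeric, logical(1))],
                     names(a)[vapply(a, is.numeric, logical(1))])
    parameters <- num[vapply(num, function(p) !all(is.na(m[[p]])), logical(1))]
  }
  gl <- if (!is.null(group_labels)) group_labels[m$image_id]
  two_groups <- !is.null(gl) && length(unique(gl)) == 2L
  rows <- lapply(parameters, function(p) {
    re <- relative_error(m[[p]], a[[p]])
    ct <- suppressWarnings(cor.test(m[[p]], a[[p]], method = "pearson"))
    data.frame(
      parameter = p,
      mean_relative_error = mean(re),
      max_relative_error = max(re),
      pearson_r = unname(ct$estimate),
      pearson_p = ct$p.value,
      wilcoxon_p_manual = if (two_groups)
        suppressWarnings(wilcox.test(m[[p]] ~ gl)$p.value) else NA_real_,
      wilcoxon_p_automatic = if (two_groups)
        suppressWarnings(wilcox.test(a[[p]] ~ gl)$p.value) else NA_real_)
  })
  dsc <- NULL; dsc_groups <- NULL
  if (!is.null(manual_masks) && !is.null(automatic_masks)) {
    ids <- m$image_id
    d <- vapply(ids, function(id) dice(manual_masks[[id]],
                                       automatic_masks[[id]]), numeric(1))
    dsc <- data.frame(image_id = ids, dsc = unname(d))
    if (!is.null(gl)) {
      dsc_groups <- data.frame(
        group = names(tapply(d, gl, mean)),
        mean_dsc = as.numeric(tapply(d, gl, mean)),
        sd_dsc = as.numeric(tapply(d, gl, sd)))
    }
  }
  structure(list(parameters = do.call(rbind, rows), dsc = dsc,
                 dsc_groups = dsc_groups),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Manual vs automatic agreement\n")
  print(x$parameters, row.names = FALSE)
  if (!is.null(x$dsc_groups)) print(x$dsc_groups, row.names = FALSE)
  invisible(x)
}
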