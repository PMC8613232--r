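test_that("group comparison matches a hand-rank oracle on a small 3-group toy", {
  df <- data.frame(
    group_label = rep(c("a", "b", "c"), each = 4),
    v = c(1, 2, 3, 4, 10, 11, 12, 13, 20, 21, 22, 23))
  rep <- group_comparison(df, parameters = "v")
  # from-scratch Kruskal-Wallis (no ties)
  r <- rank(df$v); N <- 12
  H <- 12 / (N * (N + 1)) * sum(tapply(r, df$group_label, function(x)
    length(x) * mean(x)^2)) - 3 * (N + 1)
  expect_equal(rep$summary$statistic, H, tolerance = 1e-12)
  expect_equal(rep$summary$p, pchisq(H, 2, lower.tail = FALSE))
  # Dunn z for pair (a, c) from scratch
  sigma2 <- N * (N + 1) / 12
  z_ac <- (mean(r[df$group_label == "a"]) - mean(r[df$group_label == "c"])) /
    sqrt(sigma2 * (1 / 4 + 1 / 4))
  ph <- rep$posthoc
  got <- ph$z[ph$group1 == "a" & ph$group2 == "c"]
  expect_equal(got, z_ac, tolerance = 1e-12)
  expect_equal(ph$p_bonferroni, pmin(1, ph$p * 3))
})

test_that("identical groups give a null omnibus statistic", {
  df <- data.frame(group_label = rep(c("g1", "g2"), each = 6),
                   v = rep(c(3, 1, 4, 1, 5, 9), 2))
  rep <- group_comparison(df, parameters = "v")
  expect_equal(rep$summary$statistic, 0, tolerance = 1e-12)
  expect_equal(rep$summary$p, 1)
})

test_that("group comparison skips tiny groups with a warning, needs 2 groups", {
  df <- data.frame(group_label = c("a", "a", "b"), v = c(1, 2, 3))
  expect_warning(expect_error(group_comparison(df, parameters = "v"),
                              "no analysable"), "skipped")
  expect_error(group_comparison(data.frame(group_label = "a", v = 1)),
               "2 groups")
})

test_that("BH and Bonferroni corrections never decrease p-values (property)", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_true(all(p.adjust(p, "BH") >= p))
    expect_true(all(p.adjust(p, "bonferroni") >= p))
    expect_true(all(p.adjust(p, "BH") <= 1))
  }
})

test_that("dice: identity, disjoint, formula, symmetry, errors", {
  a <- matrix(FALSE, 5, 5); a[1:2, 1:2] <- TRUE          # |A| = 4
  b <- matrix(FALSE, 5, 5)
  b[cbind(c(1, 1, 2, 3, 3, 3), c(1, 2, 1, 1, 2, 3))] <- TRUE  # |B| = 6, overlap 3
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, b), 2 * 3 / (4 + 6))
  expect_equal(dice(a, b), dice(b, a))
  d <- matrix(FALSE, 5, 5); d[5, 5] <- TRUE
  expect_equal(dice(a, d), 0.0)
  expect_error(dice(a, matrix(TRUE, 4, 4)), "dimensions")
  expect_error(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "empty")
})

test_that("relative error: formula, vectorised loop oracle, zero guard", {
  expect_equal(relative_error(100, 90), 0.10)
  expect_equal(relative_error(5, 5), 0)
  set.seed(43)
  av <- runif(30, 1, 100); mv <- av + rnorm(30, 0, 10)
  re <- relative_error(av, mv)
  loopre <- vapply(1:30, function(i) abs(av[i] - mv[i]) / abs(av[i]),
                   numeric(1))
  expect_equal(re, loopre)
  expect_equal(mean(re), mean(loopre))
  expect_equal(max(re), max(loopre))
  expect_error(relative_error(c(1, 0), c(1, 1)), "zero")
})

test_that("agreement analysis: exact copy, affine offset, unpaired ids", {
  m <- data.frame(image_id = paste0("i", 1:6),
                  op_alpha_min = c(40, 45, 50, 42, 47, 52),
                  op_area = c(4, 5, 6, 4.5, 5.5, 6.5) * 1e5,
                  group_label = rep(c("healthy", "dr"), each = 3))
  a <- m
  rep <- agreement_analysis(m, a, group_labels = setNames(m$group_label, m$image_id),
                            parameters = c("op_alpha_min", "op_area"))
  expect_equal(rep$parameters$mean_relative_error, c(0, 0))
  expect_equal(rep$parameters$pearson_r, c(1, 1))
  a2 <- m
  a2$op_alpha_min <- m$op_alpha_min + 5
  rep2 <- agreement_analysis(m, a2, parameters = "op_alpha_min")
  expect_equal(rep2$parameters$pearson_r, 1)
  expect_equal(rep2$parameters$mean_relative_error, mean(5 / m$op_alpha_min))
  expect_equal(rep2$parameters$max_relative_error, max(5 / m$op_alpha_min))
  a3 <- a; a3$image_id[1] <- "zzz"
  expect_error(agreement_analysis(m, a3), "zzz")
})

test_that("agreement report matches an independently scripted recomputation", {
  set.seed(47)
  m <- data.frame(image_id = sprintf("h%02d", 1:8),
                  vs = runif(8, 8000, 12000),
                  group_label = rep(c("healthy", "dr"), 4))
  a <- m; a$vs <- m$vs * runif(8, 0.8, 1.2)
  masks_m <- masks_a <- list()
  for (id in m$image_id) {
    g <- matrix(runif(100) < 0.4, 10, 10)
    h <- g; flip <- sample(100, 10); h[flip] <- !h[flip]
    masks_m[[id]] <- g; masks_a[[id]] <- h
  }
  gl <- setNames(m$group_label, m$image_id)
  rep <- agreement_analysis(m, a, masks_m, masks_a, gl, parameters = "vs")
  expect_equal(rep$parameters$mean_relative_error,
               mean(abs(m$vs - a$vs) / m$vs))
  expect_equal(rep$parameters$pearson_p, cor.test(m$vs, a$vs)$p.value)
  expect_equal(rep$parameters$wilcoxon_p_manual,
               wilcox.test(m$vs[gl == "dr"], m$vs[gl == "healthy"])$p.value)
  d1 <- 2 * sum(masks_m[["h01"]] & masks_a[["h01"]]) /
    (sum(masks_m[["h01"]]) + sum(masks_a[["h01"]]))
  expect_equal(rep$dsc$dsc[1], d1)
  expect_equal(rep$dsc_groups$mean_dsc[rep$dsc_groups$group == "dr"],
               mean(rep$dsc$dsc[gl == "dr"]))
})

test_that("auc_score matches the Mann-Whitney construction", {
  set.seed(51)
  sc <- rnorm(40); lab <- sc + rnorm(40) > 0
  wins <- 0; n <- 0
  for (i in which(lab)) for (j in which(!lab)) {
    n <- n + 1
    wins <- wins + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  }
  expect_equal(auc_score(sc, lab), wins / n)
  expect_equal(auc_score(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
})

test_that("bootstrap importance is deterministic and recovers a planted signal", {
  set.seed(53)
  n <- 120
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(signal = ifelse(lab, 1, 0) + rnorm(n, 0, 0.8),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  r1 <- bootstrap_feature_importance(X, lab, n_trials = 25, per_class = 40,
                                     regularisers = "lasso", seed = 7)
  r2 <- bootstrap_feature_importance(X, lab, n_trials = 25, per_class = 40,
                                     regularisers = "lasso", seed = 7)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$auc, r2$auc)
  cmin <- r1$counts[r1$counts$lambda_rule == "lambda_min", -(1:2)]
  expect_equal(names(cmin)[which.max(unlist(cmin))], "signal")
  expect_gt(r1$auc$mean_auc, 0.6)
  expect_true(all(unlist(r1$counts[, -(1:2)]) <= 25))
  expect_lt(r1$auc$ci_low, r1$auc$mean_auc)
  # degenerate feature exclusion
  expect_warning(
    bootstrap_feature_importance(cbind(X, const = 1), lab, n_trials = 2,
                                 per_class = 20, regularisers = "lasso",
                                 seed = 1), "degenerate")
  # regulariser name -> mixing parameter contract (lasso 1, ridge 0, en 0.5):
  # ridge keeps every coefficient non-zero, lasso does not
  rr <- bootstrap_feature_importance(X, lab, n_trials = 5, per_class = 30,
                                     regularisers = "ridge", seed = 3)
  expect_true(all(unlist(rr$counts[rr$counts$lambda_rule == "lambda_min",
                                   -(1:2)]) == 5))
})
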