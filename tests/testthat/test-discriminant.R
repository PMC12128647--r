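# Fertility grouping, group tests, stepwise selection, LDA and
# cross-validation.

test_that("the one-SD fertility threshold uses the population SD", {
  # rates constructed with population mean 89.0 and population SD 6.6
  rec <- data.frame(ram_id = paste0("r", 1:4),
                    conception_rate = c(82.4, 95.6, 82.4, 95.6))
  res <- threshold_groups(rec)
  expect_equal(res$mean, 89.0)
  expect_equal(res$sd, 6.6)
  expect_equal(res$cutoff, 82.4)
  # a ram exactly at the cutoff is AF (>= cutoff rule)
  expect_equal(res$records$group, c("AF", "AF", "AF", "AF"))
  rec$conception_rate[1] <- 60
  res2 <- threshold_groups(rec)
  expect_equal(res2$records$group[1], "LF")

  expect_error(threshold_groups(data.frame(conception_rate = rep(90, 5))),
               "zero variance")
  expect_error(threshold_groups(data.frame(conception_rate = c(1, 2))),
               "at least 3")
  expect_error(threshold_groups(data.frame(conception_rate = c(50, 80, 101))),
               "0, 100")
})

test_that("group t-tests match the pooled-variance closed form", {
  idb <- group_ttest(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(idb$t, 0)
  expect_equal(idb$p, 1)

  sep <- group_ttest(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_lt(sep$p, 0.01)

  x <- c(2, 4, 6); y <- c(1, 3, 5)
  tt <- group_ttest(c(x, y), rep(c("x", "y"), each = 3))
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(abs(tt$t), abs(t_hand), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$summary$sem[tt$summary$group == "x"], sd(x) / sqrt(3))
})

test_that("stepwise selection finds a strong variable among pure noise", {
  n <- 56; grp <- rep(c("AF", "LF"), c(47, 9))
  hits <- 0; nseeds <- 100
  for (s in seq_len(nseeds)) {
    set.seed(s)
    X <- as.data.frame(matrix(rnorm(n * 38), n, 38))
    names(X) <- paste0("f", 1:38)
    X$f1 <- X$f1 + ifelse(grp == "AF", 0, 3)   # 3-SD separated feature
    sel <- stepwise_select(X, grp)
    if (length(sel$selected) && sel$selected[1] == "f1" &&
        sel$trace$round[1] == 1) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / nseeds, 0.95)
})

test_that("the entry level governs admission on pure noise", {
  n <- 56; grp <- rep(c("AF", "LF"), c(47, 9))
  counts_015 <- counts_001 <- numeric(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    X <- as.data.frame(matrix(rnorm(n * 38), n, 38))
    sel15 <- stepwise_select(X, grp, entry_p = 0.15, stay_p = 0.15)
    sel01 <- stepwise_select(X, grp, entry_p = 0.01, stay_p = 0.01)
    counts_015[s] <- length(sel15$selected)
    counts_001[s] <- length(sel01$selected)
    # every admission respected the entry criterion
    ent <- sel15$trace[sel15$trace$action == "enter", ]
    expect_true(all(ent$p < 0.15))
  }
  # greedy best-of-38 admission at a 0.15 level is permissive by design;
  # a strict level keeps the noise model small
  expect_lt(stats::median(counts_001), stats::median(counts_015))
  expect_lte(stats::median(counts_001), 2)
})

test_that("collinear duplicates are never co-selected", {
  set.seed(2)
  n <- 40; grp <- rep(c("AF", "LF"), c(30, 10))
  X <- data.frame(sig = rnorm(n) + ifelse(grp == "AF", 0, 2.5),
                  noise = rnorm(n))
  X$dup <- X$sig
  sel <- stepwise_select(X, grp)$selected
  expect_false(all(c("sig", "dup") %in% sel))
  expect_true(any(c("sig", "dup") %in% sel))
})

test_that("the discriminant direction matches the closed-form Fisher solution", {
  set.seed(3)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4) %*% matrix(c(1, .3, 0, 0,
                                               .3, 1, .2, 0,
                                               0, .2, 1, .1,
                                               0, 0, .1, 1), 4, 4)
  colnames(X) <- paste0("v", 1:4)
  y <- rep(c("AF", "LF"), c(35, 15))
  X[y == "LF", 1] <- X[y == "LF", 1] + 2
  fit <- fit_lda(X, y)
  mu <- fit$means
  oracle <- solve(fit$pooled_cov, mu[1, ] - mu[2, ])
  expect_lt(max(abs(fit$fisher / sqrt(sum(fit$fisher^2)) -
                      oracle / sqrt(sum(oracle^2)))), 1e-9)
  # the per-group LDF difference is the same direction
  d <- fit$coef[1, ] - fit$coef[2, ]
  expect_lt(max(abs(d - oracle)), 1e-9)
})

test_that("degenerate and separable cases behave as expected", {
  set.seed(4)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- rep(c("AF", "LF"), each = 20)
  fit <- fit_lda(X, y)
  expect_lt(fit$canonical_correlation, 0.35)
  expect_gt(fit$p_value, 0.2)

  X2 <- X; X2$a <- X2$a + ifelse(y == "AF", 0, 30)
  fit2 <- fit_lda(X2, y)
  pred <- predict(fit2, X2)
  expect_equal(mean(pred$class == y), 1)
  expect_gt(fit2$canonical_correlation, 0.95)
  expect_true(fit2$canonical_correlation <= 1)

  Xs <- data.frame(a = X$a, b = X$a)   # singular pooled covariance
  expect_error(fit_lda(Xs, y), "singular")
})

test_that("model predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(6)
  X <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- rep(c("AF", "LF"), c(40, 20))
  X$a <- X$a + ifelse(y == "AF", 0, 1.4)
  fit <- fit_lda(X, y)
  m <- MASS::lda(X, grouping = y, prior = c(0.5, 0.5))
  pm <- predict(m, X)
  po <- predict(fit, X)
  expect_equal(po$class, as.character(pm$class))
  expect_equal(po$AF, unname(pm$posterior[, "AF"]), tolerance = 1e-9)
})

test_that("leave-one-out cross-validation is exact on separable data and order-invariant", {
  set.seed(7)
  X <- data.frame(a = c(rnorm(30), rnorm(10) + 20), b = rnorm(40))
  y <- rep(c("AF", "LF"), c(30, 10))
  cv <- loo_crossvalidate(X, y)
  expect_equal(cv$overall_error_pct, 0)
  expect_equal(nrow(cv$predictions), 40)

  ord <- sample(40)
  cv2 <- loo_crossvalidate(X[ord, ], y[ord])
  expect_equal(cv2$counts, cv$counts)
})

test_that("swapping group labels swaps sensitivity and specificity under equal priors", {
  set.seed(8)
  X <- data.frame(a = rnorm(24) + rep(c(0, 1.2), each = 12), b = rnorm(24))
  y <- rep(c("AF", "LF"), each = 12)
  cv <- loo_crossvalidate(X, y)
  yswap <- ifelse(y == "AF", "LF", "AF")
  cv2 <- loo_crossvalidate(X, yswap)
  expect_equal(cv$sensitivity_pct, cv2$specificity_pct)
  expect_equal(cv$specificity_pct, cv2$sensitivity_pct)
})

test_that("confusion metrics are pure functions of the counts", {
  cm <- confusion_metrics(30, 40, 5, 10)
  expect_equal(cm$sensitivity_pct, 75)
  expect_equal(cm$specificity_pct, 50)
  expect_equal(cm$overall_error_pct, 100 * 15 / 50)
  expect_equal(sum(cm$counts), 50)
  expect_error(confusion_metrics(11, 10, 1, 2))
})

test_that("reports round-trip through JSON and recompute their error rate", {
  set.seed(9)
  X <- data.frame(a = rnorm(30) + rep(c(0, 2), c(20, 10)), b = rnorm(30))
  y <- rep(c("AF", "LF"), c(20, 10))
  fit <- fit_lda(X, y)
  cv <- loo_crossvalidate(X, y)
  td <- withr::local_tempdir()
  rep <- fertility_report(fit, cv, out_dir = td)
  back <- jsonlite::read_json(file.path(td, "results.json"),
                              simplifyVector = TRUE)
  expect_equal(back$cross_validation$sensitivity_pct, cv$sensitivity_pct)
  expect_equal(back$model$canonical_correlation,
               fit$canonical_correlation, tolerance = 1e-12)
  cts <- back$cross_validation$counts
  expect_equal(back$cross_validation$overall_error_pct,
               100 * (cts$af_wrong + cts$lf_wrong) / sum(unlist(cts)))
  # null model report
  repn <- fertility_report(NULL, confusion_metrics(20, 20, 0, 10),
                           out_dir = td)
  expect_true(repn$json$model$null_model)
  md <- readLines(file.path(td, "report.md"))
  expect_true(any(grepl("null model|majority", md)))
})
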