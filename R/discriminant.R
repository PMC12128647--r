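# Fertility classification: threshold-based group assignment, group
# comparisons, stepwise discriminant variable selection by partial Wilks'
# lambda F-tests, two-group linear discriminant functions with canonical
# correlation, and leave-one-out cross-validation.

#' Assign fertility groups by the one-SD-below-mean rule
#'
#' Rams whose conception rate falls below `mean - 1 SD` of the population
#' are labeled low fertility (LF); the rest adequate fertility (AF). The SD
#' is the population SD (divisor `n`), matching the published arithmetic
#' `89.0 - 6.6 = 82.4`. A ram exactly at the cutoff is AF.
#'
#' @param records Data frame with `ram_id` and `conception_rate` (percent,
#'   0-100), at least 3 rows.
#' @return List with `records` (input plus a `group` column) and `cutoff`.
#' @export
threshold_groups <- function(records) {
  stopifnot(is.data.frame(records), !is.null(records$conception_rate))
  rate <- records$conception_rate
  if (length(rate) < 3) stop("threshold_groups: need at least 3 records")
  if (any(rate < 0 | rate > 100)) {
    stop("threshold_groups: conception rates must be in [0, 100]")
  }
  m <- mean(rate)
  s <- sqrt(mean((rate - m)^2))           # population SD
  if (s == 0) stop("threshold_groups: zero variance in conception rates")
  cutoff <- m - s
  records$group <- ifelse(rate < cutoff, "LF", "AF")
  list(records = records, cutoff = cutoff, mean = m, sd = s)
}

#' Two-group t-test with formatted group summaries
#'
#' Independent-sample Student's t-test (pooled variance) by default; Welch's
#' variant by flag.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of two levels aligned with
#'   `values`.
#' @param welch Use Welch's unequal-variance t-test.
#' @return List: `t`, `df`, `p`, and a data frame `summary` with group n,
#'   mean and SEM.
#' @export
group_ttest <- function(values, groups, welch = FALSE) {
  groups <- as.factor(groups)
  stopifnot(nlevels(droplevels(groups)) == 2)
  sizes <- table(droplevels(groups))
  if (any(sizes < 2)) stop("group_ttest: need at least 2 values per group")
  tt <- stats::t.test(values ~ groups, var.equal = !welch)
  sm <- do.call(rbind, lapply(split(values, droplevels(groups)), function(v)
    data.frame(n = length(v), mean = mean(v), sem = sem(v))))
  sm$group <- rownames(sm)
  rownames(sm) <- NULL
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, summary = sm[c("group", "n", "mean", "sem")])
}

# Wilks' lambda det(W)/det(T) for the given feature columns (two groups).
wilks_lambda <- function(X, y, cols) {
  Xs <- as.matrix(X[, cols, drop = FALSE])
  Tm <- crossprod(scale(Xs, center = TRUE, scale = FALSE))
  Wm <- matrix(0, ncol(Xs), ncol(Xs))
  for (g in unique(y)) {
    Xg <- Xs[y == g, , drop = FALSE]
    Wm <- Wm + crossprod(scale(Xg, center = TRUE, scale = FALSE))
  }
  dT <- determinant(Tm, logarithm = TRUE)
  dW <- determinant(Wm, logarithm = TRUE)
  if (!is.finite(dT$modulus) || !is.finite(dW$modulus)) return(NA_real_)
  exp(as.numeric(dW$modulus - dT$modulus))
}

#' Stepwise discriminant variable selection (Wilks' lambda)
#'
#' Forward selection with backward elimination for a two-group discriminant
#' model, using partial Wilks' lambda F-tests: at each round the candidate
#' with the largest F-to-enter joins if its p-value is below `entry_p`, then
#' included variables whose F-to-remove p-value exceeds `stay_p` are
#' dropped. Near-collinear candidates (squared multiple correlation with
#' the selected set above `1 - tol`) are skipped.
#'
#' @param X Data frame or matrix of candidate features (rows = rams).
#' @param y Group labels (two levels).
#' @param entry_p,stay_p Significance thresholds (defaults 0.15, the SAS
#'   STEPDISC defaults).
#' @param max_rounds Maximum selection rounds.
#' @param tol Collinearity tolerance (default 1e-4).
#' @return List: `selected` (character vector, possibly empty) and `trace`
#'   (data frame: round, action, variable, F, p, lambda).
#' @export
stepwise_select <- function(X, y, entry_p = 0.15, stay_p = 0.15,
                            max_rounds = 20, tol = 1e-4) {
  stopifnot(entry_p > 0, entry_p < 1, stay_p > 0, stay_p < 1)
  X <- as.data.frame(X)
  feats <- names(X)
  y <- as.factor(y)
  stopifnot(nlevels(droplevels(y)) == 2)
  n <- nrow(X)
  g <- 2L
  # standardize internally; selection is scale-invariant but conditioning
  # benefits
  Xs <- as.data.frame(scale(X))
  keep <- vapply(Xs, function(v) all(is.finite(v)), logical(1))
  Xs <- Xs[keep]
  feats <- names(Xs)
  selected <- character(0)
  trace <- list()
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    # forward step
    lam_S <- if (length(selected)) wilks_lambda(Xs, y, selected) else 1
    cand <- setdiff(feats, selected)
    best <- NULL
    for (v in cand) {
      if (length(selected)) {
        r2 <- suppressWarnings(
          summary(stats::lm(Xs[[v]] ~ ., data = Xs[selected]))$r.squared)
        if (!is.finite(r2) || r2 > 1 - tol) next
      }
      lam_Sv <- wilks_lambda(Xs, y, c(selected, v))
      if (!is.finite(lam_Sv) || lam_Sv <= 0) next
      lam_p <- lam_Sv / lam_S
      df2 <- n - g - length(selected)
      if (df2 < 5) next   # keep residual df for a stable pooled covariance
      Fv <- df2 / (g - 1) * (1 - lam_p) / lam_p
      pv <- stats::pf(Fv, g - 1, df2, lower.tail = FALSE)
      if (is.null(best) || Fv > best$F) {
        best <- list(var = v, F = Fv, p = pv, lambda = lam_Sv)
      }
    }
    if (!is.null(best) && best$p < entry_p) {
      selected <- c(selected, best$var)
      trace[[length(trace) + 1L]] <- data.frame(
        round = round, action = "enter", variable = best$var,
        F = best$F, p = best$p, lambda = best$lambda)
      changed <- TRUE
    }
    # backward step
    if (length(selected) > 1) {
      lam_S <- wilks_lambda(Xs, y, selected)
      worst <- NULL
      for (v in selected) {
        rest <- setdiff(selected, v)
        lam_rest <- if (length(rest)) wilks_lambda(Xs, y, rest) else 1
        lam_p <- lam_S / lam_rest
        df2 <- n - g - (length(selected) - 1L)
        Fv <- df2 / (g - 1) * (1 - lam_p) / lam_p
        pv <- stats::pf(Fv, g - 1, df2, lower.tail = FALSE)
        if (is.null(worst) || pv > worst$p) {
          worst <- list(var = v, F = Fv, p = pv, lambda = lam_rest)
        }
      }
      if (!is.null(worst) && worst$p > stay_p) {
        selected <- setdiff(selected, worst$var)
        trace[[length(trace) + 1L]] <- data.frame(
          round = round, action = "remove", variable = worst$var,
          F = worst$F, p = worst$p, lambda = worst$lambda)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(round = integer(0), action = character(0),
               variable = character(0), F = numeric(0), p = numeric(0),
               lambda = numeric(0))
  list(selected = selected, trace = trace)
}

#' Fit a two-group linear discriminant model
#'
#' Linear discriminant (classification) functions from the pooled
#' within-group covariance, with the canonical correlation of the single
#' canonical variate and the Wilks'-lambda F-test of the model.
#'
#' @param X Data frame or matrix of the selected features (rows = rams).
#' @param y Group labels, two levels; the first level sorted alphabetically
#'   is used as the reference ("AF" before "LF").
#' @param priors Named prior probabilities (default equal).
#' @return Object of class `fertility_lda`: group means, pooled covariance
#'   and its inverse, per-group linear discriminant coefficients and
#'   constants, the Fisher discriminant direction, `canonical_correlation`
#'   (and square), Wilks' lambda with F and p, priors, feature names.
#' @export
fit_lda <- function(X, y, priors = NULL) {
  X <- as.matrix(as.data.frame(X))
  y <- as.factor(y)
  lev <- levels(droplevels(y))
  stopifnot(length(lev) == 2)
  if (is.null(priors)) priors <- stats::setNames(c(0.5, 0.5), lev)
  priors <- priors[lev] / sum(priors[lev])
  n <- nrow(X); p <- ncol(X)
  if (min(table(y)) < 2) stop("fit_lda: need at least 2 rams per group")
  means <- t(vapply(lev, function(g) colMeans(X[y == g, , drop = FALSE]),
                    numeric(p)))
  Wm <- matrix(0, p, p)
  for (g in lev) {
    Xg <- X[y == g, , drop = FALSE]
    Wm <- Wm + crossprod(scale(Xg, center = TRUE, scale = FALSE))
  }
  Sp <- Wm / (n - 2)
  # solve on the correlation scale: features mix units (um^2 variances vs
  # gray levels), and the raw covariance can be numerically singular
  s <- sqrt(diag(Sp))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("fit_lda: singular pooled covariance; reduce the feature set")
  }
  Spc <- Sp / tcrossprod(s)
  Spi <- tryCatch(solve(Spc) / tcrossprod(s), error = function(e)
    stop("fit_lda: singular pooled covariance; reduce the feature set"))
  coef_g <- means %*% Spi                     # per-group LDF coefficients
  const_g <- -0.5 * rowSums(coef_g * means) + log(priors)
  fisher <- drop(Spi %*% (means[1, ] - means[2, ]))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  lam <- wilks_lambda(as.data.frame(X), y, colnames(X))
  canc <- sqrt(max(0, min(1, 1 - lam)))
  df2 <- n - p - 1
  Fstat <- if (df2 > 0) df2 / p * (1 - lam) / lam else NA_real_
  pval <- if (df2 > 0) {
    stats::pf(Fstat, p, df2, lower.tail = FALSE)
  } else NA_real_
  structure(list(features = colnames(X), levels = lev, priors = priors,
                 means = means, pooled_cov = Sp, pooled_cov_inv = Spi,
                 coef = coef_g, const = const_g, fisher = fisher,
                 wilks_lambda = lam, canonical_correlation = canc,
                 canonical_correlation_sq = canc^2,
                 F = Fstat, df = c(p, df2), p_value = pval, n = n),
            class = "fertility_lda")
}

#' @export
print.fertility_lda <- function(x, ...) {
  cat("Two-group linear discriminant model\n")
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  Wilks' lambda %.4f | canonical correlation %.3f (r^2 %.3f)\n",
              x$wilks_lambda, x$canonical_correlation,
              x$canonical_correlation_sq))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$df[1], x$df[2], x$F,
              x$p_value))
  invisible(x)
}

#' Classify rams with a fitted discriminant model
#'
#' @param object A [fit_lda()] model.
#' @param newdata Data frame or matrix with the model's feature columns.
#' @param ... Unused.
#' @return Data frame: `class`, posterior probability columns per group.
#'   Posterior ties go to the first (majority, AF) level.
#' @export
predict.fertility_lda <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  scores <- X %*% t(object$coef) + matrix(object$const, nrow(X), 2,
                                          byrow = TRUE)
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- object$levels
  cls <- object$levels[ifelse(post[, 1] >= post[, 2], 1L, 2L)]
  data.frame(class = cls, post, stringsAsFactors = FALSE)
}

#' Confusion metrics from cross-validation counts
#'
#' Pure arithmetic on the confusion counts of the two fertility groups:
#' sensitivity is the percentage of AF rams identified correctly,
#' specificity the percentage of LF rams identified correctly, and the
#' overall error rate is (false positives + false negatives) / total.
#'
#' @param af_correct,af_total Correctly classified and total AF rams.
#' @param lf_correct,lf_total Correctly classified and total LF rams.
#' @return List of class `cv_report`: confusion counts, `sensitivity_pct`,
#'   `specificity_pct`, `overall_error_pct` (raw) and
#'   `overall_error_pct_rounded` (integer percent).
#' @examples
#' confusion_metrics(39, 47, 6, 9)  # 83.0 / 66.7 / 19.6 (prints as 20)
#' @export
confusion_metrics <- function(af_correct, af_total, lf_correct, lf_total) {
  stopifnot(af_correct <= af_total, lf_correct <= lf_total,
            af_total > 0, lf_total > 0)
  n <- af_total + lf_total
  wrong <- (af_total - af_correct) + (lf_total - lf_correct)
  structure(list(
    counts = c(af_correct = af_correct, af_wrong = af_total - af_correct,
               lf_correct = lf_correct, lf_wrong = lf_total - lf_correct),
    n = n,
    sensitivity_pct = round(100 * af_correct / af_total, 1),
    specificity_pct = round(100 * lf_correct / lf_total, 1),
    overall_error_pct = 100 * wrong / n,
    overall_error_pct_rounded = round(100 * wrong / n)
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation confusion summary\n")
  cat(sprintf("  AF: %d/%d correct (sensitivity %.1f%%)\n",
              x$counts["af_correct"],
              x$counts["af_correct"] + x$counts["af_wrong"],
              x$sensitivity_pct))
  cat(sprintf("  LF: %d/%d correct (specificity %.1f%%)\n",
              x$counts["lf_correct"],
              x$counts["lf_correct"] + x$counts["lf_wrong"],
              x$specificity_pct))
  cat(sprintf("  overall error %.1f%% (%d%%)\n", x$overall_error_pct,
              x$overall_error_pct_rounded))
  invisible(x)
}

#' Leave-one-out cross-validation of the discriminant model
#'
#' Refits the model n times, each time excluding one ram and predicting it,
#' and reports the confusion counts and derived rates. Folds with a
#' singular pooled covariance are flagged and predicted by the larger
#' prior.
#'
#' @param X Data frame or matrix of features (rows = rams).
#' @param y Group labels ("AF"/"LF").
#' @param priors Named priors (default equal).
#' @return A `cv_report` (see [confusion_metrics()]) with an extra
#'   `predictions` data frame and `singular_folds` count.
#' @export
loo_crossvalidate <- function(X, y, priors = NULL) {
  X <- as.data.frame(X)
  y <- as.character(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  pred <- character(n)
  singular <- 0L
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_lda(X[-i, , drop = FALSE], y[-i], priors = priors),
                    error = function(e) NULL)
    if (is.null(fit)) {
      singular <- singular + 1L
      pred[i] <- names(which.max(table(y[-i])))
    } else {
      pred[i] <- predict(fit, X[i, , drop = FALSE])$class
    }
  }
  rep <- confusion_metrics(sum(pred == "AF" & y == "AF"), sum(y == "AF"),
                           sum(pred == "LF" & y == "LF"), sum(y == "LF"))
  rep$predictions <- data.frame(observed = y, predicted = pred,
                                stringsAsFactors = FALSE)
  rep$singular_folds <- singular
  rep
}

#' Assemble a machine- and human-readable classification report
#'
#' @param model A [fit_lda()] model, or `NULL` for a null (empty-selection)
#'   model.
#' @param cv A `cv_report`, or `NULL`.
#' @param summaries Optional named list of data frames echoed into the
#'   report (e.g. group summary tables).
#' @param out_dir Optional directory; when given, writes `results.json` and
#'   `report.md` there.
#' @return List with `json` (the report list) and the file paths written
#'   (or `NULL`).
#' @export
fertility_report <- function(model = NULL, cv = NULL, summaries = NULL,
                             out_dir = NULL) {
  rep <- list(
    model = if (is.null(model)) {
      list(null_model = TRUE,
           note = "empty feature selection; majority-class baseline")
    } else {
      list(null_model = FALSE, features = model$features,
           priors = as.list(model$priors),
           coefficients = apply(model$coef, 1, as.list),
           constants = as.list(stats::setNames(model$const, model$levels)),
           wilks_lambda = model$wilks_lambda,
           canonical_correlation = model$canonical_correlation,
           canonical_correlation_sq = model$canonical_correlation_sq,
           F = model$F, df = model$df, p_value = model$p_value)
    },
    cross_validation = if (is.null(cv)) NULL else list(
      counts = as.list(cv$counts),
      sensitivity_pct = cv$sensitivity_pct,
      specificity_pct = cv$specificity_pct,
      overall_error_pct = cv$overall_error_pct,
      overall_error_pct_rounded = cv$overall_error_pct_rounded),
    summaries = summaries)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json_path <- file.path(out_dir, "results.json")
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    md_path <- file.path(out_dir, "report.md")
    writeLines(report_markdown(rep), md_path)
    paths <- c(json = json_path, markdown = md_path)
  }
  list(json = rep, paths = paths)
}

report_markdown <- function(rep) {
  lines <- c("# Sperm nuclear shape fertility classification", "")
  if (isTRUE(rep$model$null_model)) {
    lines <- c(lines, "No variables met the entry criterion: null model;",
               "cross-validation falls back to the majority class.", "")
  } else {
    lines <- c(lines, "## Model",
               paste("Variables:", paste(rep$model$features,
                                         collapse = ", ")),
               sprintf("Canonical correlation: %.3f (r^2 = %.3f)",
                       rep$model$canonical_correlation,
                       rep$model$canonical_correlation_sq),
               sprintf("Wilks' lambda %.4f, F(%d, %d) = %.3f, p = %.4g",
                       rep$model$wilks_lambda, rep$model$df[1],
                       rep$model$df[2], rep$model$F, rep$model$p_value),
               "")
  }
  if (!is.null(rep$cross_validation)) {
    cv <- rep$cross_validation
    lines <- c(lines, "## Cross-validation (leave-one-out)",
               sprintf("- AF correct: %d/%d (sensitivity %.1f%%)",
                       cv$counts$af_correct,
                       cv$counts$af_correct + cv$counts$af_wrong,
                       cv$sensitivity_pct),
               sprintf("- LF correct: %d/%d (specificity %.1f%%)",
                       cv$counts$lf_correct,
                       cv$counts$lf_correct + cv$counts$lf_wrong,
                       cv$specificity_pct),
               sprintf("- overall error: %.1f%% (%d%%)",
                       cv$overall_error_pct, cv$overall_error_pct_rounded),
               "")
  }
  lines
}
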