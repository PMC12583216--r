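# Agreement and accuracy statistics: regression error metrics, bootstrap
# confidence intervals, ICC(2,1), weighted kappa and severity-stratified
# classification metrics.

#' Paired reference/predicted score table
#'
#' @param reference Integer manual-standard totals in `[0, 24]`.
#' @param predicted Continuous or integer predicted totals.
#' @param ids Optional case identifiers.
#' @return Object of class `paired_scores`.
#' @export
paired_scores <- function(reference, predicted, ids = NULL) {
  if (length(reference) != length(predicted) || length(reference) < 2) {
    stop("reference and predicted must have equal length >= 2",
         call. = FALSE)
  }
  if (anyNA(reference) || any(reference != as.integer(reference)) ||
      any(reference < 0 | reference > 24)) {
    stop("reference scores must be integers in [0, 24]", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_along(reference))
  structure(list(reference = as.integer(reference),
                 predicted = as.numeric(predicted),
                 ids = as.character(ids)),
            class = "paired_scores")
}

#' Regression accuracy metrics
#'
#' MAE, MSE, Spearman rank correlation (average ranks for ties) and
#' R-squared against the reference mean. With a zero-variance reference,
#' Spearman and R-squared are returned as `NA` (flagged, not fabricated).
#'
#' @param p A [paired_scores()].
#' @return List of class `metrics_report` with `mae`, `mse`,
#'   `spearman_rho`, `r2` and `n`.
#' @export
regression_metrics <- function(p) {
  stopifnot(inherits(p, "paired_scores"))
  err <- p$predicted - p$reference
  mae <- mean(abs(err))
  mse <- mean(err^2)
  if (stats::var(p$reference) == 0) {
    rho <- NA_real_
    r2 <- NA_real_
  } else {
    rho <- stats::cor(p$reference, p$predicted, method = "spearman")
    r2 <- 1 - sum(err^2) / sum((p$reference - mean(p$reference))^2)
  }
  structure(list(mae = mae, mse = mse, spearman_rho = rho, r2 = r2,
                 n = length(err)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  MAE %.3f  MSE %.3f  Spearman rho %.3f  R2 %.3f\n",
              x$n, x$mae, x$mse, x$spearman_rho, x$r2))
  invisible(x)
}

#' Proportion of clinically acceptable predictions
#'
#' Fraction of cases with absolute error strictly below the threshold
#' (default 4 points).
#'
#' @param p A [paired_scores()].
#' @param threshold Acceptability threshold.
#' @return Numeric in `[0, 1]`.
#' @export
acceptable_proportion <- function(p, threshold = 4) {
  stopifnot(inherits(p, "paired_scores"))
  mean(abs(p$predicted - p$reference) < threshold)
}

#' Percentile bootstrap confidence intervals
#'
#' Reruns a metric-producing experiment `B` times and returns the
#' empirical 2.5th/97.5th percentile interval per metric. In
#' `mode = "resample"` the experiment receives a bootstrap resample of the
#' supplied [paired_scores()]; `mode = "retrain"` passes a resampled index
#' vector so the caller can resample its training set with replacement,
#' retrain, and evaluate on the fixed test set. Replicates that error are
#' recorded; the run aborts if more than 1% fail.
#'
#' @param experiment For `"resample"`: `function(p)` returning a named
#'   numeric vector of metrics, called on resampled pairs of `data`. For
#'   `"retrain"`: `function(idx)` where `idx` indexes the training set.
#' @param data A [paired_scores()] (resample mode) or the training-set
#'   size (retrain mode).
#' @param B Number of bootstrap replicates (>= 2; 1000 to match the
#'   reference procedure).
#' @param mode `"resample"` or `"retrain"`.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List of class `bootstrap_ci`: per-metric `(lower, upper)`
#'   matrix, the replicate matrix, and the failure count.
#' @export
bootstrap_ci <- function(experiment, data, B = 1000L,
                         mode = c("resample", "retrain"), level = 0.95,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  set.seed(seed)
  reps <- vector("list", B)
  failures <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      if (mode == "resample") {
        stopifnot(inherits(data, "paired_scores"))
        idx <- sample.int(length(data$reference), replace = TRUE)
        experiment(paired_scores(data$reference[idx], data$predicted[idx],
                                 data$ids[idx]))
      } else {
        n_train <- as.integer(data)
        experiment(sample.int(n_train, replace = TRUE))
      }
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else reps[[b]] <- res
    if (failures > max(1L, ceiling(0.01 * B))) {
      stop(sprintf("bootstrap aborted: %d replicates failed", failures),
           call. = FALSE)
    }
  }
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  a <- (1 - level) / 2
  # replicates whose metric was undefined (e.g. a zero-variance resample)
  # are dropped per metric; an all-undefined metric yields an NA interval
  ci <- apply(mat, 2, function(col) {
    if (all(is.na(col))) c(NA_real_, NA_real_) else
      stats::quantile(col, probs = c(a, 1 - a), names = FALSE, type = 7,
                      na.rm = TRUE)
  })
  rownames(ci) <- c("lower", "upper")
  structure(list(ci = ci, replicates = mat, failures = failures,
                 B = B, mode = mode, level = level),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("bootstrap (%s mode, B = %d, %.0f%% CI):\n", x$mode, x$B,
              100 * x$level))
  print(round(x$ci, 4))
  invisible(x)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation, computed from the ANOVA mean squares of the subjects x
#' raters table:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`.
#'
#' @param ratings Numeric matrix, `n` subjects x `k` raters, complete.
#' @return Numeric scalar.
#' @export
icc_2_1 <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters",
                           call. = FALSE)
  if (anyNA(x)) stop("ratings must be complete (no NA)", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  (ms_rows - ms_err) /
    (ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err))
}

#' Weighted kappa for ordinal agreement
#'
#' `1 - sum(w O) / sum(w E)` with disagreement weights
#' `w_ij = |i - j| / (R - 1)` (linear) or `((i - j)/(R - 1))^2`
#' (quadratic), observed cell proportions `O` and chance-expected
#' proportions `E` from the marginals. The category range is taken as the
#' union of both raters' values unless `categories` is supplied.
#'
#' @param a,b Equal-length integer rating vectors.
#' @param scheme `"quadratic"` (default) or `"linear"`.
#' @param categories Optional full ordinal category vector.
#' @return Numeric scalar; `NA` (with a warning) when both raters use a
#'   single identical category.
#' @export
weighted_kappa <- function(a, b, scheme = c("quadratic", "linear"),
                           categories = NULL) {
  scheme <- match.arg(scheme)
  if (length(a) != length(b) || !length(a)) {
    stop("a and b must be non-empty and of equal length", call. = FALSE)
  }
  if (is.null(categories)) categories <- sort(unique(c(a, b)))
  R <- length(categories)
  if (R < 2) {
    warning("only one category present; kappa undefined")
    return(NA_real_)
  }
  ai <- match(a, categories)
  bi <- match(b, categories)
  O <- table(factor(ai, 1:R), factor(bi, 1:R)) / length(a)
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(1:R, 1:R, "-")) / (R - 1)
  w <- if (scheme == "linear") d else d^2
  denom <- sum(w * E)
  if (denom == 0) {
    warning("no chance disagreement; kappa undefined")
    return(NA_real_)
  }
  1 - sum(w * O) / denom
}

#' Severity-stratified classification report
#'
#' Converts predictions to severity categories (clamp to `[0,24]`, round
#' half-to-even, classify), builds the 3x3 confusion matrix against the
#' reference categories, and computes one-vs-rest accuracy, sensitivity,
#' specificity, NPV and PPV per category (in percent) with 95% Wilson
#' score confidence intervals. Metrics whose denominator is empty are
#' returned as `NA`.
#'
#' @param p A [paired_scores()].
#' @return Object of class `confusion_summary`: `matrix` (rows =
#'   reference, cols = predicted), `overall_accuracy`, and `per_category`
#'   data.frame.
#' @export
severity_report <- function(p) {
  stopifnot(inherits(p, "paired_scores"))
  ref <- classify_severity(p$reference)
  pred <- classify_severity(round(pmin(24, pmax(0, p$predicted))))
  lev <- severity_levels()
  m <- table(reference = factor(ref, lev), predicted = factor(pred, lev))
  n <- sum(m)
  rows <- lapply(lev, function(cat) {
    tp <- m[cat, cat]
    fn <- sum(m[cat, ]) - tp
    fp <- sum(m[, cat]) - tp
    tn <- n - tp - fn - fp
    metric <- function(num, den) {
      if (den == 0) {
        c(est = NA_real_, lower = NA_real_, upper = NA_real_)
      } else {
        ci <- wilson_ci(num, den)
        c(est = 100 * num / den, lower = 100 * ci[1], upper = 100 * ci[2])
      }
    }
    vals <- rbind(accuracy = metric(tp + tn, n),
                  sensitivity = metric(tp, tp + fn),
                  specificity = metric(tn, tn + fp),
                  npv = metric(tn, tn + fn),
                  ppv = metric(tp, tp + fp))
    data.frame(category = cat, metric = rownames(vals), vals,
               row.names = NULL)
  })
  structure(list(matrix = unclass(m),
                 overall_accuracy = 100 * sum(diag(m)) / n,
                 per_category = do.call(rbind, rows)),
            class = "confusion_summary")
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("confusion matrix (rows = reference, cols = predicted):\n")
  print(x$matrix)
  cat(sprintf("overall accuracy: %.1f%%\n", x$overall_accuracy))
  pc <- x$per_category
  pc[, c("est", "lower", "upper")] <- round(pc[, c("est", "lower",
                                                   "upper")], 1)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Full evaluation report for a validation set
#'
#' Bundles [regression_metrics()], [acceptable_proportion()],
#' [icc_2_1()] between reference and raw predictions, [weighted_kappa()]
#' on the categorised scale, [severity_report()], and (optionally)
#' bootstrap CIs for MAE/MSE/rho/R2 in resample mode.
#'
#' @param p A [paired_scores()].
#' @param kappa_scheme Weighting scheme for [weighted_kappa()].
#' @param acceptability_threshold Threshold for [acceptable_proportion()].
#' @param bootstrap_B Replicates for the metric CIs; 0 disables them.
#' @param seed Bootstrap seed.
#' @return Object of class `eval_report`.
#' @export
evaluate_scores <- function(p, kappa_scheme = "quadratic",
                            acceptability_threshold = 4,
                            bootstrap_B = 0L, seed = 1L) {
  stopifnot(inherits(p, "paired_scores"))
  reg <- regression_metrics(p)
  rounded <- round(pmin(24, pmax(0, p$predicted)))
  kap <- weighted_kappa(p$reference, rounded, scheme = kappa_scheme,
                        categories = 0:24)
  icc <- icc_2_1(cbind(p$reference, p$predicted))
  ci <- NULL
  if (bootstrap_B > 0) {
    ci <- bootstrap_ci(function(ps) {
      r <- regression_metrics(ps)
      c(mae = r$mae, mse = r$mse, spearman_rho = r$spearman_rho,
        r2 = r$r2,
        acceptable = acceptable_proportion(ps, acceptability_threshold))
    }, p, B = bootstrap_B, mode = "resample", seed = seed)
  }
  structure(list(
    metrics = reg,
    acceptable_proportion = acceptable_proportion(
      p, acceptability_threshold),
    acceptability_threshold = acceptability_threshold,
    icc = icc, weighted_kappa = kap, kappa_scheme = kappa_scheme,
    severity = severity_report(p), bootstrap = ci, n = length(p$reference)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AAC evaluation report (n = %d)\n", x$n))
  print(x$metrics)
  cat(sprintf("acceptable (|error| < %g): %.1f%%\n",
              x$acceptability_threshold, 100 * x$acceptable_proportion))
  cat(sprintf("ICC(2,1): %.3f   weighted kappa (%s): %.3f\n",
              x$icc, x$kappa_scheme, x$weighted_kappa))
  print(x$severity)
  if (!is.null(x$bootstrap)) print(x$bootstrap)
  invisible(x)
}

#' Serialise an evaluation report
#'
#' @param report An `eval_report`.
#' @param path Output file; `.json` writes JSON, `.md` a Markdown table.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    out <- list(
      n = report$n,
      mae = report$metrics$mae, mse = report$metrics$mse,
      spearman_rho = report$metrics$spearman_rho, r2 = report$metrics$r2,
      acceptable_proportion = report$acceptable_proportion,
      icc = report$icc, weighted_kappa = report$weighted_kappa,
      kappa_scheme = report$kappa_scheme,
      overall_accuracy = report$severity$overall_accuracy,
      confusion = report$severity$matrix,
      per_category = report$severity$per_category)
    if (!is.null(report$bootstrap)) out$ci <- report$bootstrap$ci
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    lines <- c(
      sprintf("| metric | value |"), "|---|---|",
      sprintf("| n | %d |", report$n),
      sprintf("| MAE | %.3f |", report$metrics$mae),
      sprintf("| MSE | %.3f |", report$metrics$mse),
      sprintf("| Spearman rho | %.3f |", report$metrics$spearman_rho),
      sprintf("| R2 | %.3f |", report$metrics$r2),
      sprintf("| acceptable (<%g) | %.1f%% |",
              report$acceptability_threshold,
              100 * report$acceptable_proportion),
      sprintf("| ICC(2,1) | %.3f |", report$icc),
      sprintf("| weighted kappa (%s) | %.3f |", report$kappa_scheme,
              report$weighted_kappa))
    writeLines(lines, path)
  }
  invisible(path)
}
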