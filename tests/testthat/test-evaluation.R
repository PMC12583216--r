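test_that("regression metrics reproduce hand arithmetic", {
  p <- paired_scores(c(0, 10, 20), c(2, 10, 18))
  m <- regression_metrics(p)
  expect_equal(m$mae, 4 / 3)
  expect_equal(m$mse, 8 / 3)
  perfect <- regression_metrics(paired_scores(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$spearman_rho, 1)
  expect_equal(perfect$r2, 1)
  # rank correlation ignores scale; R2 does not
  scaled <- regression_metrics(paired_scores(1:4, c(10, 20, 30, 40)))
  expect_equal(scaled$spearman_rho, 1)
  expect_lt(scaled$r2, 0)
})

test_that("zero-variance references flag rho and R2 as undefined", {
  m <- regression_metrics(paired_scores(c(5, 5, 5), c(4, 5, 6)))
  expect_true(is.na(m$spearman_rho))
  expect_true(is.na(m$r2))
  expect_equal(m$mae, 2 / 3)
})

test_that("MAE never exceeds the root of MSE", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    p <- paired_scores(sample(0:24, n, TRUE),
                       runif(n, -2, 26))
    m <- regression_metrics(p)
    expect_lte(m$mae, sqrt(m$mse) + 1e-12)
  }
})

test_that("acceptability uses a strict inequality", {
  ref <- c(0L, 0L, 0L)
  pred <- c(0, 3.9, 4.0)
  expect_equal(acceptable_proportion(paired_scores(ref, pred)), 2 / 3)
  expect_equal(acceptable_proportion(paired_scores(ref, ref)), 1)
  expect_equal(acceptable_proportion(paired_scores(ref, ref),
                                     threshold = 0), 0)
})

test_that("ICC(2,1) matches an independent ANOVA decomposition", {
  icc_oracle <- function(x) {
    n <- nrow(x)
    k <- ncol(x)
    df <- data.frame(y = as.vector(x), subj = factor(rep(1:n, k)),
                     rater = factor(rep(1:k, each = n)))
    a <- stats::anova(stats::aov(y ~ subj + rater, df))
    msr <- a["subj", "Mean Sq"]
    msc <- a["rater", "Mean Sq"]
    mse <- a["Residuals", "Mean Sq"]
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:15, 1)
    k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k, sd = 3) + rep(rnorm(n, sd = 2), k), n, k)
    expect_lt(abs(icc_2_1(x) - icc_oracle(x)), 1e-10)
  }
})

test_that("ICC is 1 under perfect agreement and penalises constant bias", {
  x <- cbind(1:10, 1:10)
  expect_equal(icc_2_1(x), 1)
  biased <- cbind(1:10, 1:10 + 15)
  expect_lt(icc_2_1(biased), 0.5)
  # consistency-style column scaling also departs from 1
  expect_lt(icc_2_1(cbind(1:10, (1:10) * 2)), 1)
  expect_error(icc_2_1(matrix(1:3, 3, 1)), "raters")
  expect_error(icc_2_1(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("weighted kappa matches a brute-force contingency oracle", {
  kappa_oracle <- function(a, b, scheme) {
    cats <- sort(unique(c(a, b)))
    R <- length(cats)
    w <- function(i, j) {
      d <- abs(i - j) / (R - 1)
      if (scheme == "linear") d else d^2
    }
    num <- 0
    den <- 0
    nn <- length(a)
    for (i in 1:R) {
      for (j in 1:R) {
        o <- sum(a == cats[i] & b == cats[j]) / nn
        e <- (sum(a == cats[i]) / nn) * (sum(b == cats[j]) / nn)
        num <- num + w(i, j) * o
        den <- den + w(i, j) * e
      }
    }
    1 - num / den
  }
  set.seed(8)
  for (i in 1:25) {
    nn <- sample(20:80, 1)
    a <- sample(0:4, nn, TRUE)
    b <- pmin(4, pmax(0, a + sample(-2:2, nn, TRUE)))
    for (sch in c("linear", "quadratic")) {
      expect_lt(abs(weighted_kappa(a, b, sch) - kappa_oracle(a, b, sch)),
                1e-10)
    }
  }
})

test_that("weighted kappa is 1 for identical ratings and ~0 under independence", {
  a <- c(1, 2, 3, 2, 1, 3)
  expect_equal(weighted_kappa(a, a), 1)
  set.seed(9)
  x <- sample(1:5, 4000, TRUE)
  y <- sample(1:5, 4000, TRUE)
  expect_lt(abs(weighted_kappa(x, y)), 0.06)
  expect_warning(k <- weighted_kappa(c(1, 1), c(1, 1)), "one category")
  expect_true(is.na(k))
})

test_that("agreement statistics are invariant to subject permutation", {
  set.seed(10)
  x <- matrix(rnorm(24), 12, 2)
  perm <- sample(12)
  expect_equal(icc_2_1(x[perm, ]), icc_2_1(x))
  a <- sample(0:3, 30, TRUE)
  b <- sample(0:3, 30, TRUE)
  perm <- sample(30)
  expect_equal(weighted_kappa(a[perm], b[perm]), weighted_kappa(a, b))
})

test_that("bootstrap intervals are percentile order statistics", {
  # degenerate experiment: zero-width interval at the constant
  p <- paired_scores(sample(0:24, 50, TRUE), runif(50, 0, 24))
  bs0 <- bootstrap_ci(function(ps) c(k = 3.5), p, B = 50, seed = 1)
  expect_equal(unname(bs0$ci[, "k"]), c(3.5, 3.5))
  # interval brackets the point estimate and matches quantile()
  bs <- bootstrap_ci(function(ps) c(mae = regression_metrics(ps)$mae),
                     p, B = 400, seed = 2)
  m0 <- regression_metrics(p)$mae
  expect_lte(bs$ci["lower", "mae"], m0)
  expect_gte(bs$ci["upper", "mae"], m0)
  q <- stats::quantile(bs$replicates[, "mae"], c(0.025, 0.975),
                       names = FALSE)
  expect_equal(unname(bs$ci[, "mae"]), q)
})

test_that("retrain-mode bootstrap passes resampled training indices", {
  seen <- list()
  bs <- bootstrap_ci(function(idx) {
    seen[[length(seen) + 1]] <<- idx
    c(m = mean(idx))
  }, data = 37, B = 5, mode = "retrain", seed = 3)
  expect_length(seen, 5)
  expect_true(all(vapply(seen, length, integer(1)) == 37))
  expect_true(all(unlist(seen) %in% 1:37))
  expect_identical(nrow(bs$replicates), 5L)
  expect_gt(stats::sd(bs$replicates[, "m"]), 0)
})

test_that("the bootstrap aborts when too many replicates fail", {
  p <- paired_scores(sample(0:24, 20, TRUE), runif(20))
  expect_error(
    bootstrap_ci(function(ps) stop("boom"), p, B = 100, seed = 4),
    "replicates failed")
})

test_that("severity report reproduces one-vs-rest arithmetic", {
  # construct pairs realising the confusion matrix (8,2,0 / 1,9,0 / 0,3,7)
  ref_cat <- c(rep(0, 10), rep(1, 10), rep(2, 10))
  pred_cat <- c(rep(0, 8), 1, 1, 0, rep(1, 9), 1, 1, 1, rep(2, 7))
  anchors <- c(2L, 10L, 20L)
  p <- paired_scores(anchors[ref_cat + 1], anchors[pred_cat + 1])
  sr <- severity_report(p)
  expect_identical(unname(sr$matrix),
                   matrix(c(8L, 1L, 0L, 2L, 9L, 3L, 0L, 0L, 7L), 3))
  expect_equal(sr$overall_accuracy, 100 * 24 / 30)
  get <- function(cat, met) {
    subset(sr$per_category, category == cat & metric == met)$est
  }
  expect_equal(get("no_mild", "sensitivity"), 100 * 8 / 10)
  expect_equal(get("no_mild", "specificity"), 100 * 19 / 20)
  expect_equal(get("no_mild", "ppv"), 100 * 8 / 9)
  expect_equal(get("no_mild", "npv"), 100 * 19 / 21)
  expect_equal(get("severe", "sensitivity"), 100 * 7 / 10)
  expect_equal(get("severe", "ppv"), 100)
  # marginals reproduce category counts
  expect_identical(unname(rowSums(sr$matrix)), rep(10, 3))
})

test_that("perfect predictions give a diagonal matrix and 100% everywhere", {
  ref <- c(rep(2L, 5), rep(10L, 5), rep(20L, 5))
  sr <- severity_report(paired_scores(ref, ref))
  expect_identical(sum(sr$matrix) - sum(diag(sr$matrix)), 0L)
  ests <- subset(sr$per_category,
                 metric %in% c("sensitivity", "specificity"))$est
  expect_true(all(ests == 100))
})

test_that("categories absent from the data yield NA metrics, not errors", {
  ref <- rep(2L, 10)
  pred <- rep(2, 10)
  sr <- severity_report(paired_scores(ref, pred))
  spec_no_mild <- subset(sr$per_category,
                         category == "no_mild" & metric == "specificity")
  expect_true(is.na(spec_no_mild$est))
  sens_mod <- subset(sr$per_category,
                     category == "moderate" & metric == "sensitivity")
  expect_true(is.na(sens_mod$est))
})

test_that("proportion intervals use the Wilson score method", {
  ci <- aacquant:::wilson_ci(45, 60)
  pt <- stats::prop.test(45, 60, correct = FALSE)$conf.int
  expect_equal(ci[1], pt[1], tolerance = 1e-10)
  expect_equal(ci[2], pt[2], tolerance = 1e-10)
})

test_that("evaluate_scores bundles all statistics coherently", {
  set.seed(12)
  ref <- sample(0:24, 80, TRUE)
  pred <- pmin(24, pmax(0, ref + rnorm(80, sd = 2)))
  rep_ <- evaluate_scores(paired_scores(ref, pred), bootstrap_B = 100,
                          seed = 5)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$metrics$mae, mean(abs(pred - ref)))
  expect_true(rep_$icc > 0.8)
  expect_true(rep_$weighted_kappa > 0.5)
  expect_identical(sum(rep_$severity$matrix), 80L)
  expect_true(all(c("mae", "mse") %in% colnames(rep_$bootstrap$ci)))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$mae, rep_$metrics$mae, tolerance = 1e-9)
})
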