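test_that("learning-rate schedule reproduces the printed anchor values", {
  tc <- train_config()
  total <- 5000L
  # warmup start: one third of the base rate
  expect_equal(lr_at(0, total, tc), 0.01 / 3, tolerance = 1e-12)
  # warmup end: the full base value
  expect_equal(lr_at(200, total, tc), 0.01, tolerance = 1e-12)
  # final step: the floor
  expect_equal(lr_at(total - 1, total, tc), 1e-4, tolerance = 1e-12)
})

test_that("schedule is continuous at warmup and non-increasing after", {
  tc <- train_config()
  total <- 3000L
  lr <- lr_at(0:(total - 1), total, tc)
  expect_lt(abs(lr[200] - lr[201]), 1e-4)   # boundary continuity
  expect_true(all(diff(lr[201:total]) <= 1e-15))
  expect_true(all(diff(lr[1:200]) > 0))     # strictly increasing warmup
})

test_that("zero-magnitude augmentation is the identity", {
  set.seed(1)
  px <- matrix(rnorm(250 * 125), 250, 125)
  out <- augment_patch(px, augment_config(0, 0, 0, 0, 0, 0), seed = 3)
  expect_identical(out, px)
})

test_that("augmentation is reproducible and shape/score-preserving", {
  set.seed(2)
  px <- matrix(rnorm(100 * 60), 100, 60)
  a <- augment_patch(px, augment_config(), seed = 11)
  b <- augment_patch(px, augment_config(), seed = 11)
  c <- augment_patch(px, augment_config(), seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_identical(dim(a), dim(px))
  p <- structure(list(pixels = px, normalization = list(),
                      provenance = list()), class = "aac_patch")
  ap <- augment_patch(p, augment_config(), seed = 4)
  expect_s3_class(ap, "aac_patch")
})

test_that("a pure shift moves the image centroid by the shift amount", {
  px <- matrix(0, 100, 100)
  px[48:52, 48:52] <- 1
  cfg <- augment_config(0, 0, 0, shift = 0.05, 0, 0)
  centroid <- function(m) {
    idx <- which(m > 0.5, arr.ind = TRUE)
    colMeans(idx)
  }
  moved <- FALSE
  for (seed in 1:5) {
    out <- augment_patch(px, cfg, seed = seed)
    d <- centroid(out) - centroid(px)
    expect_true(all(abs(d) <= 5 + 1))  # at most 5% of size, 1 px slack
    if (any(abs(d) > 0.5)) moved <- TRUE
  }
  expect_true(moved)
})

test_that("the regressor emits one finite scalar and clamps on request", {
  rc <- regressor_config(stem_channels = 4L, stage_blocks = c(1L, 1L),
                         stage_channels = c(4L, 8L),
                         input_size = c(64L, 32L), seed = 3L)
  m <- build_regressor(rc)
  zero <- matrix(0, 64, 32)
  out <- predict_score(m, zero)
  expect_length(out, 1)
  expect_true(is.finite(out))
  expect_true(predict_score(m, zero, "clamped") >= 0)
  expect_true(predict_score(m, zero, "clamped") <= 24)
  expect_error(predict_score(m, matrix(0, 10, 10)), "expects")
})

test_that("rounding half-to-even places borderline scores in the right tier", {
  expect_identical(as.character(classify_severity(round(4.4))), "no_mild")
  expect_identical(as.character(classify_severity(round(4.6))), "moderate")
})

test_that("attention toggling changes exactly the attention parameters", {
  mk <- function(att) build_regressor(
    regressor_config(stem_channels = 4L, stage_blocks = c(1L, 1L),
                     stage_channels = c(4L, 8L), attention = att,
                     input_size = c(64L, 32L), seed = 3L))
  n_on <- aacquant:::ptree_count(mk(TRUE)$params)
  n_off <- aacquant:::ptree_count(mk(FALSE)$params)
  scse_params <- function(c) {
    cr <- max(1L, c %/% 2L)
    (cr * c + cr) + (c * cr + c) + (c + 1)  # two fc layers + 1x1 conv
  }
  expect_identical(n_on - n_off, scse_params(4) + scse_params(8))
})

test_that("identical seeds give identical initial parameters", {
  rc <- regressor_config(seed = 9L)
  a <- build_regressor(rc)
  b <- build_regressor(rc)
  expect_identical(a$params, b$params)
})

test_that("the network can overfit a handful of patches", {
  set.seed(6)
  co <- sample_cohort(cohort_spec(10, seed = 61))
  d <- list(patches = lapply(co, function(s) {
    extract_patch(s$image, compute_crop_box(s$vertebra_mask),
                  c(64L, 32L))
  }), scores = vapply(co, function(s) s$truth$total, numeric(1)))
  rc <- regressor_config(stem_channels = 6L, stage_blocks = c(1L, 1L),
                         stage_channels = c(6L, 12L),
                         input_size = c(64L, 32L), seed = 5L)
  tc <- train_config(base_lr = 0.005, max_epochs = 200L, batch_size = 10L,
                     warmup_iters = 20L, val_check_every = 50L,
                     patience = 100L, weight_decay = 0, seed = 8L)
  m <- train_regressor(d, d, rc, tc)
  final_train <- tail(stats::aggregate(train_mse ~ epoch, m$history,
                                       mean)$train_mse, 1)
  expect_lt(final_train, 1.5)
})

test_that("history learning rates follow the schedule", {
  f <- reg_fixture()
  h <- f$model$history
  tc <- f$model$train_config
  n_iters <- ceiling(400 / tc$batch_size) * tc$max_epochs
  expect_equal(h$lr, lr_at(h$iter, n_iters, tc), tolerance = 1e-12)
})

test_that("desk-scale training recovers synthetic truth", {
  f <- reg_fixture()
  p <- paired_scores(f$test$scores, f$predictions)
  m <- regression_metrics(p)
  expect_gte(m$spearman_rho, 0.8)
  expect_lte(m$mae, 2.5)
})

test_that("a model's parameters can seed a new build (warm start hook)", {
  rc <- regressor_config(stem_channels = 4L, stage_blocks = c(1L, 1L),
                         stage_channels = c(4L, 8L),
                         input_size = c(64L, 32L), seed = 3L)
  donor <- build_regressor(rc)
  rc2 <- rc
  rc2$seed <- 99L
  rc2$init_params <- donor$params
  warm <- build_regressor(rc2)
  expect_identical(warm$params, donor$params)
  rc_bad <- regressor_config(stem_channels = 6L, stage_blocks = c(1L, 1L),
                             stage_channels = c(6L, 8L),
                             input_size = c(64L, 32L),
                             init_params = donor$params)
  expect_error(build_regressor(rc_bad), "does not match")
})
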