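# Shared fixtures. Heavy artifacts (trained networks, large cohorts) are
# built once per test run and memoised here so module tests and the
# acceptance suite reuse the same objects.

fixture_env <- new.env(parent = emptyenv())

memoise_fixture <- function(name, builder) {
  if (!exists(name, fixture_env)) {
    assign(name, builder(), fixture_env)
  }
  get(name, fixture_env)
}

# a small deterministic phantom with two calcified segments
demo_phantom <- function(seed = 5L) {
  make_phantom(
    phantom_spec(calcified_fractions = c(0.5, 0, 0, 0, 0, 0.9, 0, 0)),
    seed = seed)
}

# rectangular vertebra mask built directly from row/column extents
rect_mask <- function(h = 128, w = 256,
                      rows = list(c(15, 29), c(35, 49), c(55, 69),
                                  c(75, 89), c(95, 109)),
                      cols = rep(list(c(180, 220)), 5),
                      anterior_side = "left") {
  lab <- matrix(0L, h, w)
  for (v in 1:5) {
    lab[rows[[v]][1]:rows[[v]][2], cols[[v]][1]:cols[[v]][2]] <- v
  }
  vertebra_mask(lab, anterior_side = anterior_side)
}

# Desk-scale segmentation run: 60 training phantoms, 12 held-out.
seg_fixture <- function() {
  memoise_fixture("seg", function() {
    train <- sample_cohort(cohort_spec(60, seed = 101L))
    test <- sample_cohort(cohort_spec(12, seed = 202L))
    model <- train_segmenter(train, seg_config(seed = 7L))
    dices <- vapply(test, function(s) {
      pm <- segment_vertebrae(model, s$image)
      aacquant:::mean_label_dice(pm$labels, s$vertebra_mask$labels)
    }, numeric(1))
    list(model = model, test = test, dices = dices)
  })
}

# Desk-scale regression run: 400 training patches, 60 validation,
# 60 held-out test patches from ground-truth masks.
reg_fixture <- function() {
  memoise_fixture("reg", function() {
    target <- c(250L, 125L)
    mk <- function(n, seed) {
      co <- sample_cohort(cohort_spec(n, seed = seed))
      list(cohort = co,
           patches = lapply(co, function(s) {
             extract_patch(s$image, compute_crop_box(s$vertebra_mask),
                           target)
           }),
           scores = vapply(co, function(s) s$truth$total, numeric(1)))
    }
    tr <- mk(400, 301L)
    va <- mk(60, 302L)
    te <- mk(60, 303L)
    model <- train_regressor(
      tr, va, regressor_config(seed = 11L),
      train_config(max_epochs = 12L, batch_size = 16L,
                   warmup_iters = 100L, val_check_every = 3L,
                   patience = 4L, seed = 12L))
    preds <- predict(model, te$patches)
    list(model = model, test = te, predictions = preds)
  })
}
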