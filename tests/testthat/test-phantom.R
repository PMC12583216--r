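test_that("zero calcification yields an empty mask and zero truth", {
  s <- make_phantom(phantom_spec(), seed = 1)
  expect_identical(s$truth$total, 0L)
  expect_identical(sum(s$calcification_mask), 0L)
})

test_that("a single half-length deposit scores 2 points total", {
  sp <- phantom_spec(calcified_fractions = c(0.5, rep(0, 7)))
  s <- make_phantom(sp, seed = 1)
  expect_identical(s$truth$total, 2L)
})

test_that("rendering is deterministic for fixed spec and seed", {
  sp <- phantom_spec(calcified_fractions = runif(8))
  a <- make_phantom(sp, seed = 42)
  b <- make_phantom(sp, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$vertebra_mask$labels, b$vertebra_mask$labels)
  expect_identical(a$calcification_mask, b$calcification_mask)
  c <- make_phantom(sp, seed = 43)
  expect_false(identical(a$image, c$image))
})

test_that("image and masks share dimensions and calcification stays in the band", {
  co <- sample_cohort(cohort_spec(8, seed = 3))
  for (s in co) {
    expect_identical(dim(s$image), dim(s$vertebra_mask$labels))
    expect_identical(dim(s$image), dim(s$calcification_mask))
    g <- aacquant:::phantom_geometry(s$spec)
    calc_cols <- which(s$calcification_mask != 0, arr.ind = TRUE)[, 2] - 1L
    if (length(calc_cols)) {
      expect_true(all(calc_cols >= g$aorta_cols[1] &
                        calc_cols < g$aorta_cols[2]))
    }
    # no overlap with vertebrae
    expect_identical(sum(s$calcification_mask * (s$vertebra_mask$labels > 0)),
                     0L)
  }
})

test_that("geometry that does not fit the canvas is rejected by field", {
  expect_error(phantom_spec(image_height = 50), "image_height")
  expect_error(phantom_spec(vertebra_ap_lengths = rep(300, 5)),
               "image_width")
  expect_error(phantom_spec(calcified_fractions = rep(1.5, 8)),
               "calcified_fractions")
  expect_error(phantom_spec(wall_thickness = 20), "wall_thickness")
})

test_that("cohort sampling respects a degenerate severity mix", {
  co <- sample_cohort(cohort_spec(50, severity_mix = c(1, 0, 0), seed = 9))
  expect_true(all(vapply(co, function(s) s$truth$total, numeric(1)) <= 4))
})

test_that("empirical severity proportions approach the requested mix", {
  # small canvas keeps rendering cheap; the category draw is unaffected
  base <- phantom_spec(image_height = 64, image_width = 128,
                       vertebra_heights = rep(7, 5),
                       vertebra_ap_lengths = rep(20, 5),
                       gap_heights = rep(3, 4), top_margin = 7,
                       aorta_offset = 9, aorta_width = 12,
                       wall_thickness = 3)
  mix <- c(0.22, 0.65, 0.13)
  co <- sample_cohort(cohort_spec(1000, severity_mix = mix,
                                  base_spec = base, geometry_jitter = 0.05,
                                  seed = 77))
  cats <- vapply(co, function(s) s$truth$category, character(1))
  emp <- as.numeric(table(factor(cats, aacquant:::severity_levels())) / 1000)
  expect_true(all(abs(emp - mix) <= 0.04))
})

test_that("different cohort seeds give different content, same schema", {
  a <- sample_cohort(cohort_spec(3, seed = 1))
  b <- sample_cohort(cohort_spec(3, seed = 2))
  expect_false(identical(a[[1]]$image, b[[1]]$image))
  da <- write_dataset(a, withr::local_tempdir())
  db <- write_dataset(b, withr::local_tempdir())
  expect_identical(names(da), names(db))
})

test_that("datasets round-trip through disk exactly", {
  co <- sample_cohort(cohort_spec(10, seed = 21))
  dir <- withr::local_tempdir()
  manifest <- write_dataset(co, dir)
  expect_identical(nrow(manifest), 10L)
  expect_identical(names(manifest),
                   c("id", aacquant:::grade_columns(), "total", "category",
                     "seed"))
  rt <- read_dataset(dir)
  for (i in 1:10) {
    expect_identical(rt$samples[[i]]$truth$grades, co[[i]]$truth$grades)
    expect_identical(rt$samples[[i]]$vertebra_mask$labels,
                     co[[i]]$vertebra_mask$labels)
    expect_identical(rt$samples[[i]]$calcification_mask,
                     co[[i]]$calcification_mask)
    # 16-bit storage: intensities to ~1.6e-5
    expect_lt(max(abs(rt$samples[[i]]$image - co[[i]]$image)), 1e-4)
  }
})

test_that("an empty sample list writes a valid empty manifest", {
  dir <- withr::local_tempdir()
  manifest <- write_dataset(list(), dir)
  expect_identical(nrow(manifest), 0L)
  expect_identical(ncol(manifest), 12L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})

test_that("photometric heterogeneity never alters masks or truth", {
  base <- phantom_spec(calcified_fractions = c(0.5, 0, 0.2, 0, 0, 0.9, 0, 0))
  ref <- make_phantom(base, seed = 6)
  for (ip in list(list(brightness = 0.2, contrast = 1.3, noise_sd = 0.05),
                  list(brightness = -0.2, contrast = 0.7,
                       noise_sd = 0.001))) {
    sp <- base
    sp$intensity_params$brightness <- ip$brightness
    sp$intensity_params$contrast <- ip$contrast
    sp$intensity_params$noise_sd <- ip$noise_sd
    s <- make_phantom(sp, seed = 6)
    expect_identical(s$vertebra_mask$labels, ref$vertebra_mask$labels)
    expect_identical(s$calcification_mask, ref$calcification_mask)
    expect_identical(s$truth$grades, ref$truth$grades)
    expect_false(identical(s$image, ref$image))
  }
})
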