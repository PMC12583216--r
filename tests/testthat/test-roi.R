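test_that("crop box matches the closed-form anatomical geometry", {
  s <- demo_phantom()
  box <- compute_crop_box(s$vertebra_mask)
  g <- aacquant:::phantom_geometry(s$spec)
  mean_gap <- mean(g$vert_rows[2:5, "start"] - g$vert_rows[1:4, "end"])
  mean_ap <- mean(g$vert_cols[, "end"] - g$vert_cols[, "start"])
  expect_identical(box$row_start,
                   as.integer(g$vert_rows[1, "start"] -
                                round(0.5 * mean_gap)))
  expect_identical(box$row_end, as.integer(g$vert_rows[5, "end"]))
  expect_identical(box$col_end, as.integer(max(g$vert_cols[, "end"])))
  expect_identical(box$col_start,
                   as.integer(min(g$vert_cols[, "start"]) -
                                round(0.75 * mean_ap)))
})

test_that("crop box contains every vertebral pixel and clamps to bounds", {
  co <- sample_cohort(cohort_spec(5, seed = 13))
  for (s in co) {
    box <- compute_crop_box(s$vertebra_mask)
    idx <- which(s$vertebra_mask$labels > 0, arr.ind = TRUE)
    expect_true(all(idx[, 1] - 1 >= box$row_start &
                      idx[, 1] - 1 < box$row_end))
    expect_true(all(idx[, 2] - 1 >= box$col_start &
                      idx[, 2] - 1 < box$col_end))
  }
  # mask hugging the anterior edge clamps at column 0
  m <- rect_mask(cols = rep(list(c(5, 45)), 5))
  box <- compute_crop_box(m)
  expect_identical(box$col_start, 0L)
})

test_that("crop geometry mirrors exactly when the anterior side flips", {
  s <- demo_phantom()
  w <- ncol(s$image)
  box <- compute_crop_box(s$vertebra_mask)
  flipped <- vertebra_mask(s$vertebra_mask$labels[, w:1],
                           anterior_side = "right")
  box_f <- compute_crop_box(flipped)
  expect_identical(box_f$row_start, box$row_start)
  expect_identical(box_f$row_end, box$row_end)
  expect_identical(box_f$col_start, w - box$col_end)
  expect_identical(box_f$col_end, w - box$col_start)
})

test_that("crop geometry is translation-equivariant", {
  rows <- list(c(31, 45), c(51, 65), c(71, 85), c(91, 105), c(111, 125))
  m1 <- rect_mask(h = 160, w = 256, rows = rows,
                  cols = rep(list(c(150, 190)), 5))
  m2 <- rect_mask(h = 160, w = 256,
                  rows = lapply(rows, function(r) r + 10),
                  cols = rep(list(c(160, 200)), 5))
  b1 <- compute_crop_box(m1)
  b2 <- compute_crop_box(m2)
  expect_identical(b2$row_start, b1$row_start + 10L)
  expect_identical(b2$row_end, b1$row_end + 10L)
  expect_identical(b2$col_start, b1$col_start + 10L)
  expect_identical(b2$col_end, b1$col_end + 10L)
})

test_that("a failed coverage check propagates into the crop error", {
  m <- rect_mask()
  m$labels[m$labels == 4L] <- 0L
  expect_error(compute_crop_box(m), "missing L4")
})

test_that("patches come out at the target size, Z-scored before resize", {
  s <- demo_phantom()
  box <- compute_crop_box(s$vertebra_mask)
  p <- extract_patch(s$image, box, target = c(1000L, 500L))
  expect_identical(dim(p$pixels), c(1000L, 500L))
  expect_true(all(is.finite(p$pixels)))
  # the recorded normalisation reproduces a zero-mean unit-sd crop
  crop <- s$image[(box$row_start + 1):box$row_end,
                  (box$col_start + 1):box$col_end]
  z <- (crop - p$normalization$mean) / p$normalization$sd
  expect_lt(abs(mean(z)), 1e-6)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
})

test_that("constant crops normalise to all-zero patches", {
  img <- matrix(0.5, 64, 64)
  p <- extract_patch(img, crop_box(0, 32, 0, 32), target = c(50L, 25L))
  expect_true(all(p$pixels == 0))
})

test_that("degenerate boxes are rejected", {
  expect_error(crop_box(10, 10, 0, 5), "degenerate")
  img <- matrix(0, 20, 20)
  expect_error(extract_patch(img, crop_box(30, 40, 0, 5), c(10L, 10L)),
               "empty after clamping")
})

test_that("patches round-trip disk through TIFF plus JSON sidecar", {
  s <- demo_phantom()
  p <- extract_patch(s$image, compute_crop_box(s$vertebra_mask),
                     target = c(100L, 50L), id = "rt")
  path <- file.path(withr::local_tempdir(), "patch.tif")
  write_patch(p, path)
  expect_true(file.exists(sub("tif$", "json", path)))
  q <- read_patch(path)
  expect_lt(max(abs(q$pixels - p$pixels)), 1e-6)
  expect_identical(q$provenance$box, p$provenance$box)
  expect_identical(q$normalization$method, p$normalization$method)
})
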