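test_that("per-segment grading follows the four printed rules", {
  expect_identical(grade_segment(0), 0L)
  expect_identical(grade_segment(0.2), 1L)
  expect_identical(grade_segment(0.5), 2L)
  expect_identical(grade_segment(0.8), 3L)
  # boundary inclusivity: 2 points at exactly 1/3 and exactly 2/3
  expect_identical(grade_segment(1 / 3), 2L)
  expect_identical(grade_segment(2 / 3), 2L)
  # any nonzero calcification scores at least 1
  expect_identical(grade_segment(1e-9), 1L)
  expect_identical(grade_segment(1), 3L)
  expect_error(grade_segment(-0.1), "\\[0, 1\\]")
  expect_error(grade_segment(1.1), "\\[0, 1\\]")
})

test_that("grading is monotone and covers exactly grades 0-3", {
  f <- seq(0, 1, by = 0.001)
  g <- grade_segment(f)
  expect_true(all(diff(g) >= 0))
  expect_identical(sort(unique(g)), 0:3)
})

test_that("totals sum the eight grades and validate input", {
  expect_identical(total_score(rep(0, 8)), 0L)
  expect_identical(total_score(rep(3, 8)), 24L)
  expect_identical(total_score(c(1, 0, 2, 0, 3, 0, 0, 0)), 6L)
  named <- stats::setNames(rep(1, 8), segment_keys())
  expect_identical(total_score(named), 8L)
  expect_error(total_score(rep(1, 7)), "8 segment")
  expect_error(total_score(c(rep(0, 7), 4)), "0, 1, 2, 3")
  expect_error(total_score(stats::setNames(rep(1, 8),
                                           c(segment_keys()[-1], "bogus"))),
               "L1_anterior")
})

test_that("severity tiers partition 0-24 as no/mild, moderate, severe", {
  totals <- 0:24
  cats <- as.character(classify_severity(totals))
  expect_identical(cats[totals <= 4], rep("no_mild", 5))
  expect_identical(cats[totals >= 5 & totals <= 15], rep("moderate", 11))
  expect_identical(cats[totals >= 16], rep("severe", 9))
  expect_identical(as.character(classify_severity(9)), "moderate")
  expect_error(classify_severity(25), "\\[0, 24\\]")
  expect_error(classify_severity(-1), "\\[0, 24\\]")
})

test_that("kauppila_score records grades, total and category consistently", {
  ks <- kauppila_score(c(3, 3, 3, 3, 2, 1, 1, 0))
  expect_s3_class(ks, "kauppila_score")
  expect_identical(ks$total, 16L)
  expect_identical(ks$category, "severe")
  expect_named(ks$grades, segment_keys())
  d <- as.data.frame(ks, id = "x")
  expect_identical(ncol(d), 11L)  # id + 8 grades + total + category
})

test_that("segment boundaries sit at intervertebral midpoints", {
  # vertebra rows (1-based): L1 101..200, L2 221..320, then 20-row gaps
  rows <- list(c(101, 200), c(221, 320), c(341, 440), c(461, 560),
               c(581, 680))
  mask <- rect_mask(h = 700, w = 256, rows = rows)
  sp <- segment_spans(mask)
  # 0-based half-open: L1 ends at (200 + 220) %/% 2 = 210
  expect_identical(sp$spans["L1", ], c(start = 100L, end = 210L))
  expect_identical(sp$spans["L2", "start"], 210L)
  # spans tile the column contiguously
  expect_true(all(sp$spans[-1, "start"] == sp$spans[-4, "end"]))
})

test_that("segment_spans matches the generator's analytic geometry", {
  s <- demo_phantom()
  sp <- segment_spans(s$vertebra_mask)
  expect_identical(sp$spans,
                   aacquant:::phantom_segment_spans(s$spec))
})

test_that("segment_spans reports structural mask defects", {
  m <- rect_mask()
  m$labels[m$labels == 3L] <- 0L
  expect_error(segment_spans(m), "missing L3")
  m2 <- rect_mask()
  m2$labels[60:61, ] <- 0L  # split L3 into two components
  expect_error(segment_spans(m2), "L3 split")
})

test_that("mask-based scoring reproduces known phantom truth", {
  s <- demo_phantom()
  g <- aacquant:::phantom_geometry(s$spec)
  sc <- score_from_masks(s$calcification_mask, s$vertebra_mask,
                         midline = g$aorta_midline)
  expect_identical(sc$total, 5L)  # grades 2 (0.5) + 3 (0.9)
  expect_identical(unname(sc$grades["L1_anterior"]), 2L)
  expect_identical(unname(sc$grades["L3_posterior"]), 3L)
  # default midline estimate agrees when both walls carry deposits
  sc2 <- score_from_masks(s$calcification_mask, s$vertebra_mask)
  expect_identical(sc2$grades, sc$grades)
})

test_that("empty calcification masks score zero", {
  s <- make_phantom(phantom_spec(), seed = 2)
  expect_identical(sum(s$calcification_mask), 0L)
  sc <- score_from_masks(s$calcification_mask, s$vertebra_mask)
  expect_identical(sc$total, 0L)
})

test_that("a strip spanning a whole segment wall grades 3", {
  sp <- phantom_spec(calcified_fractions = c(0, 0, 1, 0, 0, 0, 0, 0))
  s <- make_phantom(sp, seed = 1)
  sc <- score_from_masks(s$calcification_mask, s$vertebra_mask,
                         midline = aacquant:::phantom_geometry(sp)$aorta_midline)
  expect_identical(unname(sc$grades["L2_anterior"]), 3L)
  expect_identical(sc$total, 3L)
})

test_that("scoring is invariant to left-right mirroring", {
  for (seed in 1:5) {
    co <- sample_cohort(cohort_spec(1, seed = seed))
    s <- co[[1]]
    g <- aacquant:::phantom_geometry(s$spec)
    w <- ncol(s$image)
    sc <- score_from_masks(s$calcification_mask, s$vertebra_mask,
                           midline = g$aorta_midline)
    flip <- function(m) m[, w:1]
    mirrored <- vertebra_mask(flip(s$vertebra_mask$labels),
                              anterior_side = "right")
    sc_m <- score_from_masks(flip(s$calcification_mask), mirrored,
                             midline = w - 1 - g$aorta_midline)
    expect_identical(sc_m$grades, sc$grades)
  }
})
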