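# Synthetic lateral-radiograph phantoms: five vertebral bodies with
# intervertebral gaps, an anterior aortic band, per-segment calcified
# deposits of known length fraction, soft-tissue background and
# multicenter-style photometric heterogeneity. Every phantom carries its
# analytic ground-truth Kauppila score.

#' Specification of a single radiograph phantom
#'
#' Coordinate convention: row 0 is superior, rows increase inferiorly;
#' indices are 0-based and boxes half-open. `anterior_side` says which
#' column direction is the patient's front.
#'
#' @param image_height,image_width Canvas size in pixels.
#' @param vertebra_heights Five vertebral body heights (pixels, L1..L5).
#' @param vertebra_ap_lengths Five anteroposterior lengths (pixels).
#' @param gap_heights Four intervertebral gap heights (pixels).
#' @param top_margin Rows above the superior border of L1.
#' @param aorta_offset Distance from the anterior vertebral margin to the
#'   posterior aortic wall (pixels).
#' @param aorta_width Aortic band width (pixels).
#' @param wall_thickness Rendered thickness of a calcified wall deposit
#'   (pixels, must fit twice inside `aorta_width`).
#' @param calcified_fractions Eight fractions in `[0,1]`, ordered as
#'   [segment_keys()] (L1 anterior, L1 posterior, ..., L4 posterior).
#' @param intensity_params List with `background`, `bone`, `calcification`
#'   mean intensities (arbitrary units, stored as 16-bit), `noise_sd`, and
#'   optional `brightness` offset and `contrast` scale.
#' @param anterior_side `"left"` or `"right"`.
#' @param random_strip_position Place each calcified strip at a random
#'   row offset inside its segment instead of at the segment's superior
#'   boundary. Grades depend only on length fraction, so truth is
#'   unaffected.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_height = 128,
                         image_width = 256,
                         vertebra_heights = rep(14, 5),
                         vertebra_ap_lengths = rep(40, 5),
                         gap_heights = rep(6, 4),
                         top_margin = 14,
                         aorta_offset = 18,
                         aorta_width = 22,
                         wall_thickness = 4,
                         calcified_fractions = rep(0, 8),
                         intensity_params = list(background = 0.25,
                                                 bone = 0.75,
                                                 calcification = 0.55,
                                                 noise_sd = 0.02,
                                                 brightness = 0,
                                                 contrast = 1),
                         anterior_side = "left",
                         random_strip_position = FALSE) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  chk <- function(ok, field, why) {
    if (!all(ok)) stop(sprintf("invalid phantom_spec: %s (%s)", field, why),
                       call. = FALSE)
  }
  chk(length(spec$vertebra_heights) == 5, "vertebra_heights", "need 5 values")
  chk(length(spec$vertebra_ap_lengths) == 5, "vertebra_ap_lengths",
      "need 5 values")
  chk(length(spec$gap_heights) == 4, "gap_heights", "need 4 values")
  geom <- c(image_height = spec$image_height, image_width = spec$image_width,
            vertebra_heights = spec$vertebra_heights,
            vertebra_ap_lengths = spec$vertebra_ap_lengths,
            gap_heights = spec$gap_heights, aorta_offset = spec$aorta_offset,
            aorta_width = spec$aorta_width,
            wall_thickness = spec$wall_thickness)
  chk(geom > 0, names(geom)[which(geom <= 0)[1]], "must be positive")
  col_height <- spec$top_margin + sum(spec$vertebra_heights) +
    sum(spec$gap_heights)
  chk(col_height <= spec$image_height, "image_height",
      sprintf("vertebrae+gaps need %d rows", col_height))
  chk(2 * spec$wall_thickness <= spec$aorta_width, "wall_thickness",
      "two walls must fit inside aorta_width")
  width_needed <- max(spec$vertebra_ap_lengths) + spec$aorta_offset +
    spec$aorta_width + 8
  chk(width_needed <= spec$image_width, "image_width",
      sprintf("anatomy needs %d columns", width_needed))
  chk(length(spec$calcified_fractions) == 8 &&
        all(spec$calcified_fractions >= 0 & spec$calcified_fractions <= 1),
      "calcified_fractions", "need 8 values in [0,1]")
  chk(spec$anterior_side %in% c("left", "right"), "anterior_side",
      "left or right")
  spec
}

# Closed-form geometry shared by the renderer, the truth computation and
# the tests: 0-based half-open row/column intervals of every structure.
phantom_geometry <- function(spec) {
  r <- spec$top_margin
  vert_rows <- matrix(NA_integer_, 5, 2,
                      dimnames = list(paste0("L", 1:5), c("start", "end")))
  for (v in 1:5) {
    vert_rows[v, ] <- c(r, r + spec$vertebra_heights[v])
    r <- r + spec$vertebra_heights[v] + if (v < 5) spec$gap_heights[v] else 0
  }
  # columns: vertebral column sits toward the posterior side of the canvas
  w <- spec$image_width
  ap <- spec$vertebra_ap_lengths
  if (spec$anterior_side == "left") {
    post_margin <- w - 4 - max(ap)            # posterior-most vertebral col
    vert_cols <- cbind(start = post_margin + max(ap) - ap,
                       end   = post_margin + max(ap))
    ant_edge  <- min(vert_cols[, "start"])    # anterior-most vertebral col
    aorta_end   <- ant_edge - spec$aorta_offset
    aorta_start <- aorta_end - spec$aorta_width
  } else {
    post_margin <- 4
    vert_cols <- cbind(start = post_margin,
                       end   = post_margin + ap)
    ant_edge  <- max(vert_cols[, "end"])
    aorta_start <- ant_edge + spec$aorta_offset
    aorta_end   <- aorta_start + spec$aorta_width
  }
  rownames(vert_cols) <- paste0("L", 1:5)
  # anterior wall strip = the band edge on the patient's front side
  wt <- spec$wall_thickness
  if (spec$anterior_side == "left") {
    ant_wall  <- c(aorta_start, aorta_start + wt)
    post_wall <- c(aorta_end - wt, aorta_end)
  } else {
    ant_wall  <- c(aorta_end - wt, aorta_end)
    post_wall <- c(aorta_start, aorta_start + wt)
  }
  list(vert_rows = vert_rows, vert_cols = vert_cols,
       aorta_cols = c(aorta_start, aorta_end),
       aorta_midline = (aorta_start + aorta_end - 1) / 2,
       ant_wall_cols = ant_wall, post_wall_cols = post_wall)
}

# Segment spans implied analytically by the geometry (same midpoint rule as
# segment_spans() applied to a perfect mask).
phantom_segment_spans <- function(spec) {
  g <- phantom_geometry(spec)
  ext <- g$vert_rows
  mids <- integer(4)
  for (v in 1:4) mids[v] <- (ext[v, "end"] + ext[v + 1, "start"]) %/% 2L
  spans <- cbind(start = as.integer(c(ext[1, "start"], mids[1:3])),
                 end = as.integer(mids))
  rownames(spans) <- SEGMENT_LEVELS
  spans
}

# Number of calcified rows to render for a target fraction, chosen as the
# rounding of fraction*len that preserves the Kauppila grade (so the
# rasterised mask re-scores to exactly the analytic truth).
calc_rows_for_fraction <- function(fraction, len) {
  if (fraction == 0) return(0L)
  target <- grade_segment(fraction)
  cand <- unique(pmin(len, pmax(1L, round(fraction * len) + (-1:1))))
  ok <- cand[grade_segment(cand / len) == target]
  if (!length(ok)) {
    cand <- 1:len
    ok <- cand[grade_segment(cand / len) == target]
  }
  if (!length(ok)) {
    stop(sprintf(
      "segment span of %d rows cannot represent grade %d", len, target),
      call. = FALSE)
  }
  ok[which.min(abs(ok / len - fraction))]
}

#' Render a synthetic lateral radiograph phantom
#'
#' Deterministic for a fixed `(spec, seed)`. Calcification is rendered per
#' wall and level as a contiguous high-intensity strip whose craniocaudal
#' extent realises `calcified_fractions`; the ground-truth score is derived
#' analytically from the fractions via [grade_segment()].
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed controlling noise, texture and (optionally)
#'   strip placement.
#' @return An object of class `phantom_sample`: list with `image` (numeric
#'   matrix in `[0,1]`), `vertebra_mask` ([vertebra_mask()]),
#'   `calcification_mask` (0/1 integer matrix), `truth`
#'   ([kauppila_score()]), `spec` and `seed`.
#' @export
make_phantom <- function(spec, seed = 1L) {
  validate_phantom_spec(spec)
  g <- phantom_geometry(spec)
  h <- spec$image_height; w <- spec$image_width
  ip <- spec$intensity_params

  rng <- local_rng(seed)
  img <- matrix(ip$background, h, w)
  # mild low-frequency soft-tissue texture
  tex <- outer(sin(seq(0, 3 * pi, length.out = h) + rng$unif(1) * 2 * pi),
               cos(seq(0, 2 * pi, length.out = w) + rng$unif(1) * 2 * pi))
  img <- img + 0.02 * tex

  labels <- matrix(0L, h, w)
  for (v in 1:5) {
    rr <- (g$vert_rows[v, 1] + 1):g$vert_rows[v, 2]
    cc <- (g$vert_cols[v, 1] + 1):g$vert_cols[v, 2]
    img[rr, cc] <- ip$bone + 0.03 * tex[rr, cc]
    labels[rr, cc] <- v
  }
  # faint aortic band so the vessel is visible even without calcification
  band_cc <- (g$aorta_cols[1] + 1):g$aorta_cols[2]
  band_rr <- (g$vert_rows[1, 1] + 1):g$vert_rows[5, 2]
  img[band_rr, band_cc] <- img[band_rr, band_cc] + 0.03

  spans <- phantom_segment_spans(spec)
  calc <- matrix(0L, h, w)
  k <- 0L
  for (lev in 1:4) {
    len <- spans[lev, "end"] - spans[lev, "start"]
    for (wall in c("ant", "post")) {
      k <- k + 1L
      f <- spec$calcified_fractions[k]
      n <- calc_rows_for_fraction(f, len)
      if (n == 0L) next
      off <- if (isTRUE(spec$random_strip_position) && n < len) {
        floor(rng$unif(1) * (len - n + 1))
      } else 0
      rr <- (spans[lev, "start"] + off + 1):(spans[lev, "start"] + off + n)
      cc <- if (wall == "ant") {
        (g$ant_wall_cols[1] + 1):g$ant_wall_cols[2]
      } else {
        (g$post_wall_cols[1] + 1):g$post_wall_cols[2]
      }
      calc[rr, cc] <- 1L
      img[rr, cc] <- ip$calcification
    }
  }

  if (ip$noise_sd > 0) img <- img + rng$norm(h * w, sd = ip$noise_sd)
  contrast <- if (is.null(ip$contrast)) 1 else ip$contrast
  brightness <- if (is.null(ip$brightness)) 0 else ip$brightness
  img <- (img - 0.5) * contrast + 0.5 + brightness
  img <- pmin(pmax(img, 0), 1)

  grades <- grade_segment(spec$calcified_fractions)
  structure(
    list(image = img,
         vertebra_mask = vertebra_mask(labels,
                                       anterior_side = spec$anterior_side),
         calcification_mask = calc,
         truth = kauppila_score(grades),
         spec = spec, seed = as.integer(seed)),
    class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample: %d x %d image, seed %d, truth total %d (%s)\n",
              nrow(x$image), ncol(x$image), x$seed, x$truth$total,
              x$truth$category))
  invisible(x)
}

#' @export
plot.phantom_sample <- function(x, what = c("image", "masks"), ...) {
  what <- match.arg(what)
  z <- if (what == "image") x$image else
    x$vertebra_mask$labels / 5 + x$calcification_mask
  graphics::image(t(z)[, nrow(z):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(z) / ncol(z), ...)
  invisible(x)
}

# isolated RNG stream so phantom generation never disturbs the caller's RNG
local_rng <- function(seed) {
  state <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  state$rs <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(fun) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", state$rs, globalenv())
      on.exit({
        state$rs <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, globalenv())
      })
      fun(...)
    }
  }
  list(unif = with_state(stats::runif),
       norm = with_state(stats::rnorm),
       int  = with_state(function(n, max) sample.int(max, n, replace = TRUE)))
}

#' Specification of a synthetic phantom cohort
#'
#' The default severity mix mirrors the near-normal severity distribution
#' of a large multicenter AAC training cohort (roughly 22% no/mild, 65%
#' moderate, 13% severe). Photometric heterogeneity emulates acquisition
#' diversity across centers as brightness/contrast/noise strata only.
#'
#' @param n_cases Number of phantoms.
#' @param severity_mix Proportions for (no/mild, moderate, severe); must
#'   sum to 1.
#' @param heterogeneity List of 2-vectors `brightness`, `contrast`,
#'   `noise_sd` giving per-case uniform sampling ranges.
#' @param base_spec Template [phantom_spec()] whose geometry is jittered
#'   per case.
#' @param geometry_jitter Relative jitter applied to vertebra heights,
#'   AP lengths and gaps (uniform in `[1-j, 1+j]`).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases,
                        severity_mix = c(387, 1124, 226) / 1737,
                        heterogeneity = list(brightness = c(-0.05, 0.05),
                                             contrast = c(0.9, 1.1),
                                             noise_sd = c(0.01, 0.03)),
                        base_spec = phantom_spec(),
                        geometry_jitter = 0.12,
                        seed = 1L) {
  if (length(n_cases) != 1 || n_cases < 1 || n_cases != as.integer(n_cases)) {
    stop("n_cases must be a positive integer", call. = FALSE)
  }
  if (length(severity_mix) != 3 || any(severity_mix < 0) ||
      abs(sum(severity_mix) - 1) > 1e-8) {
    stop("severity_mix must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 severity_mix = severity_mix,
                 heterogeneity = heterogeneity,
                 base_spec = validate_phantom_spec(base_spec),
                 geometry_jitter = geometry_jitter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Draw 8 grades with a given total, uniformly over compositions with each
# grade <= 3, via sequential conditional sampling on feasible ranges.
draw_grades_with_total <- function(total, runif_fun) {
  g <- integer(8)
  remaining <- total
  for (i in 1:8) {
    slots_left <- 8 - i
    lo <- max(0L, remaining - 3L * slots_left)
    hi <- min(3L, remaining)
    g[i] <- lo + floor(runif_fun(1) * (hi - lo + 1))
    g[i] <- min(g[i], hi)
    remaining <- remaining - g[i]
  }
  sample_perm <- order(runif_fun(8))
  g[sample_perm]
}

# A fraction drawn uniformly inside the grade's open/closed interval,
# kept away from the 1/3 and 2/3 boundaries by eps for raster robustness.
draw_fraction_for_grade <- function(grade, runif_fun, eps = 0.03) {
  lims <- switch(as.character(grade),
                 "0" = c(0, 0),
                 "1" = c(0.05, 1 / 3 - eps),
                 "2" = c(1 / 3 + eps, 2 / 3 - eps),
                 "3" = c(2 / 3 + eps, 0.97))
  if (grade == 0) 0 else lims[1] + runif_fun(1) * (lims[2] - lims[1])
}

#' Sample a cohort of phantoms
#'
#' Per case: a severity category is drawn from `severity_mix`; a target
#' total score is drawn uniformly within the category's range; eight grades
#' summing to that total are drawn; per-segment fractions are drawn within
#' each grade's interval; geometry is jittered and photometric parameters
#' drawn from the heterogeneity ranges; the phantom is rendered with a
#' per-case derived seed.
#'
#' @param cohort A [cohort_spec()].
#' @return List of [make_phantom()] samples (class `phantom_cohort`).
#' @export
sample_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  rng <- local_rng(cohort$seed)
  ranges <- list(no_mild = c(0L, 4L), moderate = c(5L, 15L),
                 severe = c(16L, 24L))
  out <- vector("list", cohort$n_cases)
  for (i in seq_len(cohort$n_cases)) {
    u <- rng$unif(1)
    cat_i <- findInterval(u, cumsum(cohort$severity_mix)[1:2],
                          left.open = TRUE) + 1L
    rr <- ranges[[cat_i]]
    total <- rr[1] + floor(rng$unif(1) * (rr[2] - rr[1] + 1))
    total <- min(total, rr[2])
    grades <- draw_grades_with_total(total, rng$unif)
    fracs <- vapply(grades, draw_fraction_for_grade, numeric(1),
                    runif_fun = rng$unif)
    b <- cohort$base_spec
    j <- cohort$geometry_jitter
    jit <- function(x, n) round(x * (1 - j + 2 * j * rng$unif(n)))
    spec <- phantom_spec(
      image_height = b$image_height, image_width = b$image_width,
      vertebra_heights = pmax(6, jit(b$vertebra_heights, 5)),
      vertebra_ap_lengths = pmax(12, jit(b$vertebra_ap_lengths, 5)),
      gap_heights = pmax(3, jit(b$gap_heights, 4)),
      top_margin = b$top_margin,
      aorta_offset = b$aorta_offset, aorta_width = b$aorta_width,
      wall_thickness = b$wall_thickness,
      calcified_fractions = fracs,
      intensity_params = list(
        background = b$intensity_params$background,
        bone = b$intensity_params$bone,
        calcification = b$intensity_params$calcification,
        noise_sd = draw_range(cohort$heterogeneity$noise_sd, rng$unif),
        brightness = draw_range(cohort$heterogeneity$brightness, rng$unif),
        contrast = draw_range(cohort$heterogeneity$contrast, rng$unif)),
      anterior_side = b$anterior_side,
      random_strip_position = b$random_strip_position)
    case_seed <- floor(rng$unif(1) * 2^30)
    out[[i]] <- make_phantom(spec, seed = case_seed)
    out[[i]]$id <- sprintf("case_%04d", i)
  }
  # re-check total landed in the drawn category (construction guarantees it)
  structure(out, class = "phantom_cohort")
}

draw_range <- function(range, runif_fun) {
  range[1] + runif_fun(1) * (range[2] - range[1])
}

#' @export
print.phantom_cohort <- function(x, ...) {
  totals <- vapply(x, function(s) s$truth$total, numeric(1))
  cat(sprintf("phantom_cohort: %d cases, total score %d-%d (median %g)\n",
              length(x), min(totals), max(totals), stats::median(totals)))
  print(table(category = vapply(x, function(s) s$truth$category,
                                character(1))))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Images are written as 16-bit grayscale TIFF, vertebra and calcification
#' masks as 8-bit label PNG, and the ground truth as a single CSV manifest
#' with columns `id, g_L1a..g_L4p, total, category, seed`.
#'
#' @param samples List of `phantom_sample` objects.
#' @param directory Output directory (created if needed).
#' @return The manifest `data.frame`, invisibly written to
#'   `manifest.csv`.
#' @export
write_dataset <- function(samples, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) {
    stop("cannot create directory ", directory, call. = FALSE)
  }
  rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    id <- if (!is.null(s$id)) s$id else sprintf("case_%04d", i)
    tiff::writeTIFF(s$image, file.path(directory, paste0(id, ".tif")),
                    bits.per.sample = 16L)
    png::writePNG(s$vertebra_mask$labels / 255,
                  file.path(directory, paste0(id, "_vertebrae.png")))
    png::writePNG(s$calcification_mask / 255,
                  file.path(directory, paste0(id, "_calc.png")))
    d <- as.data.frame(s$truth, id = id)
    d$seed <- s$seed
    rows[[i]] <- d
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 12)),
      c("id", grade_columns(), "total", "category", "seed"))
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' @param directory Dataset directory containing `manifest.csv`.
#' @param load_images Read image/mask files as well (else scores only).
#' @return List with `manifest` (data.frame) and, when `load_images`,
#'   `samples`: a list of lists with `image`, `vertebra_mask`,
#'   `calcification_mask`, `truth`.
#' @export
read_dataset <- function(directory, load_images = TRUE) {
  mf <- file.path(directory, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", directory,
                             call. = FALSE)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  samples <- NULL
  if (load_images && nrow(manifest)) {
    samples <- lapply(seq_len(nrow(manifest)), function(i) {
      id <- manifest$id[i]
      img <- tiff::readTIFF(file.path(directory, paste0(id, ".tif")))
      vm <- round(png::readPNG(
        file.path(directory, paste0(id, "_vertebrae.png"))) * 255)
      cm <- round(png::readPNG(
        file.path(directory, paste0(id, "_calc.png"))) * 255)
      grades <- as.integer(manifest[i, grade_columns()])
      list(id = id, image = img,
           vertebra_mask = vertebra_mask(matrix(as.integer(vm), nrow(vm))),
           calcification_mask = matrix(as.integer(cm), nrow(cm)),
           truth = kauppila_score(grades))
    })
  }
  list(manifest = manifest, samples = samples)
}
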