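#' @useDynLib aacquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The eight Kauppila segments: aortic wall (anterior/posterior) at L1-L4.
# Key order is fixed and used everywhere a grade vector is flattened.
SEGMENT_LEVELS <- c("L1", "L2", "L3", "L4")
SEGMENT_WALLS  <- c("anterior", "posterior")

#' Names of the eight Kauppila aortic segments
#'
#' Returns the canonical key order used for flattened grade vectors:
#' `L1_anterior, L1_posterior, ..., L4_posterior`.
#'
#' @return Character vector of length 8.
#' @export
segment_keys <- function() {
  as.vector(t(outer(SEGMENT_LEVELS, SEGMENT_WALLS, paste, sep = "_")))
}

#' Grade one aortic wall segment from its calcified length fraction
#'
#' Applies the Kauppila AAC-24 per-segment grading rule to the fraction of
#' the segment's craniocaudal length that shows calcification:
#' 0 points for no detectable calcification; 1 point when the calcified
#' length is less than 1/3 of the segment; 2 points when it is at least 1/3
#' but at most 2/3; 3 points when it exceeds 2/3.
#'
#' @param calcified_fraction Numeric vector of fractions in `[0, 1]`.
#' @return Integer vector of grades in `{0, 1, 2, 3}`.
#' @examples
#' grade_segment(c(0, 0.2, 0.5, 0.8))
#' @export
grade_segment <- function(calcified_fraction) {
  f <- calcified_fraction
  if (!is.numeric(f) || anyNA(f)) {
    stop("calcified_fraction must be numeric without NA", call. = FALSE)
  }
  if (any(f < 0 | f > 1)) {
    stop("calcified_fraction must lie in [0, 1]; got ",
         paste(format(f[f < 0 | f > 1]), collapse = ", "), call. = FALSE)
  }
  g <- integer(length(f))
  g[f > 0]       <- 1L
  g[f >= 1 / 3]  <- 2L
  g[f > 2 / 3]   <- 3L
  g
}

#' Total Kauppila score from eight per-segment grades
#'
#' @param grades Numeric/integer vector or named list of the 8 per-segment
#'   grades (order of [segment_keys()] when unnamed), each in `{0,1,2,3}`.
#' @return Integer total in `[0, 24]`.
#' @export
total_score <- function(grades) {
  g <- unlist(grades, use.names = TRUE)
  if (!is.null(names(g)) && all(nzchar(names(g)))) {
    missing <- setdiff(segment_keys(), names(g))
    if (length(missing)) {
      stop("missing segment grade(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    g <- g[segment_keys()]
  }
  if (length(g) != 8L) {
    stop("expected 8 segment grades, got ", length(g), call. = FALSE)
  }
  if (anyNA(g) || any(g != as.integer(g)) || any(g < 0 | g > 3)) {
    stop("grades must be integers in {0, 1, 2, 3}", call. = FALSE)
  }
  as.integer(sum(g))
}

#' Severity category for a total AAC-24 score
#'
#' Totals 0-4 are classed as no/mild AAC, 5-15 as moderate AAC and 16-24 as
#' severe AAC.
#'
#' @param total Integer vector of total scores in `[0, 24]`.
#' @return Factor with levels `no_mild`, `moderate`, `severe`.
#' @export
classify_severity <- function(total) {
  if (anyNA(total) || any(total != as.integer(total)) ||
      any(total < 0 | total > 24)) {
    stop("total must be an integer in [0, 24]", call. = FALSE)
  }
  cut(as.integer(total), breaks = c(-1L, 4L, 15L, 24L),
      labels = c("no_mild", "moderate", "severe"))
}

severity_levels <- function() c("no_mild", "moderate", "severe")

#' Construct a Kauppila score record
#'
#' @param grades The 8 per-segment grades (see [total_score()]).
#' @return An object of class `kauppila_score`: list with `grades` (named
#'   integer vector in [segment_keys()] order), `total`, and `category`.
#' @export
kauppila_score <- function(grades) {
  g <- unlist(grades)
  total <- total_score(g)
  g <- as.integer(g)
  names(g) <- segment_keys()
  structure(
    list(grades = g, total = total,
         category = as.character(classify_severity(total))),
    class = "kauppila_score")
}

#' @export
print.kauppila_score <- function(x, ...) {
  cat("Kauppila AAC-24 score\n")
  m <- matrix(x$grades, nrow = 2,
              dimnames = list(SEGMENT_WALLS, SEGMENT_LEVELS))
  print(m)
  cat(sprintf("total: %d  category: %s\n", x$total, x$category))
  invisible(x)
}

#' @export
as.data.frame.kauppila_score <- function(x, ..., id = NA_character_) {
  d <- as.data.frame(as.list(x$grades))
  names(d) <- grade_columns()
  cbind(data.frame(id = id, stringsAsFactors = FALSE), d,
        data.frame(total = x$total, category = x$category,
                   stringsAsFactors = FALSE))
}

# manifest column names for the 8 grades: g_L1a, g_L1p, ..., g_L4p
grade_columns <- function() {
  paste0("g_", rep(SEGMENT_LEVELS, each = 2), c("a", "p"))
}

#' Craniocaudal row spans of the four Kauppila segments
#'
#' Derives, from a vertebra label mask, the half-open row interval spanned
#' by each aortic segment L1-L4. Segment boundaries sit at the row midpoints
#' of adjacent intervertebral spaces: the L1 segment starts at L1's superior
#' extent; for L1-L3 the inferior boundary is the midpoint between that
#' vertebra's inferior extent and the next vertebra's superior extent; the
#' L4 segment ends at the midpoint of the L4-L5 gap.
#'
#' @param mask A `vertebra_mask` (see [vertebra_mask()]) or an integer
#'   matrix with labels 0 (background) and 1..5 for L1..L5.
#' @return An object of class `segment_spans`: list with `spans`, a 4 x 2
#'   integer matrix of half-open `[start, end)` rows (0-based) with rownames
#'   L1..L4, and `vertebra_rows`, the 5 x 2 matrix of vertebral extents.
#' @export
segment_spans <- function(mask) {
  labels <- mask_labels(mask)
  problems <- character(0)
  ext <- matrix(NA_integer_, 5, 2,
                dimnames = list(paste0("L", 1:5), c("start", "end")))
  for (v in 1:5) {
    rows <- which(apply(labels == v, 1, any))
    if (!length(rows)) {
      problems <- c(problems, sprintf("missing L%d", v))
      next
    }
    comp <- label_components(labels == v)
    if (comp > 1L) {
      problems <- c(problems,
                    sprintf("L%d split into %d components", v, comp))
    }
    ext[v, ] <- c(min(rows) - 1L, max(rows))  # half-open, 0-based
  }
  if (!length(problems)) {
    for (v in 1:4) {
      if (ext[v, "end"] > ext[v + 1, "start"]) {
        problems <- c(problems,
                      sprintf("L%d not superior to L%d", v, v + 1))
      }
    }
  }
  if (length(problems)) {
    stop("invalid vertebra mask: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  # midpoints of the intervertebral gaps (round toward the superior side)
  mids <- integer(4)
  for (v in 1:4) mids[v] <- (ext[v, "end"] + ext[v + 1, "start"]) %/% 2L
  spans <- cbind(start = c(ext[1, "start"], mids[1:3]), end = mids)
  rownames(spans) <- SEGMENT_LEVELS
  structure(list(spans = spans, vertebra_rows = ext),
            class = "segment_spans")
}

#' @export
print.segment_spans <- function(x, ...) {
  cat("Kauppila segment row spans (half-open, 0-based):\n")
  print(x$spans)
  invisible(x)
}

# count 4-connected components of a logical matrix
label_components <- function(bw) {
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  as.integer(max(EBImage::imageData(lab)))
}

mask_labels <- function(mask) {
  if (inherits(mask, "vertebra_mask")) mask$labels else {
    if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
    mask
  }
}

mask_anterior_side <- function(mask, default = "left") {
  if (inherits(mask, "vertebra_mask")) mask$anterior_side else default
}

#' Score a radiograph automatically from calcification and vertebra masks
#'
#' Reference ("oracle") scorer: given a binary calcification mask and a
#' vertebra label mask, applies the Kauppila rules exactly. Calcified
#' pixels are split between the anterior and posterior aortic walls by a
#' vertical midline through the aortic band; for each (level, wall) the
#' calcified fraction is the number of distinct rows within the segment
#' span containing assigned pixels, divided by the span length.
#'
#' @param calc_mask Logical/0-1 matrix of calcified pixels.
#' @param mask `vertebra_mask` or label matrix (see [segment_spans()]).
#' @param anterior_side `"left"` or `"right"`: which image side (low or
#'   high column indices) is the patient's front. Defaults to the mask's
#'   own annotation when available.
#' @param midline Optional explicit aortic-band midline (0-based column,
#'   pixels strictly on the anterior side of it are assigned to the
#'   anterior wall). By default it is estimated as the midpoint of the
#'   calcification-bearing column range.
#' @return A [kauppila_score()] object.
#' @export
score_from_masks <- function(calc_mask, mask,
                             anterior_side = mask_anterior_side(mask),
                             midline = NULL) {
  labels <- mask_labels(mask)
  calc <- calc_mask != 0
  if (!identical(dim(calc), dim(labels))) {
    stop("calc_mask and vertebra mask differ in shape", call. = FALSE)
  }
  anterior_side <- match.arg(anterior_side, c("left", "right"))
  sp <- segment_spans(mask)

  if (!any(calc)) {
    return(kauppila_score(rep(0L, 8)))
  }
  idx <- which(calc, arr.ind = TRUE)
  rows0 <- idx[, 1] - 1L   # 0-based
  cols0 <- idx[, 2] - 1L
  if (is.null(midline)) midline <- (min(cols0) + max(cols0)) / 2
  # anterior pixels sit strictly on the patient's front side of the midline
  is_ant <- if (anterior_side == "left") cols0 < midline else cols0 > midline

  grades <- integer(8)
  k <- 0L
  for (lev in 1:4) {
    span <- sp$spans[lev, ]
    len <- span["end"] - span["start"]
    in_span <- rows0 >= span["start"] & rows0 < span["end"]
    for (ant in c(TRUE, FALSE)) {
      k <- k + 1L
      covered <- unique(rows0[in_span & (is_ant == ant)])
      grades[k] <- grade_segment(length(covered) / len)
    }
  }
  kauppila_score(grades)
}
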