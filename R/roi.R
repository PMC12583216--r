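# Anatomy-driven region-of-interest extraction: crop geometry anchored on
# the vertebra mask, Z-score normalisation, and resizing to the regressor
# input size.

#' Compute the anatomical crop box for the scoring regressor
#'
#' The vertical span runs from the estimated inferior border of T12 to the
#' inferior border of L5. T12 itself is unlabelled, so its inferior border
#' is estimated as L1's superior extent minus `t12_gap_fraction` times the
#' mean inter-vertebral gap (the T12-L1 gap resembles the lumbar gaps).
#' The horizontal span covers all vertebrae and extends anteriorly by
#' `anterior_extension` times the mean anteroposterior vertebral length to
#' include the pre-vertebral soft tissue carrying the aorta. All bounds
#' are clamped to the image.
#'
#' @param mask A [vertebra_mask()].
#' @param image_dim Image dimensions `(rows, cols)`; defaults to the mask
#'   shape.
#' @param anterior_extension Anterior soft-tissue extension as a fraction
#'   of the mean AP vertebral length (default 3/4).
#' @param t12_gap_fraction Fraction of the mean inter-vertebral gap used
#'   for the T12 inferior-border estimate (default 1/2).
#' @return Object of class `crop_box`: list with 0-based half-open
#'   `row_start, row_end, col_start, col_end`.
#' @export
compute_crop_box <- function(mask, image_dim = dim(mask_labels(mask)),
                             anterior_extension = 0.75,
                             t12_gap_fraction = 0.5) {
  cov <- check_roi_coverage(mask)
  if (!cov$pass) {
    stop(paste0("mask fails ROI coverage: ",
                paste(cov$reasons, collapse = "; ")),
         call. = FALSE)
  }
  labels <- mask_labels(mask)
  side <- mask_anterior_side(mask)
  rows <- matrix(NA_integer_, 5, 2)   # 0-based half-open extents
  cols <- matrix(NA_integer_, 5, 2)
  for (v in 1:5) {
    sel <- which(labels == v, arr.ind = TRUE)
    rows[v, ] <- c(min(sel[, 1]) - 1L, max(sel[, 1]))
    cols[v, ] <- c(min(sel[, 2]) - 1L, max(sel[, 2]))
  }
  gaps <- rows[2:5, 1] - rows[1:4, 2]
  mean_gap <- mean(gaps)
  mean_ap <- mean(cols[, 2] - cols[, 1])

  row_start <- rows[1, 1] - round(t12_gap_fraction * mean_gap)
  row_end <- rows[5, 2]
  ext <- round(anterior_extension * mean_ap)
  if (side == "left") {
    col_start <- min(cols[, 1]) - ext
    col_end <- max(cols[, 2])
  } else {
    col_start <- min(cols[, 1])
    col_end <- max(cols[, 2]) + ext
  }
  crop_box(max(0L, row_start), min(image_dim[1], row_end),
           max(0L, col_start), min(image_dim[2], col_end))
}

#' Construct a crop box
#'
#' @param row_start,row_end,col_start,col_end 0-based half-open pixel
#'   bounds.
#' @return Object of class `crop_box`.
#' @export
crop_box <- function(row_start, row_end, col_start, col_end) {
  b <- list(row_start = as.integer(row_start),
            row_end = as.integer(row_end),
            col_start = as.integer(col_start),
            col_end = as.integer(col_end))
  if (b$row_start >= b$row_end || b$col_start >= b$col_end) {
    stop("degenerate crop box", call. = FALSE)
  }
  structure(b, class = "crop_box")
}

#' @export
print.crop_box <- function(x, ...) {
  cat(sprintf("crop_box rows [%d,%d) cols [%d,%d)\n",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

#' Extract the normalised, resized regressor input patch
#'
#' Crops the image to `box`, Z-score normalises the crop (a zero-variance
#' crop maps to all zeros), then resizes to the target shape with bilinear
#' interpolation. Normalisation precedes resizing; the record of the
#' method travels with the patch.
#'
#' @param image Numeric matrix.
#' @param box A [crop_box()] (clamped to the image).
#' @param target Output shape `(rows, cols)`; the radiograph-scale default
#'   is 1000 x 500, the desk-scale phantoms use 250 x 125.
#' @param id Optional provenance identifier.
#' @return Object of class `aac_patch`: list with `pixels`,
#'   `normalization` and `provenance`.
#' @export
extract_patch <- function(image, box, target = c(1000L, 500L), id = NULL) {
  rs <- max(0L, box$row_start); re <- min(nrow(image), box$row_end)
  cs <- max(0L, box$col_start); ce <- min(ncol(image), box$col_end)
  if (rs >= re || cs >= ce) stop("crop box empty after clamping",
                                 call. = FALSE)
  crop <- image[(rs + 1):re, (cs + 1):ce, drop = FALSE]
  mu <- mean(crop)
  s <- stats::sd(crop)
  z <- if (is.na(s) || s == 0) crop * 0 else (crop - mu) / s
  resized <- EBImage::imageData(
    EBImage::resize(EBImage::Image(z), w = target[1], h = target[2],
                    filter = "bilinear", antialias = FALSE))
  structure(list(
    pixels = matrix(resized, target[1], target[2]),
    normalization = list(method = "zscore_before_resize", mean = mu,
                         sd = s, resize = "bilinear"),
    provenance = list(id = id, box = crop_box(rs, re, cs, ce))),
    class = "aac_patch")
}

#' @export
print.aac_patch <- function(x, ...) {
  cat(sprintf("aac_patch %d x %d (%s), source rows [%d,%d) cols [%d,%d)\n",
              nrow(x$pixels), ncol(x$pixels), x$normalization$method,
              x$provenance$box$row_start, x$provenance$box$row_end,
              x$provenance$box$col_start, x$provenance$box$col_end))
  invisible(x)
}

# Map a pixel mask through the same crop + resize as its patch, returning
# a binary mask aligned with the patch (used by the explanation module).
warp_mask_to_patch <- function(mask, box, target) {
  rs <- max(0L, box$row_start); re <- min(nrow(mask), box$row_end)
  cs <- max(0L, box$col_start); ce <- min(ncol(mask), box$col_end)
  crop <- (mask[(rs + 1):re, (cs + 1):ce, drop = FALSE] != 0) * 1
  resized <- EBImage::imageData(
    EBImage::resize(EBImage::Image(crop), w = target[1], h = target[2],
                    filter = "bilinear", antialias = FALSE))
  matrix(resized, target[1], target[2]) > 0.25
}

#' Persist a patch as 32-bit float TIFF with a JSON provenance sidecar
#'
#' @param patch An [aac_patch()].
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_patch <- function(patch, path) {
  stopifnot(inherits(patch, "aac_patch"))
  # TIFF storage is defined on [0, 1]: store affinely rescaled pixels and
  # record the transform in the sidecar
  lo <- min(patch$pixels)
  hi <- max(patch$pixels)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((patch$pixels - lo) / scale, path,
                  bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(normalization = patch$normalization,
                  storage = list(offset = lo, scale = scale),
                  provenance = list(
                    id = patch$provenance$id,
                    box = unclass(patch$provenance$box)),
                  dim = dim(patch$pixels))
  jsonlite::write_json(sidecar, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a patch written by [write_patch()]
#'
#' @param path TIFF path (sidecar expected alongside).
#' @return An [aac_patch()].
#' @export
read_patch <- function(path) {
  px <- tiff::readTIFF(path)
  side <- jsonlite::read_json(sub("\\.[^.]+$", ".json", path),
                              simplifyVector = TRUE)
  box <- do.call(crop_box, as.list(side$provenance$box))
  px <- px * side$storage$scale + side$storage$offset
  structure(list(pixels = matrix(px, nrow(px)),
                 normalization = side$normalization,
                 provenance = list(id = side$provenance$id, box = box)),
            class = "aac_patch")
}
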