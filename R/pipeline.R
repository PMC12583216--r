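# End-to-end orchestration: phantom simulation -> segmentation training
# -> ROI extraction -> regressor training -> evaluation -> explanation,
# with per-stage derived seeds and artifacts on disk.

#' Default pipeline configuration
#'
#' @param output_dir Where artifacts are written.
#' @param n_train,n_val,n_test Cohort sizes.
#' @param seg Segmentation config ([seg_config()]).
#' @param reg Regressor config ([regressor_config()]).
#' @param opt Training config ([train_config()]).
#' @param patch_target Patch shape `(rows, cols)` fed to the regressor;
#'   must equal `reg$input_size`.
#' @param use_predicted_masks Extract ROIs from the segmenter's masks
#'   (with ground-truth fallback when the coverage check fails) rather
#'   than from ground truth.
#' @param eval_bootstrap_B Bootstrap replicates in the final report.
#' @param seed Global seed; all stage seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("aacquant_run_"),
                       n_train = 60L, n_val = 20L, n_test = 20L,
                       seg = seg_config(),
                       reg = regressor_config(),
                       opt = train_config(max_epochs = 40L,
                                          warmup_iters = 40L,
                                          batch_size = 16L,
                                          val_check_every = 5L,
                                          patience = 3L),
                       patch_target = reg$input_size,
                       use_predicted_masks = TRUE,
                       eval_bootstrap_B = 200L,
                       seed = 1L) {
  if (n_train < 1) stop("n_train must be >= 1", call. = FALSE)
  if (n_val < 1 || n_test < 1) stop("n_val and n_test must be >= 1",
                                    call. = FALSE)
  if (!identical(as.integer(patch_target), reg$input_size)) {
    stop("patch_target must match reg$input_size", call. = FALSE)
  }
  structure(list(output_dir = output_dir, n_train = as.integer(n_train),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 seg = seg, reg = reg, opt = opt,
                 patch_target = as.integer(patch_target),
                 use_predicted_masks = isTRUE(use_predicted_masks),
                 eval_bootstrap_B = as.integer(eval_bootstrap_B),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `seg`,
#' `reg` and `opt` maps mirror [seg_config()], [regressor_config()] and
#' [train_config()].
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("seg", "reg", "opt", "augment"))]
  if (!is.null(y$seg)) args$seg <- do.call(seg_config, y$seg)
  if (!is.null(y$reg)) args$reg <- do.call(regressor_config, y$reg)
  if (!is.null(y$opt)) {
    opt <- y$opt
    if (!is.null(y$augment)) opt$augment <- do.call(augment_config,
                                                    y$augment)
    args$opt <- do.call(train_config, opt)
  }
  do.call(run_config, args)
}

stage_seed <- function(seed, stage) {
  (seed * 131L + stage * 9973L) %% 2147483647L
}

#' Run the full phantom-to-report pipeline
#'
#' Stages, in fixed order: (1) simulate train/val/test phantom cohorts;
#' (2) train the vertebra segmenter; (3) extract score-regression patches
#' through the anatomical crop (predicted masks with QC fallback, or
#' ground truth); (4) train the score regressor; (5) evaluate predictions
#' on the test set; (6) produce a gradient-weighted activation heatmap
#' for one test case. Every stage's seed derives from the global seed and
#' artifacts are written under `config$output_dir`.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Object of class `pipeline_result`: the `eval_report`, trained
#'   models, the test-set [paired_scores()], heatmap focus fraction, and
#'   stage metadata.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("stage 1/6: simulating %d + %d + %d phantoms",
      config$n_train, config$n_val, config$n_test)
  cohorts <- stage("simulate", {
    mk <- function(n, s) sample_cohort(cohort_spec(n, seed = s))
    list(train = mk(config$n_train, stage_seed(config$seed, 1L)),
         val = mk(config$n_val, stage_seed(config$seed, 2L)),
         test = mk(config$n_test, stage_seed(config$seed, 3L)))
  })
  manifest <- stage("simulate", {
    write_dataset(cohorts$test, file.path(config$output_dir, "test_set"))
  })

  say("stage 2/6: training segmenter on %d phantoms", config$n_train)
  seg_cfg <- config$seg
  seg_cfg$seed <- stage_seed(config$seed, 4L)
  seg_model <- stage("train-seg",
                     train_segmenter(cohorts$train, seg_cfg))

  say("stage 3/6: extracting patches")
  extract <- function(samples) {
    out <- list(patches = list(), scores = numeric(0), ids = character(0),
                fallbacks = 0L)
    for (s in samples) {
      mask <- s$vertebra_mask
      if (config$use_predicted_masks) {
        pm <- segment_vertebrae(seg_model, s$image,
                                anterior_side = mask$anterior_side)
        if (check_roi_coverage(pm)$pass) mask <- pm else
          out$fallbacks <- out$fallbacks + 1L
      }
      box <- compute_crop_box(mask)
      p <- extract_patch(s$image, box, target = config$patch_target,
                         id = s$id)
      out$patches[[length(out$patches) + 1L]] <- p
      out$scores <- c(out$scores, s$truth$total)
      out$ids <- c(out$ids, if (is.null(s$id)) NA_character_ else s$id)
    }
    out
  }
  sets <- stage("extract-roi", lapply(cohorts, extract))

  say("stage 4/6: training regressor on %d patches",
      length(sets$train$patches))
  opt <- config$opt
  opt$seed <- stage_seed(config$seed, 5L)
  reg_model <- stage("train-reg", {
    rc <- config$reg
    rc$seed <- stage_seed(config$seed, 6L)
    train_regressor(sets$train, sets$val, rc, opt)
  })

  say("stage 5/6: evaluating on %d test cases", config$n_test)
  report <- stage("evaluate", {
    preds <- predict(reg_model, sets$test$patches)
    p <- paired_scores(sets$test$scores, preds, sets$test$ids)
    evaluate_scores(p, bootstrap_B = config$eval_bootstrap_B,
                    seed = stage_seed(config$seed, 7L))
  })
  write_eval_report(report, file.path(config$output_dir, "report.json"))
  write_eval_report(report, file.path(config$output_dir, "report.md"))

  say("stage 6/6: explanation heatmap")
  explain <- stage("explain", {
    i <- which.max(sets$test$scores)
    h <- grad_cam(reg_model, sets$test$patches[[i]])
    s <- cohorts$test[[i]]
    wm <- warp_mask_to_patch(s$calcification_mask,
                             sets$test$patches[[i]]$provenance$box,
                             config$patch_target)
    ff <- if (any(wm)) focus_fraction(h, wm, dilate_radius = 3) else
      NA_real_
    write_overlay(sets$test$patches[[i]], h,
                  file.path(config$output_dir, "heatmap_overlay.png"))
    list(heatmap = h, focus_fraction = ff, case = i)
  })

  preds <- predict(reg_model, sets$test$patches)
  structure(list(
    report = report,
    paired = paired_scores(sets$test$scores, preds, sets$test$ids),
    seg_model = seg_model, reg_model = reg_model,
    focus_fraction = explain$focus_fraction,
    roi_fallbacks = vapply(sets, `[[`, integer(1), "fallbacks"),
    manifest = manifest, output_dir = config$output_dir,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    config = config),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (%.0f s, artifacts in %s)\n", x$elapsed,
              x$output_dir))
  print(x$report)
  cat(sprintf("heatmap focus fraction: %.2f\n", x$focus_fraction))
  invisible(x)
}

#' Score a single radiograph with trained models
#'
#' @param image Numeric matrix (grayscale radiograph).
#' @param seg_model Trained `seg_model`.
#' @param reg_model Trained `aac_net`.
#' @param anterior_side Patient's front side in the image.
#' @return List with `score` (clamped), `category`, `mask`, `box`.
#' @export
score_image <- function(image, seg_model, reg_model,
                        anterior_side = "left") {
  mask <- segment_vertebrae(seg_model, image,
                            anterior_side = anterior_side)
  cov <- check_roi_coverage(mask)
  if (!cov$pass) {
    stop("segmentation failed coverage QC: ",
         paste(cov$reasons, collapse = "; "), call. = FALSE)
  }
  box <- compute_crop_box(mask)
  patch <- extract_patch(image, box,
                         target = reg_model$config$input_size)
  raw <- predict_score(reg_model, patch, "raw")
  clamped <- min(24, max(0, raw))
  list(score = clamped,
       category = as.character(classify_severity(round(clamped))),
       raw = raw, mask = mask, box = box)
}

#' Save a trained model with a JSON configuration sidecar
#'
#' Serialises a `seg_model` or `aac_net` as RDS and writes its
#' configuration next to it as JSON for inspection without loading R
#' objects.
#'
#' @param model A `seg_model` or `aac_net`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model") || inherits(model, "aac_net"))
  saveRDS(model, path)
  cfg <- if (inherits(model, "seg_model")) model$config else model$config
  jsonlite::write_json(unclass(cfg), sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path The `.rds` path.
#' @return The model object.
#' @export
load_model <- function(path) readRDS(path)
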