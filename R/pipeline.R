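#' Configuration for an end-to-end experiment run
#'
#' Bundles every knob of the full strategy — phantom cohort, fold protocol,
#' Bayesian-optimisation budget, arms (with / without correction design
#' variables), backbone sizes, preprocessing — with a single master seed,
#' so that re-running a config reproduces all outputs bit-for-bit with the
#' reference backends.
#'
#' @param tasks subset of `c("detection", "segmentation")`.
#' @param phantom a [phantom_params()] object describing the cohort.
#' @param n_patients cohort size.
#' @param k fold count for patient-level cross-validation.
#' @param folds_to_run which test folds to execute (default 1; `seq_len(k)`
#'   for the full protocol).
#' @param arms experiment arms: `"cdv"` optimises hyperparameters plus the
#'   correction design variables; `"baseline"` optimises hyperparameters
#'   only, with the augmentation ratio pinned at the raw class ratio (no
#'   augmentation) and class weights pinned at their minima.
#' @param baseline_mode `"pinned"` (baseline runs the same BO over
#'   hyperparameters) or `"none"` (fixed mid-range design, no BO).
#' @param budget,n_init BO evaluation budget and initial design count.
#' @param detector_input_size,detector_channels,segmenter_input_size,segmenter_channels
#'   reference-backbone geometry.
#' @param seg_factor segmentation augmentation multiple (default 4).
#' @param inner_val_fraction fraction of training-fold patients held out as
#'   the BO validation split (test folds never influence design selection).
#' @param window,stretch,angle_range preprocessing / augmentation settings.
#' @param objective_cap cap recorded for failed or degenerate objectives.
#' @param seed master seed.
#' @return a `run_config` object (a list).
#' @export
run_config <- function(tasks = c("detection", "segmentation"),
                       phantom = phantom_params(),
                       n_patients = 40L,
                       k = 5L,
                       folds_to_run = 1L,
                       arms = c("cdv", "baseline"),
                       baseline_mode = c("pinned", "none"),
                       budget = 20L,
                       n_init = 8L,
                       detector_input_size = 16L,
                       detector_channels = 4L,
                       segmenter_input_size = 32L,
                       segmenter_channels = 4L,
                       seg_factor = 4L,
                       inner_val_fraction = 0.25,
                       window = c(-190, 150),
                       stretch = c(1, 99),
                       angle_range = 15,
                       objective_cap = 1e6,
                       seed = 1L) {
  baseline_mode <- match.arg(baseline_mode)
  tasks <- match.arg(tasks, several.ok = TRUE)
  stopifnot(inherits(phantom, "phantom_params"))
  if (!all(arms %in% c("cdv", "baseline"))) stop("unknown arm")
  structure(list(tasks = tasks, phantom = phantom,
                 n_patients = as.integer(n_patients), k = as.integer(k),
                 folds_to_run = as.integer(folds_to_run), arms = arms,
                 baseline_mode = baseline_mode,
                 budget = as.integer(budget), n_init = as.integer(n_init),
                 detector_input_size = as.integer(detector_input_size),
                 detector_channels = as.integer(detector_channels),
                 segmenter_input_size = as.integer(segmenter_input_size),
                 segmenter_channels = as.integer(segmenter_channels),
                 seg_factor = as.integer(seg_factor),
                 inner_val_fraction = inner_val_fraction,
                 window = window, stretch = stretch,
                 angle_range = angle_range,
                 objective_cap = objective_cap, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config()]; keys under `phantom` are passed to [phantom_params()].
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom)) y$phantom <- do.call(phantom_params, y$phantom)
  do.call(run_config, y)
}

.combo_seed <- function(master, task, fold, arm = "shared", extra = 0L) {
  ti <- match(task, c("detection", "segmentation", "cohort", "folds"))
  ai <- match(arm, c("cdv", "baseline", "shared"))
  as.integer((as.numeric(master) + 7919 * ti + 104729 * fold +
                1299709 * ai + 15485863 * extra) %%
               (.Machine$integer.max - 2)) + 1L
}

# index of the true L3 slice nearest to a prediction (ties -> lower index)
nearest_l3_index <- function(volume, predicted_index) {
  flagged <- which(volume$l3_flags)
  flagged[which.min(abs(flagged - predicted_index))]
}

.det_pixel_argmax <- function(probs) as.integer(probs[, 2] > probs[, 1])

.seg_argmax <- function(prob_array_n) {
  S <- dim(prob_array_n)[1]; K <- dim(prob_array_n)[3]
  pm <- matrix(prob_array_n, S * S, K)
  matrix(max.col(pm, ties.method = "first") - 1L, S, S)
}

# --- detection arm ---------------------------------------------------------

.run_detection_arm <- function(cohort, folds, fold, arm, cfg, out_dir) {
  train_ids <- fold_patients(folds, fold, test = FALSE)
  test_ids <- fold_patients(folds, fold, test = TRUE)
  split_seed <- .combo_seed(cfg$seed, "detection", fold)
  n_val <- max(1L, round(cfg$inner_val_fraction * length(train_ids)))
  val_ids <- with_seed(split_seed, sample(train_ids, n_val))
  inner_ids <- setdiff(train_ids, val_ids)

  trainer <- reference_detector(cfg$detector_input_size,
                                cfg$detector_channels)
  counts <- detection_class_counts(cohort, inner_ids)
  freq <- c(counts[["n_majority"]], counts[["n_minority"]]) / sum(counts)
  use_cdv <- arm == "cdv"
  space <- default_design_space("detection", include_cdv = use_cdv,
                                class_frequencies = freq)
  val_set <- build_detection_dataset(cohort, val_ids,
                                     input_size = cfg$detector_input_size,
                                     window = cfg$window,
                                     stretch = cfg$stretch)
  arm_seed <- .combo_seed(cfg$seed, "detection", fold, arm)
  eval_seeds <- derive_seeds(arm_seed, cfg$budget + 2L)
  eval_no <- 0L

  fit_for <- function(design, ids, cts, fit_seed) {
    plan <- NULL
    d_c <- NULL
    if (use_cdv) {
      plan <- make_augmentation_plan(cts[["n_minority"]],
                                     cts[["n_majority"]],
                                     design$d_a, seed = fit_seed)
      d_c <- c(design$d_c_0, design$d_c_1)
    }
    f <- c(cts[["n_majority"]], cts[["n_minority"]]) / sum(cts)
    weights <- compute_class_weights(f, d_c, task = "detection")
    ds <- build_detection_dataset(cohort, ids, plan,
                                  input_size = cfg$detector_input_size,
                                  window = cfg$window, stretch = cfg$stretch,
                                  angle_range = cfg$angle_range)
    trainer$fit(ds$images, ds$labels, design, weights, seed = fit_seed)
  }

  objective <- function(design) {
    eval_no <<- eval_no + 1L
    handle <- fit_for(design, inner_ids, counts, eval_seeds[eval_no])
    probs <- trainer$predict(handle, val_set$images)
    cc <- confusion(.det_pixel_argmax(probs), val_set$labels, 2)
    objective_from_counts(cc, classes = 1L, cap = cfg$objective_cap)
  }

  if (arm == "baseline" && cfg$baseline_mode == "none") {
    best_design <- midrange_design()
    bo <- NULL
  } else {
    bo <- bo_optimize(objective, space, budget = cfg$budget,
                      n_init = cfg$n_init, seed = arm_seed,
                      objective_cap = cfg$objective_cap)
    write.csv(bo$history,
              file.path(out_dir, sprintf("detection_fold%d_%s_history.csv",
                                         fold, arm)), row.names = FALSE)
    best_design <- bo$best_design
  }
  jsonlite::write_json(best_design,
                       file.path(out_dir,
                                 sprintf("detection_fold%d_%s_design.json",
                                         fold, arm)),
                       auto_unbox = TRUE, digits = NA)

  final_counts <- detection_class_counts(cohort, train_ids)
  handle <- fit_for(best_design, train_ids, final_counts,
                    eval_seeds[cfg$budget + 1L])

  preds <- lapply(Filter(function(p) p$patient_id %in% test_ids, cohort),
                  function(p) {
    pr <- predict_l3_slice(trainer, handle, p,
                           window = cfg$window, stretch = cfg$stretch)
    true_idx <- nearest_l3_index(p, pr$index)
    data.frame(patient_id = p$patient_id,
               predicted_index = pr$index,
               true_index = true_idx,
               signed_error = slice_error(pr$index, true_idx),
               abs_error = abs_slice_error(pr$index, true_idx),
               stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, c(preds, list(make.row.names = FALSE)))
  write.csv(preds,
            file.path(out_dir, sprintf("detection_fold%d_%s_predictions.csv",
                                       fold, arm)), row.names = FALSE)
  ba <- bland_altman(preds$predicted_index, preds$true_index)
  list(arm = arm, fold = fold, bo = bo, design = best_design,
       predictions = preds,
       mean_abs_error = mean(preds$abs_error),
       sd_abs_error = sd(preds$abs_error),
       bland_altman = ba)
}

# --- segmentation arm ------------------------------------------------------

.run_segmentation_arm <- function(cohort, folds, fold, arm, cfg, out_dir) {
  train_ids <- fold_patients(folds, fold, test = FALSE)
  test_ids <- fold_patients(folds, fold, test = TRUE)
  split_seed <- .combo_seed(cfg$seed, "segmentation", fold)
  n_val <- max(1L, round(cfg$inner_val_fraction * length(train_ids)))
  val_ids <- with_seed(split_seed, sample(train_ids, n_val))
  inner_ids <- setdiff(train_ids, val_ids)

  trainer <- reference_segmenter(cfg$segmenter_input_size,
                                 cfg$segmenter_channels)
  arm_seed <- .combo_seed(cfg$seed, "segmentation", fold, arm)
  eval_seeds <- derive_seeds(arm_seed, cfg$budget + 2L)

  inner_set <- build_segmentation_dataset(
    cohort, inner_ids, factor = cfg$seg_factor,
    seed = .combo_seed(cfg$seed, "segmentation", fold, arm, extra = 1L),
    input_size = cfg$segmenter_input_size,
    window = cfg$window, stretch = cfg$stretch,
    angle_range = cfg$angle_range)
  val_set <- build_segmentation_dataset(
    cohort, val_ids, factor = 1L, seed = 1L,
    input_size = cfg$segmenter_input_size,
    window = cfg$window, stretch = cfg$stretch)
  full_set <- build_segmentation_dataset(
    cohort, train_ids, factor = cfg$seg_factor,
    seed = .combo_seed(cfg$seed, "segmentation", fold, arm, extra = 2L),
    input_size = cfg$segmenter_input_size,
    window = cfg$window, stretch = cfg$stretch,
    angle_range = cfg$angle_range)

  pixel_freq <- function(masks_array) {
    tab <- tabulate(as.integer(masks_array) + 1L, nbins = 5L)
    tab / sum(tab)
  }
  freq <- pixel_freq(inner_set$masks)
  use_cdv <- arm == "cdv"
  space <- default_design_space("segmentation", include_cdv = use_cdv,
                                class_frequencies = freq)
  eval_no <- 0L

  weights_for <- function(design, f) {
    d_c <- if (use_cdv) unlist(design[paste0("d_c_", 0:4)], use.names = FALSE)
           else NULL
    compute_class_weights(f, d_c, task = "segmentation")
  }

  objective <- function(design) {
    eval_no <<- eval_no + 1L
    handle <- trainer$fit(inner_set$images, inner_set$masks, design,
                          weights_for(design, freq), seed = eval_seeds[eval_no])
    probs <- trainer$predict(handle, val_set$images)
    pred <- unlist(lapply(seq_len(dim(probs)[4]), function(n)
      .seg_argmax(probs[, , , n, drop = TRUE])))
    cc <- confusion(pred, as.integer(val_set$masks), 5)
    objective_from_counts(cc, classes = 1:4, average = "macro",
                          cap = cfg$objective_cap)
  }

  if (arm == "baseline" && cfg$baseline_mode == "none") {
    best_design <- midrange_design()
    bo <- NULL
  } else {
    bo <- bo_optimize(objective, space, budget = cfg$budget,
                      n_init = cfg$n_init, seed = arm_seed,
                      objective_cap = cfg$objective_cap)
    write.csv(bo$history,
              file.path(out_dir, sprintf("segmentation_fold%d_%s_history.csv",
                                         fold, arm)), row.names = FALSE)
    best_design <- bo$best_design
  }
  jsonlite::write_json(best_design,
                       file.path(out_dir,
                                 sprintf("segmentation_fold%d_%s_design.json",
                                         fold, arm)),
                       auto_unbox = TRUE, digits = NA)

  full_freq <- pixel_freq(full_set$masks)
  handle <- trainer$fit(full_set$images, full_set$masks, best_design,
                        weights_for(best_design, full_freq),
                        seed = eval_seeds[cfg$budget + 1L])

  # test-fold evaluation: predict, HU-refine, measure
  native <- cfg$phantom$image_size
  spacing <- cfg$phantom$pixel_spacing_mm
  cur <- cfg$segmenter_input_size
  rows <- list(); areas <- list()
  for (p in Filter(function(q) q$patient_id %in% test_ids, cohort)) {
    for (z in which(p$l3_flags)) {
      x <- apply_hu_window(p$slices[[z]], cfg$window[1], cfg$window[2])
      x <- histogram_stretch(x, cfg$stretch[1], cfg$stretch[2])
      img <- resize_image(x, cur)
      probs <- trainer$predict(handle, array(img, dim = c(cur, cur, 1)))
      pred <- .seg_argmax(probs[, , , 1, drop = TRUE])
      pred <- hu_refine(pred, p$slices[[z]])
      truth <- resize_mask(p$masks[[z]], cur)
      sm <- seg_metrics(pred, truth,
                        pixel_spacing_mm = spacing * native / cur,
                        classes = 1:4, n_classes = 5)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(patient_id = p$patient_id, slice_index = z),
        sm$per_class)
      areas[[length(areas) + 1]] <- data.frame(
        patient_id = p$patient_id, slice_index = z, class = 1:4,
        predicted_mm2 = vapply(1:4, function(k)
          tissue_area(pred, k, spacing, native), 0),
        reference_mm2 = vapply(1:4, function(k)
          tissue_area(truth, k, spacing, native), 0))
    }
  }
  per_slice <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  area_df <- do.call(rbind, c(areas, list(make.row.names = FALSE)))
  write.csv(per_slice,
            file.path(out_dir, sprintf("segmentation_fold%d_%s_metrics.csv",
                                       fold, arm)), row.names = FALSE)
  write.csv(area_df,
            file.path(out_dir, sprintf("segmentation_fold%d_%s_areas.csv",
                                       fold, arm)), row.names = FALSE)
  area_r2 <- vapply(1:4, function(k) {
    d <- area_df[area_df$class == k, ]
    if (nrow(d) >= 2 && var(d$reference_mm2) > 0)
      r_squared(d$predicted_mm2, d$reference_mm2) else NA_real_
  }, 0)
  list(arm = arm, fold = fold, bo = bo, design = best_design,
       per_slice = per_slice, areas = area_df,
       macro_dice = mean(per_slice$dice),
       macro_jaccard = mean(per_slice$jaccard),
       area_r2 = area_r2)
}

#' Run the full optimisation-incorporated experiment
#'
#' Generates (or reuses) a phantom cohort, splits it into patient-level
#' folds, and for each requested task / test fold / arm: runs Bayesian
#' optimisation of the design variables on an inner train/validation split
#' of the training folds, trains the final model on the full training
#' folds with the optimal design, predicts the test fold, applies HU
#' post-processing (segmentation), and writes per-slice predictions,
#' metrics, BO histories, designs, the fold table and an aggregate report
#' to the run directory.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created; default a fresh temporary
#'   directory).
#' @param cohort optionally, a pre-generated `ct_cohort` to reuse.
#' @return (invisibly) list with `dir`, `detection` and `segmentation`
#'   results per fold and arm, and `report` (the comparison summary).
#' @export
run_experiment <- function(config, out_dir = tempfile("ctbalance_run_"),
                           cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- config
  cfg_json$phantom <- unclass(config$phantom)
  jsonlite::write_json(unclass(cfg_json), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (is.null(cohort))
    cohort <- generate_cohort(config$phantom, config$n_patients,
                              seed = .combo_seed(config$seed, "cohort", 0L))
  folds <- split_folds(cohort, config$k,
                       seed = .combo_seed(config$seed, "folds", 0L))
  write.csv(as.data.frame(folds), file.path(out_dir, "folds.csv"),
            row.names = FALSE)

  results <- list(detection = list(), segmentation = list())
  for (fold in config$folds_to_run) {
    for (arm in config$arms) {
      if ("detection" %in% config$tasks) {
        key <- sprintf("fold%d_%s", fold, arm)
        results$detection[[key]] <-
          .run_detection_arm(cohort, folds, fold, arm, config, out_dir)
      }
      if ("segmentation" %in% config$tasks) {
        key <- sprintf("fold%d_%s", fold, arm)
        results$segmentation[[key]] <-
          .run_segmentation_arm(cohort, folds, fold, arm, config, out_dir)
      }
    }
  }

  report <- list()
  if ("detection" %in% config$tasks) {
    report$detection <- do.call(rbind, lapply(results$detection, function(r)
      data.frame(fold = r$fold, arm = r$arm,
                 mean_abs_slice_error = r$mean_abs_error,
                 sd_abs_slice_error = r$sd_abs_error,
                 ba_mean_difference = r$bland_altman$mean_difference,
                 ba_fraction_within = r$bland_altman$fraction_within,
                 stringsAsFactors = FALSE)))
    rownames(report$detection) <- NULL
    write.csv(report$detection, file.path(out_dir, "detection_summary.csv"),
              row.names = FALSE)
  }
  if ("segmentation" %in% config$tasks) {
    report$segmentation <- do.call(rbind, lapply(results$segmentation,
                                                 function(r)
      data.frame(fold = r$fold, arm = r$arm,
                 macro_dice = r$macro_dice,
                 macro_jaccard = r$macro_jaccard,
                 stringsAsFactors = FALSE)))
    rownames(report$segmentation) <- NULL
    write.csv(report$segmentation,
              file.path(out_dir, "segmentation_summary.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(dir = out_dir, detection = results$detection,
                 segmentation = results$segmentation, report = report,
                 folds = folds))
}
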