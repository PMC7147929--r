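#' Run the full synthetic STN-localization pipeline
#'
#' Simulate a labelled dataset, extract one feature family, split into
#' training and held-out partitions, fit a classifier, score the held-out
#' epochs and localize the STN borders of the held-out trajectories.
#' Every stage draws its randomness from `seed`, so the run is reproducible
#' end to end.
#'
#' @param n_trajectories Number of simulated trajectories.
#' @param seed Master seed for simulation, split and training.
#' @param family Feature family: `"conventional"`, `"fft"` or `"wavelet"`.
#' @param model Classifier kind (see [fit_stn_classifier()]).
#' @param config A [sim_config()]; its `seed` is overridden by `seed`.
#' @param test_frac Held-out fraction.
#' @param split_mode Partitioning mode (see [split_epochs()]); whole held-out
#'   trajectories are required for border localization, so the default is
#'   `"by_trajectory"`.
#' @param normalize Z-score features per trajectory before fitting (the
#'   post-operative step; sensible for the conventional family only).
#' @param out_dir Optional directory; when given, writes `eval.json`,
#'   `borders.csv`, `cv.csv` (if `cv_folds > 0`), and a `run_config.yaml`
#'   snapshot.
#' @param cv_folds If > 0, additionally run stratified k-fold
#'   cross-validation on the training partition.
#' @param dnn A [dnn_config()] for `model = "dnn"`.
#' @param hyper Hyperparameter list for the classical kinds.
#' @param window Border median-smoothing window.
#' @return An `stn_run` list: `model` (fitted classifier), `eval`
#'   (`stn_eval` on held-out epochs), `predictions`, `borders`
#'   (per-trajectory estimates and errors), `cv` (or `NULL`) and `timing`
#'   (per-epoch prediction latency, seconds).
#' @export
run_stn_pipeline <- function(n_trajectories = 60, seed = 7L,
                             family = "wavelet", model = "dnn",
                             config = sim_config(epoch_s = 1),
                             test_frac = 0.2, split_mode = "by_trajectory",
                             normalize = FALSE, out_dir = NULL,
                             cv_folds = 0, dnn = dnn_config(),
                             hyper = list(), window = 3) {
  epochs <- simulate_dataset(n_trajectories, config, seed = seed)
  feats <- extract_features(epochs, family = family)
  if (normalize) feats <- normalize_by_trajectory(feats)
  parts <- split_epochs(feats, test_frac = test_frac, mode = split_mode,
                        seed = seed)
  fit <- fit_stn_classifier(parts$train, kind = model, seed = seed,
                            hyper = hyper, dnn = dnn)
  t0 <- proc.time()[["elapsed"]]
  pred <- predict(fit, parts$test)
  latency <- (proc.time()[["elapsed"]] - t0) / nrow(parts$test)
  ev <- score_predictions(parts$test$label, pred$.pred_class)
  pred_tbl <- dplyr::bind_cols(
    as_tibble(parts$test)[intersect(c("trajectory_id", "depth_mm", "label",
                                      "true_dorsal_mm", "true_ventral_mm"),
                                    names(parts$test))],
    pred
  )
  borders <- if (split_mode == "by_trajectory") {
    localize_trajectories(pred_tbl, window = window)
  } else {
    NULL
  }
  cv <- if (cv_folds > 0) {
    cross_validate(parts$train, model = model, k = cv_folds, seed = seed,
                   hyper = hyper, dnn = dnn)
  } else {
    NULL
  }
  run <- structure(
    list(model = fit, eval = ev, predictions = pred_tbl, borders = borders,
         cv = cv, timing = latency,
         settings = list(n_trajectories = n_trajectories, seed = seed,
                         family = family, model = model,
                         test_frac = test_frac, split_mode = split_mode,
                         normalize = normalize, window = window,
                         epoch_s = config$epoch_s, fs = config$fs)),
    class = "stn_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(glance(run$eval), file.path(out_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(run$borders)) {
    readr::write_csv(run$borders, file.path(out_dir, "borders.csv"),
                     progress = FALSE)
  }
  if (!is.null(run$cv)) {
    readr::write_csv(as_tibble(run$cv), file.path(out_dir, "cv.csv"),
                     progress = FALSE)
  }
  yaml::write_yaml(run$settings, file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

#' @export
print.stn_run <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<stn_run> %d trajectories | %s features + %s | seed %d\n",
              s$n_trajectories, s$family, s$model, s$seed))
  print(x$eval)
  if (!is.null(x$borders)) {
    ok <- x$borders$found
    cat(sprintf("borders found on %d/%d held-out trajectories; median |dorsal error| %.2f mm, median |ventral error| %.2f mm\n",
                sum(ok), nrow(x$borders),
                median(abs(x$borders$error_dorsal_mm[ok])),
                median(abs(x$borders$error_ventral_mm[ok]))))
  }
  cat(sprintf("per-epoch prediction latency: %.4f s\n", x$timing))
  invisible(x)
}

#' @rdname run_stn_pipeline
#' @param x An `stn_run`.
#' @param ... Unused.
#' @export
glance.stn_run <- function(x, ...) {
  out <- glance(x$eval)
  out$family <- x$settings$family
  out$model <- x$settings$model
  out$seed <- x$settings$seed
  if (!is.null(x$borders)) {
    ok <- x$borders$found
    out$border_found_frac <- mean(ok)
    out$median_abs_dorsal_err_mm <- median(abs(x$borders$error_dorsal_mm[ok]))
    out$median_abs_ventral_err_mm <- median(abs(x$borders$error_ventral_mm[ok]))
  }
  out
}
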