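#' Split epochs into training and test partitions
#'
#' `by_epoch` samples individual epochs (the protocol used for the headline
#' clinical evaluation); `by_trajectory` holds out whole microelectrode
#' tracks, which prevents within-track leakage and keeps held-out
#' trajectories intact for border localization; `by_patient` does the same
#' at the patient level and requires a `patient_id` column.
#'
#' @param data An epoch or feature tibble.
#' @param test_frac Test fraction in (0, 1).
#' @param mode `"by_epoch"`, `"by_trajectory"` or `"by_patient"`.
#' @param seed Split seed.
#' @return List with `train` and `test` tibbles (attributes preserved).
#' @export
split_epochs <- function(data, test_frac = 0.2,
                         mode = c("by_epoch", "by_trajectory", "by_patient"),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (test_frac <= 0 || test_frac >= 1) abort("test_frac must be in (0, 1).")
  n <- nrow(data)
  test_rows <- withr::with_seed(seed, {
    if (mode == "by_epoch") {
      sort(sample.int(n, round(test_frac * n)))
    } else {
      key <- if (mode == "by_trajectory") "trajectory_id" else "patient_id"
      if (is.null(data[[key]])) abort(paste0("column ", key, " required for mode ", mode))
      ids <- unique(data[[key]])
      test_ids <- sample(ids, max(1L, round(test_frac * length(ids))))
      which(data[[key]] %in% test_ids)
    }
  })
  if (length(test_rows) == 0 || length(test_rows) == n) {
    abort("split left an empty partition; adjust test_frac.")
  }
  list(train = keep_feature_attrs(data[-test_rows, ], data),
       test = keep_feature_attrs(data[test_rows, ], data))
}

keep_feature_attrs <- function(x, template) {
  if (inherits(template, "stn_features")) {
    x <- new_stn_features(x, family = attr(template, "family"),
                          normalized = attr(template, "normalized"),
                          feature_names = attr(template, "feature_names"))
  }
  x
}

#' Score predicted labels against the truth
#'
#' Builds the 2x2 confusion matrix (inside STN = positive class) and the
#' derived metrics: accuracy, precision, recall (sensitivity), specificity
#' and false-positive rate `FP / (FP + TN)`. A low false-positive rate is
#' the safety-critical quantity here: a false "inside" call risks placing
#' the electrode outside the nucleus.
#'
#' @param truth,estimate Equal-length 0/1 vectors.
#' @return An `stn_eval` object; `tidy()` gives the confusion matrix in long
#'   form, `glance()` the metrics in one row, and printing shows percentages
#'   to one decimal.
#' @export
score_predictions <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have the same length.")
  }
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  tp <- sum(truth == 1 & estimate == 1)
  tn <- sum(truth == 0 & estimate == 0)
  fp <- sum(truth == 0 & estimate == 1)
  fn <- sum(truth == 1 & estimate == 0)
  n <- length(truth)
  structure(
    list(
      confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                         dimnames = list(predicted = c("0", "1"),
                                         truth = c("0", "1"))),
      n = n,
      accuracy = (tp + tn) / n,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_
    ),
    class = "stn_eval"
  )
}

#' @export
print.stn_eval <- function(x, ...) {
  cat(sprintf("<stn_eval> n = %d epochs\n", x$n))
  print(x$confusion)
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("accuracy %s | precision %s | recall %s | FP rate %s\n",
              pct(x$accuracy), pct(x$precision), pct(x$recall),
              pct(x$fp_rate)))
  invisible(x)
}

#' @rdname score_predictions
#' @param x An `stn_eval` object.
#' @param ... Unused.
#' @export
tidy.stn_eval <- function(x, ...) {
  tibble(
    truth = rep(c(0L, 1L), each = 2),
    predicted = rep(c(0L, 1L), 2),
    count = c(x$confusion["0", "0"], x$confusion["1", "0"],
              x$confusion["0", "1"], x$confusion["1", "1"])
  )
}

#' @rdname score_predictions
#' @export
glance.stn_eval <- function(x, ...) {
  tibble(n = x$n, accuracy = x$accuracy, precision = x$precision,
         recall = x$recall, specificity = x$specificity,
         fp_rate = x$fp_rate)
}

#' Stratified k-fold cross-validation
#'
#' Assigns folds stratified by class so every fold's training part contains
#' both classes, fits the model on each training part and scores it on the
#' held-out fold. The model is given either as a kind string (passed to
#' [fit_stn_classifier()]) or, for oracle/stub experiments, as a
#' `list(fit = function(features), predict = function(model, features))`
#' pair returning 0/1 labels.
#'
#' @param features A labelled `stn_features` tibble.
#' @param model Kind string or fit/predict list.
#' @param k Number of folds (>= 2).
#' @param seed Fold-assignment seed (also passed to kind-based fits).
#' @param ... Extra arguments to [fit_stn_classifier()].
#' @return An `stn_cv` tibble, one row of metrics per fold; mean/SD summary
#'   via `glance()`.
#' @export
cross_validate <- function(features, model = "svm", k = 10, seed = 1L, ...) {
  if (k < 2) abort("k must be >= 2.")
  y <- features$label
  check_training_labels(y, nrow(features))
  folds <- withr::with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  rows <- lapply(seq_len(k), function(fold) {
    tr <- keep_feature_attrs(features[folds != fold, ], features)
    te <- keep_feature_attrs(features[folds == fold, ], features)
    pred <- if (is.character(model)) {
      m <- fit_stn_classifier(tr, kind = model, seed = seed, ...)
      predict(m, te)$.pred_class
    } else {
      m <- model$fit(tr)
      model$predict(m, te)
    }
    ev <- glance(score_predictions(te$label, pred))
    dplyr::bind_cols(tibble(fold = fold), ev)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "folds") <- folds
  class(out) <- unique(c("stn_cv", class(out)))
  out
}

#' @export
glance.stn_cv <- function(x, ...) {
  tibble(
    k = nrow(x),
    mean_accuracy = mean(x$accuracy),
    sd_accuracy = sd(x$accuracy),
    mean_precision = mean(x$precision, na.rm = TRUE),
    mean_fp_rate = mean(x$fp_rate, na.rm = TRUE)
  )
}

# Median-smooth a 0/1 sequence with an odd window, treating positions
# beyond the track ends as 0 (the electrode starts and finishes outside
# the nucleus).
median_smooth_binary <- function(labels, window) {
  if (window < 1 || window %% 2 == 0) abort("smoothing window must be odd and >= 1.")
  if (window == 1) return(as.integer(labels))
  half <- (window - 1) %/% 2
  padded <- c(rep(0L, half), as.integer(labels), rep(0L, half))
  vapply(seq_along(labels), function(i) {
    as.integer(median(padded[i:(i + window - 1)]))
  }, integer(1))
}

#' Locate the dorsal and ventral STN borders from per-depth labels
#'
#' Median-smooths the inside/outside sequence along depth (window default 3
#' epochs, ends padded with "outside") and takes the longest contiguous run
#' of inside calls; the first and last depths of that run are the dorsal and
#' ventral border estimates. Ties between equally long runs go to the
#' shallowest run.
#'
#' @param depths Strictly increasing recording depths, mm.
#' @param labels 0/1 inside calls aligned with `depths`.
#' @param window Odd median-smoothing window (epochs).
#' @return One-row tibble: `found`, `dorsal_mm`, `ventral_mm`.
#' @export
#' @examples
#' localize_borders(-3:2, c(0, 0, 1, 1, 1, 0))
localize_borders <- function(depths, labels, window = 3) {
  if (length(depths) != length(labels)) {
    abort("depths and labels must be aligned.")
  }
  if (is.unsorted(depths, strictly = TRUE)) {
    abort("depths must be strictly increasing.")
  }
  sm <- median_smooth_binary(labels, window)
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ones <- which(r$values == 1)
  if (length(ones) == 0) {
    return(tibble(found = FALSE, dorsal_mm = NA_real_, ventral_mm = NA_real_))
  }
  best <- ones[which.max(r$lengths[ones])]
  tibble(found = TRUE,
         dorsal_mm = depths[starts[best]],
         ventral_mm = depths[ends[best]])
}

#' Border estimates and errors for every trajectory of a prediction table
#'
#' @param predictions Tibble with `trajectory_id`, `depth_mm`, a prediction
#'   column and (optionally) `true_dorsal_mm` / `true_ventral_mm` for error
#'   computation.
#' @param pred_col Name of the 0/1 prediction column.
#' @param window Median-smoothing window passed to [localize_borders()].
#' @return Tibble with one row per trajectory: borders, `found`, and signed
#'   errors (estimate minus truth) where ground truth is available.
#' @export
localize_trajectories <- function(predictions, pred_col = ".pred_class",
                                  window = 3) {
  predictions |>
    dplyr::arrange(.data$trajectory_id, .data$depth_mm) |>
    dplyr::group_by(.data$trajectory_id) |>
    dplyr::group_modify(function(df, key) {
      est <- localize_borders(df$depth_mm, df[[pred_col]], window = window)
      est$true_dorsal_mm <- df$true_dorsal_mm[1] %||% NA_real_
      est$true_ventral_mm <- df$true_ventral_mm[1] %||% NA_real_
      est$error_dorsal_mm <- est$dorsal_mm - est$true_dorsal_mm
      est$error_ventral_mm <- est$ventral_mm - est$true_ventral_mm
      est
    }) |>
    dplyr::ungroup()
}
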