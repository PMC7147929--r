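#' Weighted majority vote
#'
#' Combines member class votes by summing each member's weight into the
#' class it voted for and returning the class with the largest total,
#' `argmax_i sum_j w_j [C_j(x) = i]`. The vote is invariant to positive
#' rescaling of all weights. Ties default to the lowest class label —
#' conservative for this application, where class 0 (outside the STN) is
#' the safe call.
#'
#' @param votes Integer/numeric vector of member votes for one sample, or a
#'   matrix with one column per member (rows = samples).
#' @param weights Non-negative member weights, same length as the vote set.
#' @param classes Candidate class labels; defaults to the sorted unique
#'   votes.
#' @param tie_policy `"lowest"` (default) or `"first"` (first class reaching
#'   the maximum in `classes` order).
#' @return The winning class label (or vector of labels for a vote matrix).
#' @export
#' @examples
#' weighted_majority_vote(c(1, 0, 1), c(0.9, 0.8, 0.6)) # 1
weighted_majority_vote <- function(votes, weights, classes = NULL,
                                   tie_policy = c("lowest", "first")) {
  tie_policy <- match.arg(tie_policy)
  if (is.matrix(votes)) {
    return(apply(votes, 1, weighted_majority_vote, weights = weights,
                 classes = classes, tie_policy = tie_policy))
  }
  if (length(votes) == 0) abort("empty vote set.")
  if (length(votes) != length(weights)) {
    abort("votes and weights must have the same length.")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with a positive sum.")
  }
  if (is.null(classes)) classes <- sort(unique(votes))
  totals <- vapply(classes, function(cl) sum(weights[votes == cl]), 0)
  # class totals that are equal as real numbers can differ in the last bits
  # depending on summation order; treat near-equal totals as tied
  tol <- 1e-9 * max(sum(weights), 1)
  winners <- classes[totals >= max(totals) - tol]
  if (tie_policy == "lowest") min(winners) else winners[1]
}

#' Fit an inside/outside-STN epoch classifier
#'
#' Trains one of the supported classifiers on a feature table with known
#' labels:
#' `"svm"` (RBF support vector machine), `"lr"` (ridge-penalized logistic
#' regression), `"knn"` (k-nearest neighbours), `"dt"` (CART decision tree),
#' `"ensemble"` (weighted majority vote over the four classical members,
#' each weighted by its accuracy on an internal validation split), or
#' `"dnn"` (deep feed-forward network, see [dnn_config()]).
#'
#' SVM, LR and DNN inputs are standardized per feature using statistics of
#' the training data only; KNN and DT operate on the raw features.
#'
#' @param features An `stn_features` tibble whose `label` column is 0/1 with
#'   both classes present.
#' @param kind Classifier kind (see above).
#' @param seed Seed controlling every stochastic step of the fit.
#' @param hyper Named list of hyperparameters: `cost`/`gamma` (svm),
#'   `lambda` (lr ridge penalty, default 1e-4), `k` (knn, default 5),
#'   `minsplit`/`cp` (dt), `val_frac` (ensemble weight split, default 0.25),
#'   `refit` (ensemble: refit members on all data after weighting, default
#'   `TRUE`), `tie_policy` (ensemble).
#' @param dnn A [dnn_config()] (dnn kind only); its seed is overridden by
#'   `seed`.
#' @return An `stn_classifier` object; use [predict.stn_classifier()],
#'   [tidy()] and [glance()] on it.
#' @export
fit_stn_classifier <- function(features, kind = c("svm", "lr", "knn", "dt",
                                                  "ensemble", "dnn"),
                               seed = 1L, hyper = list(), dnn = dnn_config()) {
  kind <- match.arg(kind)
  x <- feature_matrix(features)
  y <- features$label
  check_training_labels(y, nrow(x))
  fit_stn_matrix(x, y, kind, seed = seed, hyper = hyper, dnn = dnn,
                 feature_names = colnames(x),
                 family = attr(features, "family"))
}

check_training_labels <- function(y, n_rows) {
  if (is.null(y) || length(y) != n_rows) {
    abort("features must carry one 0/1 label per row.")
  }
  if (anyNA(y)) abort("training labels must not be NA.")
  if (length(unique(y)) < 2) abort("training data must contain both classes.")
}

fit_stn_matrix <- function(x, y, kind, seed, hyper = list(),
                           dnn = dnn_config(), feature_names = colnames(x),
                           family = NULL) {
  scaler <- NULL
  if (kind %in% c("svm", "lr", "dnn")) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
    scaler <- list(center = ctr, scale = scl)
    x <- scale_with(x, scaler)
  }
  fit <- withr::with_seed(seed, switch(kind,
    svm = {
      h <- modifyList(list(cost = 1, gamma = 1 / ncol(x)), hyper)
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = h$cost, gamma = h$gamma, scale = FALSE)
    },
    lr = {
      h <- modifyList(list(lambda = 1e-4), hyper)
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = h$lambda, standardize = FALSE)
    },
    knn = {
      h <- modifyList(list(k = 5), hyper)
      list(x = x, y = y, k = h$k)
    },
    dt = {
      h <- modifyList(list(minsplit = 20, cp = 0.01), hyper)
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     minsplit = h$minsplit, cp = h$cp,
                     xval = 0, maxcompete = 0, maxsurrogate = 0))
    },
    ensemble = fit_ensemble_members(x, y, hyper, seed),
    dnn = {
      cfg <- dnn
      cfg$seed <- seed
      fit_mlp(x, y, cfg)
    }
  ))
  structure(
    list(kind = kind, fit = fit, scaler = scaler,
         feature_names = feature_names, family = family, seed = seed,
         n_train = length(y)),
    class = c(paste0("stn_", kind), "stn_classifier")
  )
}

# Ensemble: fit the four classical members on an internal split, weight each
# by its held-back accuracy, then (by default) refit members on all data.
fit_ensemble_members <- function(x, y, hyper, seed) {
  h <- modifyList(list(val_frac = 0.25, refit = TRUE, tie_policy = "lowest"),
                  hyper)
  kinds <- c("svm", "lr", "knn", "dt")
  n <- length(y)
  val <- sort(sample.int(n, max(2L, round(h$val_frac * n))))
  if (length(unique(y[-val])) < 2 || length(unique(y[val])) < 1) {
    abort("internal ensemble split left a partition without both classes; need more data.")
  }
  members <- lapply(kinds, function(k) {
    fit_stn_matrix(x[-val, , drop = FALSE], y[-val], k, seed = seed,
                   hyper = hyper[setdiff(names(hyper),
                                         c("val_frac", "refit", "tie_policy"))])
  })
  weights <- vapply(seq_along(members), function(i) {
    pred <- predict_stn_matrix(members[[i]], x[val, , drop = FALSE])$.pred_class
    mean(pred == y[val])
  }, 0)
  if (sum(weights) == 0) weights <- rep(1, length(weights))
  if (isTRUE(h$refit)) {
    members <- lapply(kinds, function(k) {
      fit_stn_matrix(x, y, k, seed = seed,
                     hyper = hyper[setdiff(names(hyper),
                                           c("val_frac", "refit", "tie_policy"))])
    })
  }
  list(members = setNames(members, kinds), weights = setNames(weights, kinds),
       tie_policy = h$tie_policy, val_idx = val)
}

scale_with <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Predict inside/outside-STN labels
#'
#' @param object A fitted `stn_classifier`.
#' @param new_data An `stn_features` tibble or a numeric feature matrix with
#'   the training feature dimension.
#' @param ... Unused.
#' @return A tibble with `.pred_class` (integer 0/1) and `.pred_prob`
#'   (probability of class 1 where the kind supports it, otherwise `NA`).
#' @export
predict.stn_classifier <- function(object, new_data, ...) {
  x <- if (is.matrix(new_data)) new_data else feature_matrix(new_data)
  if (ncol(x) != length(object$feature_names)) {
    abort(sprintf("feature dimension mismatch: model expects %d, got %d.",
                  length(object$feature_names), ncol(x)))
  }
  predict_stn_matrix(object, x)
}

predict_stn_matrix <- function(object, x) {
  x <- scale_with(x, object$scaler)
  out <- switch(object$kind,
    svm = {
      cls <- as.integer(as.character(predict(object$fit, x)))
      tibble(.pred_class = cls, .pred_prob = NA_real_)
    },
    lr = {
      p <- as.numeric(predict(object$fit, x, type = "response"))
      tibble(.pred_class = as.integer(p >= 0.5), .pred_prob = p)
    },
    knn = {
      cls <- withr::with_seed(object$seed, {
        as.integer(as.character(
          class::knn(object$fit$x, x, factor(object$fit$y, levels = c(0, 1)),
                     k = object$fit$k)
        ))
      })
      tibble(.pred_class = cls, .pred_prob = NA_real_)
    },
    dt = {
      p <- predict(object$fit, as.data.frame(x), type = "prob")[, "1"]
      tibble(.pred_class = as.integer(p >= 0.5), .pred_prob = as.numeric(p))
    },
    ensemble = {
      votes <- vapply(object$fit$members, function(m) {
        predict_stn_matrix(m, x)$.pred_class
      }, integer(nrow(x)))
      votes <- matrix(votes, nrow = nrow(x))
      cls <- weighted_majority_vote(votes, object$fit$weights,
                                    classes = c(0L, 1L),
                                    tie_policy = object$fit$tie_policy)
      tibble(.pred_class = as.integer(cls), .pred_prob = NA_real_)
    },
    dnn = {
      p <- predict_mlp(object$fit, x)
      tibble(.pred_class = as.integer(p >= 0.5), .pred_prob = p)
    }
  )
  out
}

#' @export
print.stn_classifier <- function(x, ...) {
  cat(sprintf("<stn_classifier: %s> trained on %d epochs x %d features (%s)\n",
              x$kind, x$n_train, length(x$feature_names),
              x$family %||% "unknown family"))
  if (x$kind == "ensemble") {
    w <- x$fit$weights
    cat("  member weights:",
        paste(sprintf("%s=%.3f", names(w), w), collapse = ", "), "\n")
  }
  if (x$kind == "dnn") {
    cat(sprintf("  layers: %s; best epoch %d (val loss %.4f); ||W||_2 = %.3f\n",
                paste(x$fit$dims, collapse = "-"),
                x$fit$best_epoch, x$fit$val_loss, x$fit$weight_l2))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a fitted STN classifier
#'
#' Returns a per-term tibble whose shape depends on the kind: ensemble
#' member weights, logistic-regression coefficients, decision-tree variable
#' importances, SVM support-vector counts per class, per-layer weight norms
#' for the network, or the `k` neighbour setting.
#'
#' @param x A fitted `stn_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stn_classifier <- function(x, ...) {
  switch(x$kind,
    ensemble = tibble(member = names(x$fit$weights),
                      weight = as.numeric(x$fit$weights)),
    lr = {
      cf <- as.matrix(stats::coef(x$fit))
      tibble(term = rownames(cf), estimate = as.numeric(cf))
    },
    dt = {
      imp <- x$fit$variable.importance
      if (is.null(imp)) tibble(term = character(), importance = numeric())
      else tibble(term = names(imp), importance = as.numeric(imp))
    },
    svm = tibble(class = c("0", "1"), n_support = as.numeric(x$fit$nSV)),
    dnn = tibble(layer = seq_along(x$fit$W),
                 n_weights = vapply(x$fit$W, length, 0L),
                 weight_l2 = vapply(x$fit$W, function(w) sqrt(sum(w^2)), 0)),
    knn = tibble(term = "k", estimate = x$fit$k)
  )
}

#' Glance at a fitted STN classifier
#'
#' @param x A fitted `stn_classifier`.
#' @param ... Unused.
#' @return A one-row tibble with the kind, training size, feature dimension
#'   and (for the network) regularization constants and weight norm.
#' @export
glance.stn_classifier <- function(x, ...) {
  out <- tibble(kind = x$kind, n_train = x$n_train,
                n_features = length(x$feature_names),
                family = x$family %||% NA_character_, seed = x$seed)
  if (x$kind == "dnn") {
    out$l2_lambda <- x$fit$config$l2_lambda
    out$dropout_rate <- x$fit$config$dropout_rate
    out$weight_l2 <- x$fit$weight_l2
    out$best_epoch <- x$fit$best_epoch
  }
  out
}
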