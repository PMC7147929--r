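# exhaustive-sum oracle for the weighted vote
oracle_vote <- function(votes, weights, classes) {
  totals <- sapply(classes, function(cl) {
    s <- 0
    for (j in seq_along(votes)) if (votes[j] == cl) s <- s + weights[j]
    s
  })
  tol <- 1e-9 * max(sum(weights), 1) # tie detection as in the implementation
  classes[totals >= max(totals) - tol]
}

test_that("weighted majority vote matches direct arithmetic and ties go low", {
  expect_identical(weighted_majority_vote(c(1, 0, 1), c(0.9, 0.8, 0.6)), 1)
  expect_identical(weighted_majority_vote(c(1, 0), c(0.5, 0.5)), 0)
  expect_error(weighted_majority_vote(integer(0), numeric(0)), "empty")
  expect_error(weighted_majority_vote(c(1, 0), 1), "same length")

  # invariant to positive rescaling of the weights
  expect_identical(weighted_majority_vote(c(2, 0, 1), c(0.2, 0.3, 0.4)),
                   weighted_majority_vote(c(2, 0, 1), 10 * c(0.2, 0.3, 0.4)))
})

test_that("weighted vote equals exhaustive enumeration on a weight grid", {
  grid <- seq(0.1, 1, by = 0.3)
  for (m in 2:4) {
    vote_sets <- expand.grid(rep(list(0:2), m))
    weight_sets <- expand.grid(rep(list(grid), m))
    withr::with_seed(61, {
      weight_sets <- weight_sets[sample(nrow(weight_sets),
                                        min(40, nrow(weight_sets))), ,
                                 drop = FALSE]
    })
    for (vi in seq_len(nrow(vote_sets))) {
      v <- as.numeric(vote_sets[vi, ])
      for (wi in seq_len(nrow(weight_sets))) {
        w <- as.numeric(weight_sets[wi, ])
        got <- weighted_majority_vote(v, w, classes = 0:2)
        expect_identical(got, min(oracle_vote(v, w, 0:2)))
      }
    }
  }
})

test_that("separable data is learned exactly by LR and 1-NN", {
  feats <- toy_features(shift = 6)
  lr <- fit_stn_classifier(feats, "lr", seed = 1)
  expect_equal(mean(predict(lr, feats)$.pred_class == feats$label), 1)

  knn1 <- fit_stn_classifier(feats, "knn", seed = 1, hyper = list(k = 1))
  expect_equal(mean(predict(knn1, feats)$.pred_class == feats$label), 1)
})

test_that("training rejects degenerate inputs and dimension mismatches", {
  feats <- toy_features()
  one_class <- feats[feats$label == 0, ]
  expect_error(fit_stn_classifier(one_class, "svm"), "both classes")

  fit <- fit_stn_classifier(feats, "lr")
  expect_error(predict(fit, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("ensemble stores internal validation accuracies as weights", {
  feats <- toy_features(n_per_class = 40, shift = 2, seed = 9)
  ens <- fit_stn_classifier(feats, "ensemble", seed = 3,
                            hyper = list(refit = FALSE))
  w <- ens$fit$weights
  val <- ens$fit$val_idx
  X <- feature_matrix(feats)
  for (k in names(ens$fit$members)) {
    pred <- merstn:::predict_stn_matrix(ens$fit$members[[k]],
                                        X[val, , drop = FALSE])$.pred_class
    expect_equal(unname(w[k]), mean(pred == feats$label[val]))
  }
  expect_true(all(w >= 0) && sum(w) > 0)
})

test_that("ensemble prediction is the weighted vote of its members", {
  feats <- toy_features(n_per_class = 40, shift = 2, seed = 9)
  ens <- fit_stn_classifier(feats, "ensemble", seed = 3)
  X <- feature_matrix(feats)
  votes <- sapply(ens$fit$members, function(m) {
    merstn:::predict_stn_matrix(m, X)$.pred_class
  })
  manual <- weighted_majority_vote(votes, ens$fit$weights, classes = c(0L, 1L))
  expect_identical(predict(ens, feats)$.pred_class, as.integer(manual))

  # unanimity wins regardless of the weights
  agree <- votes[apply(votes, 1, function(v) length(unique(v)) == 1), ,
                 drop = FALSE]
  if (nrow(agree) > 0) {
    expect_equal(
      weighted_majority_vote(agree, c(0.01, 0.9, 0.05, 0.04),
                             classes = c(0L, 1L)),
      as.numeric(agree[, 1])
    )
  }
})

test_that("the network has nonlinear capacity (XOR) when trained end to end", {
  withr::with_seed(71, {
    base <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
    idx <- rep(1:4, each = 25)
    x <- base[idx, ] + matrix(rnorm(200, 0, 0.05), ncol = 2)
    y <- as.integer(xor(base[idx, 1] > 0.5, base[idx, 2] > 0.5))
    tab <- tibble::tibble(trajectory_id = "A", depth_mm = seq_along(y),
                          label = y, f1 = x[, 1], f2 = x[, 2])
    tab <- merstn:::new_stn_features(tab, "conventional", FALSE, c("f1", "f2"))
    fit <- fit_stn_classifier(
      tab, "dnn", seed = 2,
      dnn = dnn_config(hidden_layers = 3, nodes_per_layer = 16,
                       l2_lambda = 0, dropout_rate = 0,
                       learning_rate = 1e-2, epochs = 300, batch_size = 25,
                       val_frac = 0, patience = 300, probe_init = FALSE)
    )
    acc <- mean(predict(fit, tab)$.pred_class == y)
    expect_gte(acc, 0.99)
  })
})

test_that("L2 regularization shrinks trained weights; dropout masks ~30%", {
  feats <- toy_features(n_per_class = 50, shift = 1.5, seed = 12)
  small <- function(lam, drop = 0) {
    dnn_config(hidden_layers = 2, nodes_per_layer = 20, l2_lambda = lam,
               dropout_rate = drop, learning_rate = 1e-2, epochs = 80,
               batch_size = 20, val_frac = 0, patience = 80,
               probe_init = FALSE)
  }
  free <- fit_stn_classifier(feats, "dnn", seed = 4, dnn = small(0))
  tight <- fit_stn_classifier(feats, "dnn", seed = 4, dnn = small(1000))
  expect_lt(tight$fit$weight_l2, free$fit$weight_l2)

  dropped <- fit_stn_classifier(feats, "dnn", seed = 4,
                                dnn = small(0, drop = 0.3))
  fr <- dropped$fit$dropout_fractions
  expect_gt(length(fr), 0)
  # mean masked fraction over all steps: binomial tolerance around 0.3
  n_units <- 2 * 20 * 20 # units masked per step across hidden layers x batch
  tol <- 4 * sqrt(0.3 * 0.7 / (n_units * length(fr)))
  expect_lt(abs(mean(fr) - 0.3), tol + 0.01)
})

test_that("training is reproducible under a fixed seed", {
  feats <- toy_features(n_per_class = 30, shift = 2, seed = 14)
  cfgs <- list(
    svm = NULL, lr = NULL, dt = NULL,
    dnn = dnn_config(hidden_layers = 2, nodes_per_layer = 8, epochs = 20,
                     probe_init = FALSE)
  )
  for (kind in names(cfgs)) {
    dnn_cfg <- if (is.null(cfgs[[kind]])) dnn_config() else cfgs[[kind]]
    a <- fit_stn_classifier(feats, kind, seed = 6, dnn = dnn_cfg)
    b <- fit_stn_classifier(feats, kind, seed = 6, dnn = dnn_cfg)
    expect_identical(predict(a, feats)$.pred_class,
                     predict(b, feats)$.pred_class)
  }
})

test_that("tidy and glance summarize fitted classifiers", {
  feats <- toy_features()
  ens <- fit_stn_classifier(feats, "ensemble", seed = 2)
  td <- tidy(ens)
  expect_identical(td$member, c("svm", "lr", "knn", "dt"))
  gl <- glance(ens)
  expect_identical(gl$kind, "ensemble")
  expect_identical(gl$n_features, 2L)

  lr <- fit_stn_classifier(feats, "lr")
  expect_true("estimate" %in% names(tidy(lr)))
})
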