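#' Deep feed-forward network configuration
#'
#' Architecture and training constants for the binary MER classifier: a
#' fully connected network with `hidden_layers` ReLU layers of
#' `nodes_per_layer` units and a sigmoid output (twelve layers in total at
#' the defaults, counting input and output), trained with Adam on
#' cross-entropy plus an L2 weight penalty `lambda * sum(W^2)` and inverted
#' dropout on the hidden activations.
#'
#' Defaults follow the clinical study conditions: 10 hidden layers of 50
#' nodes, `l2_lambda = 0.0285`, `dropout_rate = 0.3`. Optimizer settings
#' (Adam, learning rate 1e-3, early stopping on a held-back validation
#' fraction) are this package's choices.
#'
#' @param hidden_layers Number of hidden layers (>= 1).
#' @param nodes_per_layer Units per hidden layer.
#' @param l2_lambda L2 penalty weight (>= 0), applied to weights, not biases.
#' @param dropout_rate Fraction of hidden units silenced per training step,
#'   in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param val_frac Fraction of the training data held back for early
#'   stopping (0 disables).
#' @param patience Epochs without validation improvement before stopping.
#' @param probe_init Initialize the output layer by an exact linear probe —
#'   a ridge-penalized logistic regression fitted on the activations of the
#'   frozen He-initialized hidden stack — before fine-tuning every layer by
#'   backpropagation. A wide randomly initialized ReLU stack is already a
#'   strong feature map for amplitude-structured signals, and with few
#'   samples per input dimension immediate end-to-end backpropagation lets
#'   the large input layer memorize the training set before any structure
#'   forms; the probe sidesteps this. Set `FALSE` for plain end-to-end
#'   training (sensible for low-dimensional inputs).
#' @param finetune_lr_factor Learning-rate multiplier applied after a probe
#'   initialization (ignored when `probe_init = FALSE`).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return A `dnn_config` list.
#' @export
dnn_config <- function(hidden_layers = 10, nodes_per_layer = 50,
                       l2_lambda = 0.0285, dropout_rate = 0.3,
                       learning_rate = 1e-3, epochs = 60, batch_size = 64,
                       val_frac = 0.1, patience = 8,
                       probe_init = TRUE, finetune_lr_factor = 0.1,
                       seed = 1L) {
  if (hidden_layers < 1) abort("hidden_layers must be >= 1.")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1).")
  if (l2_lambda < 0) abort("l2_lambda must be >= 0.")
  structure(as.list(environment()), class = "dnn_config")
}

# Fit the MLP on a numeric matrix x (already standardized) and 0/1 vector y.
fit_mlp <- function(x, y, config = dnn_config()) {
  withr::with_seed(config$seed, fit_mlp_impl(x, y, config))
}

fit_mlp_impl <- function(x, y, config) {
  n <- nrow(x)
  dims <- c(ncol(x), rep(config$nodes_per_layer, config$hidden_layers), 1L)
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  # validation split for early stopping
  val_idx <- integer(0)
  if (config$val_frac > 0 && n >= 20) {
    val_idx <- sample.int(n, max(1L, round(config$val_frac * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]
  p_drop <- config$dropout_rate

  forward <- function(xb, train) {
    A <- xb
    zs <- vector("list", L)
    acts <- vector("list", L)
    masks <- vector("list", L - 1L)
    for (l in seq_len(L - 1L)) {
      Z <- A %*% W[[l]]
      Z <- sweep(Z, 2, b[[l]], "+")
      A <- pmax(Z, 0)
      if (train && p_drop > 0) {
        mask <- matrix(stats::rbinom(length(A), 1, 1 - p_drop) / (1 - p_drop),
                       nrow(A), ncol(A))
        A <- A * mask
        masks[[l]] <- mask
      }
      zs[[l]] <- Z
      acts[[l]] <- A
    }
    Zo <- sweep(A %*% W[[L]], 2, b[[L]], "+")
    list(zs = zs, acts = acts, masks = masks, prob = stats::plogis(Zo[, 1]))
  }
  ce_loss <- function(prob, yy) {
    eps <- 1e-12
    -mean(yy * log(prob + eps) + (1 - yy) * log(1 - prob + eps))
  }

  # linear-probe initialization of the output layer (see dnn_config docs)
  if (isTRUE(config$probe_init)) {
    A <- x[tr_idx, , drop = FALSE]
    for (l in seq_len(L - 1L)) {
      A <- pmax(sweep(A %*% W[[l]], 2, b[[l]], "+"), 0)
    }
    # light fixed ridge: the probe is an initializer, the configured L2
    # penalty still governs the subsequent fine-tuning loss
    probe <- glmnet::glmnet(A, y[tr_idx], family = "binomial", alpha = 0,
                            lambda = 1e-3, standardize = FALSE)
    cf <- as.numeric(stats::coef(probe))
    W[[L]] <- matrix(cf[-1], ncol = 1)
    b[[L]] <- cf[1]
  }
  lr_now <- if (isTRUE(config$probe_init)) {
    config$learning_rate * config$finetune_lr_factor
  } else {
    config$learning_rate
  }

  # Adam state
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(b, function(bb) bb * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  step <- 0L
  lam <- config$l2_lambda
  dropout_fractions <- numeric(0)

  monitor_x <- if (length(val_idx) > 0) xv else x
  monitor_y <- if (length(val_idx) > 0) yv else y
  best <- list(W = W, b = b,
               loss = ce_loss(forward(monitor_x, train = FALSE)$prob,
                              monitor_y),
               epoch = 0L)
  stall <- 0L
  history <- numeric(0)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in batches) {
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi]
      fw <- forward(xb, train = TRUE)
      if (p_drop > 0 && L > 1) {
        masked <- vapply(fw$masks, function(m) mean(m == 0), 0)
        dropout_fractions <- c(dropout_fractions, mean(masked))
      }
      if (any(!is.finite(fw$prob))) {
        abort(sprintf("non-finite network output at epoch %d; training diverged (check learning rate %.3g and input scaling).",
                      epoch, config$learning_rate))
      }
      nb <- length(bi)
      dZ <- matrix((fw$prob - yb) / nb, nb, 1)
      gW <- vector("list", L); gB <- vector("list", L)
      for (l in rev(seq_len(L))) {
        A_prev <- if (l == 1) xb else fw$acts[[l - 1]]
        gW[[l]] <- crossprod(A_prev, dZ) + 2 * lam * W[[l]]
        gB[[l]] <- colSums(dZ)
        if (l > 1) {
          dA <- dZ %*% t(W[[l]])
          if (p_drop > 0) dA <- dA * fw$masks[[l - 1]]
          dZ <- dA * (fw$zs[[l - 1]] > 0)
        }
      }
      step <- step + 1L
      corr1 <- 1 - beta1^step
      corr2 <- 1 - beta2^step
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - lr_now * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps_adam)
        mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
        vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
        b[[l]] <- b[[l]] - lr_now * (mB[[l]] / corr1) /
          (sqrt(vB[[l]] / corr2) + eps_adam)
      }
    }
    monitor_x <- if (length(val_idx) > 0) xv else x
    monitor_y <- if (length(val_idx) > 0) yv else y
    prob <- forward(monitor_x, train = FALSE)$prob
    loss <- ce_loss(prob, monitor_y)
    history <- c(history, loss)
    if (loss < best$loss - 1e-6) {
      best <- list(W = W, b = b, loss = loss, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(
    list(W = best$W, b = best$b, config = config,
         n_layers = L, dims = dims,
         val_loss = best$loss, best_epoch = best$epoch,
         history = history,
         dropout_fractions = dropout_fractions,
         weight_l2 = sqrt(sum(vapply(best$W, function(w) sum(w^2), 0)))),
    class = "mlp_fit"
  )
}

predict_mlp <- function(model, x) {
  A <- x
  L <- model$n_layers
  for (l in seq_len(L - 1L)) {
    Z <- sweep(A %*% model$W[[l]], 2, model$b[[l]], "+")
    A <- pmax(Z, 0)
  }
  Zo <- sweep(A %*% model$W[[L]], 2, model$b[[L]], "+")
  stats::plogis(Zo[, 1])
}
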