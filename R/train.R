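#' Training configuration
#'
#' Per-architecture defaults follow the study's training protocol: Adam
#' with mean-squared-error loss, a 10% validation split carved from the
#' training rows, early stopping with best-weights restoration, and 11
#' independent repeated runs from which the repeat with the lowest best
#' validation loss is kept.
#'
#' | arch        | batch | max epochs | learning rate | patience |
#' |-------------|-------|------------|---------------|----------|
#' | simple_cnn  | 128   | 1000       | 5e-3          | 200      |
#' | s_alexnet   | 16    | 300        | 1e-5          | 300      |
#' | resnet      | 160   | 1000       | 1e-5          | 200      |
#' | googlenet   | 160   | 1000       | 1e-5          | 200      |
#'
#' @param arch Architecture tag, see [build_model()].
#' @param batch_size,max_epochs,learning_rate,val_fraction,patience
#'   Overrides of the per-architecture defaults.
#' @param n_repeats Number of independent training repetitions (default 11).
#' @param seed Integer random state (default 42).
#' @return A list of class `training_config`.
#' @export
training_config <- function(arch = c("simple_cnn", "s_alexnet", "resnet",
                                     "googlenet"),
                            batch_size = NULL, max_epochs = NULL,
                            learning_rate = NULL, val_fraction = 0.10,
                            patience = NULL, n_repeats = 11L, seed = 42L) {
  arch <- match.arg(arch)
  defaults <- switch(arch,
    simple_cnn = list(batch = 128L, epochs = 1000L, lr = 5e-3, pat = 200L),
    s_alexnet  = list(batch = 16L,  epochs = 300L,  lr = 1e-5, pat = 300L),
    resnet     = list(batch = 160L, epochs = 1000L, lr = 1e-5, pat = 200L),
    googlenet  = list(batch = 160L, epochs = 1000L, lr = 1e-5, pat = 200L))
  structure(list(
    arch = arch,
    batch_size = as.integer(batch_size %||% defaults$batch),
    max_epochs = as.integer(max_epochs %||% defaults$epochs),
    learning_rate = learning_rate %||% defaults$lr,
    val_fraction = val_fraction,
    patience = as.integer(patience %||% defaults$pat),
    n_repeats = as.integer(n_repeats),
    seed = as.integer(seed),
    loss = "mse"), class = "training_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validation-split arithmetic
#'
#' The validation set is the trailing block of the once-shuffled training
#' rows; its size is `n_train - floor((1 - val_fraction) * n_train)`, so
#' 315 training rows at a 10% split yield 32 validation spectra.
#'
#' @param n_train Number of training rows.
#' @param val_fraction Validation fraction (default 0.10).
#' @return Integer validation-set size.
#' @export
validation_size <- function(n_train, val_fraction = 0.10) {
  as.integer(n_train - floor((1 - val_fraction) * n_train))
}

#' Train a deep regressor
#'
#' Runs the full training protocol: a single seeded shuffle of the training
#' rows whose trailing `val_fraction` block becomes the validation set,
#' minibatch Adam on mean squared error, early stopping on validation loss
#' with best-weights restoration, and `n_repeats` independent repetitions
#' (fresh initialization each) of which the one with the lowest best
#' validation loss is returned. `epochs_run` accumulates across repeats.
#'
#' @param x Numeric n x m matrix of (SNV-scaled) spectra.
#' @param y Numeric length-n target vector (percent adulteration).
#' @param config A [training_config()].
#' @param model Optional pre-built [build_model()] network used for the
#'   first repeat (later repeats re-initialize with derived seeds).
#' @return An object of class `trained_regressor`: the fitted network plus
#'   `history` (per-repeat, per-epoch train/validation loss), `epochs_run`,
#'   `best_validation_loss`, `arch` and `config`.
#' @export
train_regressor <- function(x, y, config, model = NULL) {
  stopifnot(inherits(config, "training_config"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(y) != n) stop("x and y disagree on n", call. = FALSE)
  if (n < ceiling(2 / config$val_fraction)) {
    stop("too few training rows for the validation split", call. = FALSE)
  }
  if (!is.null(model) && model$input_length != ncol(x)) {
    stop("supplied model input length disagrees with x", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    perm <- sample.int(n)
    n_fit <- floor((1 - config$val_fraction) * n)
    fit_idx <- perm[seq_len(n_fit)]
    val_idx <- perm[seq.int(n_fit + 1L, n)]
    x_fit <- x[fit_idx, , drop = FALSE]
    y_fit <- y[fit_idx]
    x_val <- as_input_tensor(x[val_idx, , drop = FALSE])
    y_val <- y[val_idx]

    best <- NULL
    history <- list()
    total_epochs <- 0L
    for (rep_i in seq_len(config$n_repeats)) {
      net <- if (rep_i == 1L && !is.null(model)) {
        model
      } else {
        build_model(config$arch, ncol(x),
                    seed = stats::runif(1, 0, .Machine$integer.max))
      }
      run <- run_training(net, x_fit, y_fit, x_val, y_val, config)
      total_epochs <- total_epochs + run$epochs
      history[[rep_i]] <- data.frame(repeat_index = rep_i,
                                     epoch = seq_len(run$epochs),
                                     train_loss = run$train_loss,
                                     val_loss = run$val_loss)
      if (is.null(best) || run$best_val < best$best_val) {
        best <- run
        best$net <- net
      }
    }
  })
  leaves <- collect_leaves(best$net$layers)
  restore_weights(leaves, best$snapshot)
  structure(list(network = best$net,
                 arch = config$arch,
                 input_length = best$net$input_length,
                 history = do.call(rbind, history),
                 epochs_run = total_epochs,
                 best_validation_loss = best$best_val,
                 config = config,
                 n_val = length(val_idx)),
            class = "trained_regressor")
}

# One repetition: minibatch Adam with early stopping; assumes an active
# seeded RNG stream.
run_training <- function(net, x_fit, y_fit, x_val, y_val, config) {
  leaves <- collect_leaves(net$layers)
  n_fit <- nrow(x_fit)
  batch <- min(config$batch_size, n_fit)
  t_adam <- 0L
  best_val <- Inf
  best_snap <- snapshot_weights(leaves)
  since_best <- 0L
  tr_hist <- numeric(0)
  va_hist <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_fit)
    ep_loss <- 0
    n_batches <- 0L
    for (b0 in seq.int(1L, n_fit, by = batch)) {
      idx <- ord[b0:min(b0 + batch - 1L, n_fit)]
      xb <- as_input_tensor(x_fit[idx, , drop = FALSE])
      yb <- y_fit[idx]
      pred <- drop(network_forward(net, xb, training = TRUE))
      resid <- pred - yb
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      ep_loss <- ep_loss + loss
      n_batches <- n_batches + 1L
      dy <- matrix(2 * resid / length(resid), ncol = 1L)
      network_backward(net, dy)
      t_adam <- t_adam + 1L
      adam_step(leaves, config$learning_rate, t_adam)
    }
    val_pred <- drop(network_forward(net, x_val, training = FALSE))
    val_loss <- mean((val_pred - y_val)^2)
    if (!is.finite(val_loss)) {
      stop("training diverged (non-finite validation loss) at epoch ",
           epoch, call. = FALSE)
    }
    tr_hist[epoch] <- ep_loss / n_batches
    va_hist[epoch] <- val_loss
    if (val_loss < best_val) {
      best_val <- val_loss
      best_snap <- snapshot_weights(leaves)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  list(epochs = length(tr_hist), train_loss = tr_hist, val_loss = va_hist,
       best_val = best_val, snapshot = best_snap)
}

#' @export
print.trained_regressor <- function(x, ...) {
  cat(sprintf(
    "<trained_regressor> %s, %d epochs across %d repeat(s), best val MSE %.4g\n",
    x$arch, x$epochs_run, x$config$n_repeats, x$best_validation_loss))
  invisible(x)
}

#' Predict percent adulteration
#'
#' Deterministic inference with the restored best weights (batch-norm
#' layers use their running statistics). Predictions are not clipped and
#' may leave the training target range.
#'
#' @param object A `trained_regressor`.
#' @param x Numeric k x m matrix of (SNV-scaled) spectra, or a length-m
#'   vector.
#' @param chunk_size Rows evaluated per forward pass.
#' @param ... Unused.
#' @return Numeric vector of k predictions (percent).
#' @export
predict.trained_regressor <- function(object, x, chunk_size = 512L, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(numeric(0))
  if (ncol(x) != object$input_length) {
    stop(sprintf("input has %d features but the model expects %d",
                 ncol(x), object$input_length), call. = FALSE)
  }
  out <- numeric(nrow(x))
  for (b0 in seq.int(1L, nrow(x), by = chunk_size)) {
    idx <- b0:min(b0 + chunk_size - 1L, nrow(x))
    xb <- as_input_tensor(x[idx, , drop = FALSE])
    out[idx] <- drop(network_forward(object$network, xb, training = FALSE))
  }
  out
}
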