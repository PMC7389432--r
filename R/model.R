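#' Configuration of the gait-phase MLP classifier
#'
#' The default architecture is the three-hidden-layer perceptron
#' 200-512-256-128-1 (ReLU between hidden layers, sigmoid output) trained
#' with plain stochastic gradient descent on binary cross-entropy,
#' learning rate 0.01, for at most 100 epochs with early stopping once
#' validation accuracy has not increased for `patience` consecutive
#' epochs. The validation set is the chronological tail `val_fraction` of
#' the training sequence. `hidden_sizes = 128` gives the lighter
#' single-hidden-layer variant.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths (non-empty).
#' @param input_size Width of the window vectors (window_len x channels).
#' @param learning_rate SGD learning rate.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs.
#' @param batch_size Mini-batch size.
#' @param threshold Decision threshold on the sigmoid output; the positive
#'   (swing) label requires probability strictly greater than it.
#' @param val_fraction Fraction of the training sequence held out, from the
#'   chronological tail, as the validation set.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return An object of class `mlp_config`.
#' @export
#' @examples
#' mlp_config(hidden_sizes = 128, max_epochs = 30)
mlp_config <- function(hidden_sizes = c(512, 256, 128), input_size = 200,
                       learning_rate = 0.01, max_epochs = 100,
                       patience = 10, batch_size = 32, threshold = 0.5,
                       val_fraction = 0.10, seed = 1L) {
  if (length(hidden_sizes) == 0 || any(hidden_sizes < 1))
    stopf("`hidden_sizes` must be a non-empty vector of positive counts",
          class = "gaitphase_validation_error")
  if (threshold <= 0 || threshold >= 1)
    stopf("`threshold` must lie strictly between 0 and 1",
          class = "gaitphase_validation_error")
  if (patience > max_epochs)
    stopf("`patience` (%d) cannot exceed `max_epochs` (%d)",
          patience, max_epochs, class = "gaitphase_validation_error")
  if (val_fraction <= 0 || val_fraction >= 1)
    stopf("`val_fraction` must lie strictly between 0 and 1",
          class = "gaitphase_validation_error")
  structure(
    list(hidden_sizes = as.integer(hidden_sizes),
         input_size = as.integer(input_size),
         learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs),
         patience = as.integer(patience),
         batch_size = as.integer(batch_size),
         threshold = threshold, val_fraction = val_fraction,
         seed = as.integer(seed)),
    class = "mlp_config")
}

#' @export
print.mlp_config <- function(x, ...) {
  cat(sprintf("<mlp_config> %s | lr %g | <=%d epochs (patience %d) | seed %d\n",
              paste(c(x$input_size, x$hidden_sizes, 1), collapse = "-"),
              x$learning_rate, x$max_epochs, x$patience, x$seed))
  invisible(x)
}

#' Number of trainable parameters of an MLP configuration
#'
#' @param cfg An [mlp_config()].
#' @return Integer: total weights + biases.
#' @export
#' @examples
#' mlp_n_params(mlp_config())  # 267137
mlp_n_params <- function(cfg) {
  dims <- c(cfg$input_size, cfg$hidden_sizes, 1L)
  sum(head(dims, -1) * tail(dims, -1) + tail(dims, -1))
}

# He-style scaled-uniform initial weights, drawn under the config seed
mlp_init <- function(cfg) {
  dims <- c(cfg$input_size, cfg$hidden_sizes, 1L)
  with_seed(cfg$seed, {
    W <- vector("list", length(dims) - 1)
    b <- vector("list", length(dims) - 1)
    for (l in seq_len(length(dims) - 1)) {
      lim <- sqrt(6 / dims[l])
      W[[l]] <- matrix(runif(dims[l] * dims[l + 1], -lim, lim),
                       dims[l], dims[l + 1])
      b[[l]] <- rep(0, dims[l + 1])
    }
    list(weights = W, biases = b)
  })
}

#' Train the gait-phase MLP on labeled windows
#'
#' Takes the chronological sequence of labeled (unmasked) windows, holds
#' out its tail `val_fraction` as validation, and runs mini-batch SGD on
#' binary cross-entropy. Training stops at `max_epochs` or once validation
#' accuracy has not increased for `patience` consecutive epochs; the
#' weights of the best-validation epoch are kept. Rows are never shuffled
#' across the train/validation boundary; mini-batch order is reshuffled
#' every epoch under the config seed.
#'
#' @param windows A `window_dataset` (masked rows are dropped here), or any
#'   tibble with a matrix column `vector` and a 0/1 `label` column.
#' @param cfg An [mlp_config()]; `input_size` must match the vector width.
#' @return An `mlp_fit`: list with `weights`, `biases`, `config`,
#'   `best_epoch`, `epochs_run`, `n_train`, `n_val`, and `history`
#'   (tibble `epoch`, `train_loss`, `val_accuracy`).
#' @export
fit_mlp <- function(windows, cfg = mlp_config()) {
  stopifnot(inherits(cfg, "mlp_config"))
  if ("masked" %in% names(windows)) windows <- windows[!windows$masked, ]
  X <- windows$vector
  y <- as.numeric(windows$label)
  if (anyNA(y))
    stopf("training windows must all be labeled",
          class = "gaitphase_validation_error")
  if (ncol(X) != cfg$input_size)
    stopf("window vectors are %d wide but the model expects %d",
          ncol(X), cfg$input_size, class = "gaitphase_validation_error")
  n <- nrow(X)
  n_val <- max(1L, as.integer(round(n * cfg$val_fraction)))
  n_train <- n - n_val
  if (n_train < cfg$batch_size)
    stopf("too few windows (%d) to train with batch size %d", n,
          cfg$batch_size, class = "gaitphase_validation_error")
  if (length(unique(y[seq_len(n_train)])) < 2)
    stopf("training windows contain a single class; cannot fit",
          class = "gaitphase_degenerate_training")
  init <- mlp_init(cfg)
  res <- .mlp_train_cpp(X, y, init$weights, init$biases,
                        cfg$learning_rate, cfg$max_epochs, cfg$batch_size,
                        cfg$patience, n_train, cfg$threshold, cfg$seed)
  structure(
    list(weights = res$weights, biases = res$biases, config = cfg,
         best_epoch = res$best_epoch,
         best_val_accuracy = res$best_val_accuracy,
         epochs_run = res$epochs_run, n_train = n_train, n_val = n_val,
         history = tibble(epoch = seq_len(res$epochs_run),
                          train_loss = res$train_loss,
                          val_accuracy = res$val_accuracy)),
    class = "mlp_fit")
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf(
    "<mlp_fit> %s | %d epochs run, best epoch %d (val acc %.4f) | %d train / %d val windows\n",
    paste(c(x$config$input_size, x$config$hidden_sizes, 1), collapse = "-"),
    x$epochs_run, x$best_epoch, x$best_val_accuracy, x$n_train, x$n_val))
  invisible(x)
}

#' Predict stance/swing labels for window vectors
#'
#' @param object An `mlp_fit`.
#' @param newdata A `window_dataset`-like tibble with a matrix column
#'   `vector`, or a bare matrix of window vectors.
#' @param ... Unused.
#' @return Tibble with `prob` (sigmoid output) and `label` (1 iff
#'   `prob` strictly exceeds the configured threshold).
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else newdata$vector
  if (ncol(X) != object$config$input_size)
    stopf("window vectors are %d wide but the model expects %d",
          ncol(X), object$config$input_size,
          class = "gaitphase_validation_error")
  p <- .mlp_forward_cpp(X, object$weights, object$biases)
  tibble(prob = as.numeric(p),
         label = as.integer(p > object$config$threshold))
}

#' Stance-vs-swing classification accuracy over unmasked windows
#'
#' @param pred 0/1 predicted labels.
#' @param truth 0/1 (or NA on masked rows) true labels.
#' @param masked Logical mask; masked windows are excluded.
#' @return Fraction of unmasked windows where prediction equals truth.
#' @export
classification_accuracy <- function(pred, truth,
                                    masked = rep(FALSE, length(truth))) {
  stopifnot(length(pred) == length(truth), length(truth) == length(masked))
  keep <- !masked
  if (!any(keep))
    stopf("no unmasked windows: accuracy undefined",
          class = "gaitphase_undefined_metric")
  mean(pred[keep] == truth[keep])
}

#' @export
tidy.mlp_fit <- function(x, ...) {
  dims <- c(x$config$input_size, x$config$hidden_sizes, 1L)
  purrr::map_dfr(seq_along(x$weights), function(l) {
    tibble(layer = l, from = dims[l], to = dims[l + 1],
           n_weights = dims[l] * dims[l + 1] + dims[l + 1],
           weight_sd = sd(as.numeric(x$weights[[l]])),
           bias_mean = mean(x$biases[[l]]))
  })
}

#' @export
glance.mlp_fit <- function(x, ...) {
  tibble(n_params = mlp_n_params(x$config),
         epochs_run = x$epochs_run, best_epoch = x$best_epoch,
         best_val_accuracy = x$best_val_accuracy,
         final_train_loss = tail(x$history$train_loss, 1),
         n_train = x$n_train, n_val = x$n_val)
}

#' Plot the training history of an MLP fit
#'
#' @param object An `mlp_fit`.
#' @param ... Unused.
#' @return A ggplot: training loss and validation accuracy per epoch, with
#'   the restored best epoch marked.
#' @export
autoplot.mlp_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "MLP training history",
                  subtitle = "dashed line: restored best-validation epoch")
}
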