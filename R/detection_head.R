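#' Detection head configuration
#'
#' Architecture and training protocol of the fully-connected detection head
#' that replaces the backbone classifier: four hidden ReLU layers of 1024,
#' 1024, 1024 and 512 units, a six-unit sigmoid output (one confidence per
#' 0.16 s subframe), L2 regularization on the first three hidden layers,
#' Adam on a mean-squared-error loss with mini-batches of 32, at most 70
#' epochs and early stopping with patience 5 on the validation loss
#' (best-validation weights restored). Learning rate and L2 strength are
#' this package's own defaults (3e-4 and 1e-4): at the more conventional
#' 1e-3 this head's MSE loss is unstable under per-epoch rebalancing (see
#' the methods vignette).
#'
#' @param input_dim Feature dimension (1024-d embedding + 1 ZCR = 1025).
#' @param hidden_units Hidden layer widths.
#' @param output_units Output units (six subframes).
#' @param l2_layers Indices of hidden layers receiving L2 (first three).
#' @param l2_strength L2 penalty coefficient.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed for weight initialization and epoch balancing.
#' @return A list of class `head_config`.
#' @export
head_config <- function(input_dim = 1025L,
                        hidden_units = c(1024L, 1024L, 1024L, 512L),
                        output_units = 6L,
                        l2_layers = 1:3, l2_strength = 1e-4,
                        learning_rate = 3e-4, batch_size = 32L,
                        max_epochs = 70L, patience = 5L, seed = 1L) {
  stopifnot(input_dim > 0, all(hidden_units > 0), output_units > 0,
            l2_strength >= 0, learning_rate > 0, batch_size > 0,
            max_epochs > 0, patience > 0,
            all(l2_layers %in% seq_along(hidden_units)))
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 output_units = as.integer(output_units),
                 l2_layers = as.integer(l2_layers),
                 l2_strength = l2_strength,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "head_config")
}

#' Number of trainable parameters in the head
#' @param cfg A [head_config()].
#' @return Integer parameter count (weights + biases).
#' @export
head_param_count <- function(cfg = head_config()) {
  dims <- c(cfg$input_dim, cfg$hidden_units, cfg$output_units)
  sum(dims[-length(dims)] * dims[-1L] + dims[-1L])
}

#' Initialize head weights
#'
#' Fan-in-scaled random initialization (He for the ReLU layers, 1/fan-in
#' variance for the sigmoid output), biases zero, from the config seed.
#'
#' @param cfg A [head_config()].
#' @return List with `W` (list of weight matrices) and `b` (list of bias
#'   vectors).
#' @export
init_head <- function(cfg = head_config()) {
  dims <- c(cfg$input_dim, cfg$hidden_units, cfg$output_units)
  nl <- length(dims) - 1L
  set.seed(cfg$seed)
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    sc <- if (l < nl) sqrt(2 / dims[l]) else sqrt(1 / dims[l])
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L]) * sc, dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

#' Split participants into train/validation/test subsets
#'
#' Random split at participant granularity (all frames of one neonate fall
#' in one subset, preventing leakage) in the given ratios. Sizes follow
#' `train = round(r1 n)`, `val = round(r2 n)`, `test = remainder`, with
#' conventional half-up rounding.
#'
#' @param ids Character or integer participant identifiers (>= 3).
#' @param ratios Length-3 ratios summing to 1 (default 60/20/20).
#' @param seed Integer seed.
#' @return A list of class `data_split` with `train`, `val`, `test`.
#' @export
split_participants <- function(ids, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  ids <- unique(ids)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 participants to split, got ", n)
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be 3 values summing to 1")
  set.seed(seed)
  perm <- sample(ids)
  n_train <- floor(ratios[1L] * n + 0.5)
  n_val <- floor(ratios[2L] * n + 0.5)
  if (n_train + n_val >= n) n_val <- max(0L, n - n_train - 1L)
  structure(list(train = perm[seq_len(n_train)],
                 val = perm[n_train + seq_len(n_val)],
                 test = perm[-(seq_len(n_train + n_val))]),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> train=%d val=%d test=%d participants\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Per-epoch class balancing by undersampling
#'
#' A frame's class is "swallow" when any of its six subframe targets is 1.
#' The majority class is undersampled (a fresh draw each epoch) so both
#' classes contribute equally, and the resulting index set is shuffled.
#'
#' @param labels n x 6 binary target matrix.
#' @param seed Base seed; the draw is a deterministic function of
#'   `(seed, epoch)`.
#' @param epoch Epoch number (1-based).
#' @return Integer vector of row indices (balanced, shuffled).
#' @export
balance_epoch <- function(labels, seed = 1L, epoch = 1L) {
  cls <- rowSums(labels) > 0
  n_pos <- sum(cls); n_neg <- sum(!cls)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to balance (swallow frames: ",
         n_pos, ", non-swallow frames: ", n_neg, ")")
  set.seed((as.integer(seed) + 104729L * as.integer(epoch)) %% 2147483647L)
  pos <- which(cls); neg <- which(!cls)
  k <- min(n_pos, n_neg)
  if (n_pos > k) pos <- sample(pos, k)
  if (n_neg > k) neg <- sample(neg, k)
  sample(c(pos, neg))
}

#' Reference early-stopping trace
#'
#' Given a sequence of per-epoch validation losses, returns the epoch whose
#' weights early stopping keeps (lowest validation loss, first occurrence)
#' and the epoch at which training halts (patience consecutive epochs
#' without strict improvement). Used as an independent check of the
#' training loop's recorded history.
#'
#' @param val_losses Numeric vector of validation losses by epoch.
#' @param patience Patience in epochs.
#' @return List with `best_epoch` and `stop_epoch`.
#' @export
early_stop_trace <- function(val_losses, patience) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(list(best_epoch = best_epoch, stop_epoch = e))
    }
  }
  list(best_epoch = best_epoch, stop_epoch = length(val_losses))
}

#' Train the detection head
#'
#' Runs the training protocol: per-epoch balanced undersampling and
#' shuffling of the training frames, mini-batch Adam on the MSE between the
#' six sigmoid outputs and the binary subframe targets, L2 on the first
#' three hidden layers, early stopping on validation loss with best-weights
#' restoration. Fully deterministic given the config seed.
#'
#' @param cfg A [head_config()].
#' @param x n x 1025 feature matrix (training frames).
#' @param y n x 6 binary subframe target matrix.
#' @param x_val,y_val Validation features/targets.
#' @return An object of class `trained_head`: `weights`, `config`,
#'   `history` (per-epoch train/validation loss), `best_epoch`,
#'   `epochs_run`.
#' @export
train_head <- function(cfg, x, y, x_val, y_val) {
  x <- as.matrix(x); y <- as.matrix(y)
  x_val <- as.matrix(x_val); y_val <- as.matrix(y_val)
  if (ncol(x) != cfg$input_dim)
    stop("feature dimension ", ncol(x), " != config input_dim ", cfg$input_dim)
  if (ncol(y) != cfg$output_units || ncol(y_val) != cfg$output_units)
    stop("target dimension must be ", cfg$output_units)
  if (nrow(x) != nrow(y) || nrow(x_val) != nrow(y_val))
    stop("feature/target row mismatch")
  if (ncol(x_val) != cfg$input_dim)
    stop("validation feature dimension mismatch")

  # per-feature standardization, fitted on the training frames; stored so
  # prediction applies the identical transform (embedding activations and
  # the ZCR live on very different scales, which otherwise saturates the
  # sigmoid output at initialization)
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(x^2) - mu^2)
  sigma[sigma < 1e-8] <- 1
  x <- sweep(sweep(x, 2L, mu), 2L, sigma, "/")
  x_val <- sweep(sweep(x_val, 2L, mu), 2L, sigma, "/")

  init <- init_head(cfg)
  epoch_idx <- lapply(seq_len(cfg$max_epochs), function(e)
    balance_epoch(y, seed = cfg$seed, epoch = e))
  fit <- mlp_train_cpp(init$W, init$b, x, y, x_val, y_val, epoch_idx,
                       cfg$learning_rate, cfg$l2_strength, cfg$l2_layers,
                       cfg$batch_size, cfg$patience)
  structure(list(
    weights = list(W = fit$W, b = fit$b),
    scaling = list(mean = mu, sd = sigma),
    config = cfg,
    history = data.frame(epoch = seq_along(fit$train_loss),
                         train_loss = fit$train_loss,
                         val_loss = fit$val_loss),
    best_epoch = fit$best_epoch,
    epochs_run = fit$epochs_run,
    best_val_loss = fit$best_val_loss
  ), class = "trained_head")
}

#' @export
print.trained_head <- function(x, ...) {
  cat(sprintf("<trained_head> %s -> %d | %d epochs (best %d, val MSE %.4f), %d parameters\n",
              paste(c(x$config$input_dim, x$config$hidden_units), collapse = "-"),
              x$config$output_units, x$epochs_run, x$best_epoch,
              x$best_val_loss, head_param_count(x$config)))
  invisible(x)
}

#' Predict subframe confidences
#'
#' @param object A `trained_head`.
#' @param newdata Feature matrix (n x 1025) or a single feature vector.
#' @param ... Unused.
#' @return n x 6 matrix of confidences in `[0, 1]`.
#' @export
predict.trained_head <- function(object, newdata, ...) {
  if (is.null(object$weights)) stop("head has no trained weights")
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$config$input_dim)
    stop("feature dimension ", ncol(newdata), " != ", object$config$input_dim)
  if (!is.null(object$scaling))
    newdata <- sweep(sweep(newdata, 2L, object$scaling$mean), 2L,
                     object$scaling$sd, "/")
  mlp_forward_cpp(object$weights$W, object$weights$b, newdata)
}

#' Save / load a trained head checkpoint
#'
#' The checkpoint is the weight arrays plus a JSON sidecar carrying the head
#' and feature/backend configuration, so predictions are reproducible from
#' the checkpoint alone.
#'
#' @param head A `trained_head`.
#' @param path Checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @param extra Named list merged into the sidecar (e.g. backend/feature
#'   config).
#' @return `path`, invisibly (for `save_head`); the `trained_head` with an
#'   attached `sidecar` field (for `load_head`).
#' @export
save_head <- function(head, path, extra = list()) {
  saveRDS(head, path)
  sidecar <- c(list(config = unclass(head$config),
                    best_epoch = head$best_epoch,
                    epochs_run = head$epochs_run,
                    param_count = head_param_count(head$config)),
               extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_head
#' @export
load_head <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  head <- readRDS(path)
  if (!inherits(head, "trained_head") &&
      !inherits(head, "swallow_detector"))
    stop("corrupt checkpoint (not a trained head): ", path)
  side <- paste0(path, ".json")
  if (file.exists(side))
    head$sidecar <- jsonlite::read_json(side, simplifyVector = TRUE)
  head
}
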