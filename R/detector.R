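#' Fit a swallow-sound detector on a labeled corpus
#'
#' The package's modelling entry point. Given a corpus directory (WAV
#' recordings, swallow-interval annotations and a manifest), it: (1) splits
#' participants 60/20/20 into train/validation/test at participant
#' granularity; (2) runs the feature front end (16 kHz resampling,
#' normalization, 0.96 s frames at 50% overlap, log-Mel patches, ZCR) and
#' the embedding backend; (3) trains the six-subframe detection head with
#' per-epoch class balancing, Adam on MSE and early stopping; (4) evaluates
#' subframe-level diagnostic accuracy on the held-out test split, overall
#' and stratified by feeding type.
#'
#' @param corpus_dir Corpus directory (see [generate_corpus()] for the
#'   layout).
#' @param backend An [embedding_backend()]; the projection backend is the
#'   offline default.
#' @param head A [head_config()].
#' @param feature A [feature_config()].
#' @param split_ratios Train/validation/test ratios.
#' @param seed Seed for the participant split (the head's own seed lives in
#'   its config).
#' @param threshold Decision threshold for evaluation and prediction.
#' @param verbose Print stage progress.
#' @return An object of class `swallow_detector` with components `head`
#'   (the `trained_head`), `backend`, `feature`, `split`, `threshold`,
#'   `test_metrics` (stratified [metrics_by_class()] reports),
#'   `test_counts` (per-recording confusion counts) and `history`.
#' @seealso [predict.swallow_detector()], [segment_recording()]
#' @export
swallow_detector <- function(corpus_dir,
                             backend = embedding_backend("projection"),
                             head = head_config(),
                             feature = feature_config(),
                             split_ratios = c(0.6, 0.2, 0.2),
                             seed = 1L, threshold = 0.5, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  say("assembling corpus features")
  ds <- corpus_dataset(corpus_dir, backend, feature, verbose = verbose)
  ids <- ds$manifest$recording_id
  split <- split_participants(ids, split_ratios, seed = seed)
  in_split <- function(s) ds$frame_recording %in% s

  say(sprintf("training head (%d train / %d val / %d test participants)",
              length(split$train), length(split$val), length(split$test)))
  fit <- train_head(head,
                    ds$x[in_split(split$train), , drop = FALSE],
                    ds$y[in_split(split$train), , drop = FALSE],
                    ds$x[in_split(split$val), , drop = FALSE],
                    ds$y[in_split(split$val), , drop = FALSE])
  say(sprintf("trained %d epochs (best %d, val MSE %.4f)",
              fit$epochs_run, fit$best_epoch, fit$best_val_loss))

  say("evaluating held-out split")
  counts <- list()
  for (id in split$test) {
    rows <- ds$frame_recording == id
    conf <- predict(fit, ds$x[rows, , drop = FALSE])
    counts[[id]] <- .recording_counts(conf, ds$recordings[[id]]$frame_starts,
                                      ds$recordings[[id]]$truth, threshold)
  }
  metrics <- stratified_evaluate(counts, ds$manifest)

  structure(list(head = fit, backend = backend, feature = feature,
                 split = split, threshold = threshold,
                 test_metrics = metrics, test_counts = counts,
                 history = fit$history, call = match.call()),
            class = "swallow_detector")
}

#' @export
print.swallow_detector <- function(x, ...) {
  cat("Swallow-sound detector (transfer embeddings + subframe head)\n")
  cat(sprintf("  backend: %s (dim %d), threshold %.2f\n",
              x$backend$type, x$backend$embedding_dim, x$threshold))
  print(x$head)
  cat(sprintf("  held-out subframe accuracy: %.3f (%d test recordings)\n",
              x$test_metrics$all$accuracy, length(x$split$test)))
  invisible(x)
}

#' @export
summary.swallow_detector <- function(object, ...) {
  cat("Held-out diagnostic accuracy by stratum (subframe level, 0.16 s bins)\n\n")
  for (stratum in names(object$test_metrics)) {
    cat("== ", stratum, " ==\n", sep = "")
    print(object$test_metrics[[stratum]])
    cat("\n")
  }
  invisible(object$test_metrics)
}

#' @export
coef.swallow_detector <- function(object, ...) object$head$weights

#' Training-history plot
#' @param x A `swallow_detector`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.swallow_detector <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch", ylab = "MSE loss",
                    main = "Detection head training", ...)
  graphics::abline(v = x$head$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}

#' Predict swallow intervals for new audio
#'
#' @param object A fitted `swallow_detector`.
#' @param newdata A WAV path or an [audio_recording()].
#' @param threshold Decision threshold; defaults to the detector's.
#' @param ... Unused.
#' @return The predicted [annotation_set()], with the fused confidence
#'   [timeline()] attached as attribute `confidences`.
#' @export
predict.swallow_detector <- function(object, newdata,
                                     threshold = object$threshold, ...) {
  rec <- if (is.character(newdata)) load_audio(newdata) else newdata
  if (!inherits(rec, "audio_recording"))
    stop("newdata must be a WAV path or an audio_recording")
  seg <- segment_recording(object$head, rec, object$backend, object$feature,
                           threshold)
  out <- seg$intervals
  attr(out, "confidences") <- seg$confidences
  out
}
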