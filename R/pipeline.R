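#' Preprocess a recording for the front end
#'
#' Resamples to the front-end rate (Kaiser-window FIR polyphase) and
#' peak-normalizes to `[-1, 1]`.
#'
#' @param rec An [audio_recording()].
#' @param target_rate Front-end rate in Hz (default 16000).
#' @return The preprocessed [audio_recording()].
#' @export
preprocess_recording <- function(rec, target_rate = 16000L) {
  normalize_audio(resample_audio(rec, target_rate))
}

# Flatten a list of n_win x n_mels patches to an n x (n_win*n_mels) matrix
# (column-major per patch, matching as.vector()).
.flatten_patches <- function(patches) {
  if (!length(patches)) return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  d <- length(patches[[1L]])
  t(vapply(patches, as.vector, numeric(d)))
}

#' Frame-level feature matrix for one recording
#'
#' Frames the (preprocessed, 16 kHz) recording, computes log-Mel patches and
#' zero-crossing rates, embeds the patches, and appends the ZCR, yielding
#' one 1025-dimensional feature vector per frame.
#'
#' @param rec A preprocessed [audio_recording()] at the front-end rate.
#' @param backend An [embedding_backend()].
#' @param fcfg A [feature_config()].
#' @return List with `features` (n x 1025), `frame_starts`, `n_frames`.
#' @export
frame_features <- function(rec, backend = embedding_backend("projection"),
                           fcfg = feature_config()) {
  fs <- frame_signal(rec, fcfg$frame_length_s, fcfg$overlap)
  nf <- ncol(fs$frames)
  if (nf == 0L)
    return(list(features = matrix(numeric(0), 0L, backend$embedding_dim + 1L),
                frame_starts = numeric(0), n_frames = 0L))
  patches <- log_mel_frames(fs$frames, fcfg)
  emb <- embed_patches(backend, .flatten_patches(patches))
  zcr <- zcr_frames(fs$frames)
  rms <- sqrt(colMeans(fs$frames^2))
  list(features = cbind(emb, zcr, deparse.level = 0),
       frame_starts = fs$frame_starts, n_frames = nf, frame_rms = rms)
}

#' Assemble the frame dataset for a corpus
#'
#' Loads every manifest entry, runs the preprocessing and feature front end,
#' and converts the truth intervals to subframe targets. Fails fast if a
#' manifest entry lacks its annotation file.
#'
#' @param corpus_dir Corpus directory with `manifest.csv`, WAVs and
#'   annotation CSVs.
#' @param backend An [embedding_backend()].
#' @param fcfg A [feature_config()].
#' @param verbose Print per-recording progress.
#' @return List: `x` (frames x 1025), `y` (frames x 6), `frame_recording`
#'   (recording id per frame row), `recordings` (named list with
#'   `frame_starts`, `truth`, `feeding_type` per recording), `manifest`.
#' @export
corpus_dataset <- function(corpus_dir,
                           backend = embedding_backend("projection"),
                           fcfg = feature_config(), verbose = FALSE) {
  manifest <- read_manifest(corpus_dir)
  if (nrow(manifest) == 0L) stop("empty corpus: ", corpus_dir)
  missing_ann <- manifest$recording_id[!file.exists(
    file.path(corpus_dir, paste0(manifest$recording_id, ".csv")))]
  if (length(missing_ann))
    stop("missing annotations for: ", paste(missing_ann, collapse = ", "))

  xs <- list(); ys <- list(); rec_of_frame <- list(); recs <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$recording_id[i]
    if (verbose) message("  features: ", id)
    rec <- load_audio(file.path(corpus_dir, paste0(id, ".wav")),
                      recording_id = id,
                      feeding_type = manifest$feeding_type[i])
    rec <- preprocess_recording(rec, fcfg$sample_rate)
    ff <- frame_features(rec, backend, fcfg)
    truth <- read_annotations(file.path(corpus_dir, paste0(id, ".csv")),
                              recording_id = id)
    xs[[i]] <- ff$features
    ys[[i]] <- intervals_to_labels(truth, ff$frame_starts)
    rec_of_frame[[i]] <- rep(id, ff$n_frames)
    recs[[id]] <- list(frame_starts = ff$frame_starts, truth = truth,
                       feeding_type = manifest$feeding_type[i])
  }
  list(x = do.call(rbind, xs), y = do.call(rbind, ys),
       frame_recording = unlist(rec_of_frame),
       recordings = recs, manifest = manifest)
}

#' Segment a recording with a trained head
#'
#' Runs the full inference path: preprocessing, framing, features,
#' per-frame six-subframe confidences, mean-fusion of the two frames
#' covering each 0.16 s bin, and strict-threshold run decoding.
#'
#' @param head A `trained_head`.
#' @param rec An [audio_recording()] (any rate; it is preprocessed).
#' @param backend An [embedding_backend()].
#' @param fcfg A [feature_config()].
#' @param threshold Decision threshold (strict `>`), default 0.5.
#' @param fusion `"mean"` or `"or"` frame fusion.
#' @return List: `intervals` (predicted [annotation_set()]), `confidences`
#'   (fused [timeline()]), `frame_confidences` (n x 6 matrix).
#' @export
segment_recording <- function(head, rec,
                              backend = embedding_backend("projection"),
                              fcfg = feature_config(), threshold = 0.5,
                              fusion = "mean") {
  rec <- preprocess_recording(rec, fcfg$sample_rate)
  ff <- frame_features(rec, backend, fcfg)
  if (ff$n_frames == 0L) {
    return(list(intervals = annotation_set(recording_id = rec$recording_id),
                confidences = timeline(numeric(0)),
                frame_confidences = matrix(numeric(0), 0L, 6L)))
  }
  conf <- predict(head, ff$features)
  # degenerate-input rule: a constant (zero-RMS) frame carries no acoustic
  # content, so its subframes cannot contain a swallow
  conf[ff$frame_rms == 0, ] <- 0
  attr(conf, "frame_starts") <- ff$frame_starts
  tl <- fuse_overlapping_frames(conf, method = fusion)
  list(intervals = decode_intervals(tl, threshold, rec$recording_id),
       confidences = tl, frame_confidences = conf)
}

# Subframe-grid confusion counts for one recording given per-frame
# confidences and truth intervals.
.recording_counts <- function(conf, frame_starts, truth, threshold = 0.5,
                              fusion = "mean") {
  attr(conf, "frame_starts") <- frame_starts
  tl <- fuse_overlapping_frames(conf, method = fusion)
  truth_tl <- intervals_to_bins(truth, n_bins = length(tl$values),
                                start = tl$start, bin_width = tl$bin_width)
  confusion_counts(tl, truth_tl, threshold)
}
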