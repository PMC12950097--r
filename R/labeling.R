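#' Subframe geometry constants
#'
#' Each 0.96 s analysis frame is subdivided into six 0.16 s subframes; the
#' model predicts one confidence per subframe, improving temporal resolution
#' by a factor of six over frame-level prediction.
#' @name subframe_geometry
#' @keywords internal
NULL

.SUBFRAME_S <- 0.16
.N_SUBFRAMES <- 6L

#' Convert swallow intervals to per-frame subframe targets
#'
#' For each analysis frame, subframe k (0-based, spanning
#' `[frame_start + 0.16 k, frame_start + 0.16 (k+1))`) is labeled 1 when a
#' swallow interval overlaps it, 0 otherwise. By default any nonzero overlap
#' counts; `min_overlap_frac = 0.5` switches to a majority-overlap rule.
#'
#' @param ann An [annotation_set()] on the recording's time base.
#' @param frames A [frame_signal()] result (or a numeric vector of frame
#'   start times in seconds).
#' @param min_overlap_frac Minimum fraction of the subframe that must be
#'   covered; 0 means any nonzero overlap.
#' @return n_frames x 6 binary matrix with attribute `frame_starts`.
#' @export
intervals_to_labels <- function(ann, frames, min_overlap_frac = 0) {
  starts <- if (is.list(frames)) frames$frame_starts else as.numeric(frames)
  nf <- length(starts)
  lab <- matrix(0L, nrow = nf, ncol = .N_SUBFRAMES)
  if (nf > 0L && nrow(ann) > 0L) {
    sub_on <- rep(starts, each = .N_SUBFRAMES) +
      rep((0:(.N_SUBFRAMES - 1L)) * .SUBFRAME_S, nf)
    sub_off <- sub_on + .SUBFRAME_S
    need <- max(min_overlap_frac * .SUBFRAME_S, 1e-9)
    hit <- logical(length(sub_on))
    for (i in seq_len(nrow(ann))) {
      ov <- pmin(sub_off, ann$offset[i]) - pmax(sub_on, ann$onset[i])
      hit <- hit | (ov >= need)
    }
    lab <- matrix(as.integer(hit), nrow = nf, ncol = .N_SUBFRAMES, byrow = TRUE)
  }
  attr(lab, "frame_starts") <- starts
  lab
}

#' Binary/confidence timeline on the 0.16 s subframe grid
#'
#' @param values Per-bin values (binary truth or fused confidences).
#' @param start Start time of bin 0 in seconds.
#' @param bin_width Bin width in seconds.
#' @return A list of class `timeline`.
#' @export
timeline <- function(values, start = 0, bin_width = .SUBFRAME_S) {
  structure(list(values = as.numeric(values), start = start,
                 bin_width = bin_width),
            class = "timeline")
}

#' @export
print.timeline <- function(x, ...) {
  cat(sprintf("<timeline> %d bins of %.2f s from t=%.2f s (%.1f%% positive at 0.5)\n",
              length(x$values), x$bin_width, x$start,
              100 * mean(x$values > 0.5)))
  invisible(x)
}

#' Fuse per-frame subframe vectors into a single timeline
#'
#' With the canonical 0.48 s hop each frame spans six 0.16 s bins and
#' consecutive frames are offset by three bins, so every interior bin is
#' covered by exactly two frames. The fused confidence is the arithmetic
#' mean of the covering frames' values (`method = "mean"`), or their
#' maximum (`method = "or"`); bins covered once (the first and last three)
#' pass through unchanged.
#'
#' @param labels n_frames x 6 matrix of subframe values (binary or
#'   confidences) with a `frame_starts` attribute, as produced by
#'   [intervals_to_labels()] or by head prediction.
#' @param frame_starts Frame start times in seconds, if not attached.
#' @param method `"mean"` or `"or"`.
#' @return A [timeline()] starting at the first frame's start.
#' @export
fuse_overlapping_frames <- function(labels, frame_starts = NULL,
                                    method = c("mean", "or")) {
  method <- match.arg(method)
  starts <- frame_starts %||% attr(labels, "frame_starts")
  if (is.null(starts)) stop("frame_starts required")
  nf <- nrow(labels)
  if (nf == 0L) return(timeline(numeric(0)))
  hop_bins <- diff(starts) / .SUBFRAME_S
  if (nf > 1L && any(abs(hop_bins - 3) > 1e-6))
    stop("frames are not on the canonical 0.48 s hop grid")
  n_bins <- 3L * (nf - 1L) + .N_SUBFRAMES
  acc <- numeric(n_bins); cnt <- numeric(n_bins); mx <- numeric(n_bins)
  for (k in seq_len(nf)) {
    b <- (3L * (k - 1L) + 1L):(3L * (k - 1L) + .N_SUBFRAMES)
    acc[b] <- acc[b] + labels[k, ]
    mx[b] <- pmax(mx[b], labels[k, ])
    cnt[b] <- cnt[b] + 1
  }
  vals <- if (method == "mean") acc / cnt else mx
  timeline(vals, start = starts[1L])
}

#' Decode a confidence timeline into predicted swallow intervals
#'
#' Bins with confidence strictly above the threshold (default 0.5) are
#' predicted swallow bins; maximal runs of consecutive positive bins become
#' half-open intervals on the 0.16 s grid.
#'
#' @param tl A [timeline()] of confidences.
#' @param threshold Decision threshold in `(0, 1)`; strict `>`.
#' @param recording_id Identifier for the returned set.
#' @return An [annotation_set()] of predicted intervals.
#' @export
decode_intervals <- function(tl, threshold = 0.5, recording_id = "rec") {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  pos <- tl$values > threshold
  if (!length(pos) || !any(pos))
    return(annotation_set(recording_id = recording_id))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts_i <- ends - r$lengths + 1L
  keep <- r$values
  onset <- tl$start + (starts_i[keep] - 1L) * tl$bin_width
  offset <- tl$start + ends[keep] * tl$bin_width
  annotation_set(onset, offset, recording_id)
}

#' Rasterize swallow intervals onto the subframe grid
#'
#' Ground-truth counterpart of the fused prediction timeline: bin b
#' (spanning `[start + 0.16 b, start + 0.16 (b+1))`) is 1 when any interval
#' overlaps it.
#'
#' @param ann An [annotation_set()].
#' @param n_bins Number of bins.
#' @param start Start time of bin 0 in seconds.
#' @param bin_width Bin width in seconds.
#' @return A binary [timeline()].
#' @export
intervals_to_bins <- function(ann, n_bins, start = 0,
                              bin_width = .SUBFRAME_S) {
  v <- numeric(n_bins)
  if (nrow(ann) > 0L && n_bins > 0L) {
    bin_on <- start + (seq_len(n_bins) - 1L) * bin_width
    bin_off <- bin_on + bin_width
    for (i in seq_len(nrow(ann))) {
      ov <- pmin(bin_off, ann$offset[i]) - pmax(bin_on, ann$onset[i])
      v[ov >= 1e-9] <- 1
    }
  }
  timeline(v, start = start, bin_width = bin_width)
}
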