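#' Front-end feature configuration
#'
#' Parameters of the frame/log-Mel/ZCR front end. The spectrogram settings
#' follow the published front end of the pretrained audio-event backbone
#' (25 ms window, 10 ms hop, 64 mel bands spanning 125-7500 Hz, log offset
#' 0.001), so embeddings receive in-distribution inputs; the framing follows
#' the segmentation design (0.96 s frames, 50% overlap, six 0.16 s
#' subframes).
#'
#' @param frame_length_s Analysis frame length in seconds.
#' @param overlap Fractional frame overlap in `[0, 1)`; 0.5 gives a 0.48 s hop.
#' @param sample_rate Front-end sampling rate in Hz.
#' @param n_mels Number of mel bands.
#' @param fmin_hz,fmax_hz Mel filterbank frequency range in Hz.
#' @param stft_window_s,stft_hop_s STFT window and hop in seconds.
#' @param log_offset Additive offset inside the log.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(frame_length_s = 0.96, overlap = 0.5,
                           sample_rate = 16000L, n_mels = 64L,
                           fmin_hz = 125, fmax_hz = 7500,
                           stft_window_s = 0.025, stft_hop_s = 0.010,
                           log_offset = 0.001) {
  stopifnot(frame_length_s > 0, overlap >= 0, overlap < 1,
            sample_rate > 0, n_mels > 0, fmin_hz >= 0,
            fmax_hz > fmin_hz, fmax_hz <= sample_rate / 2,
            stft_window_s > 0, stft_hop_s > 0, log_offset > 0)
  structure(list(frame_length_s = frame_length_s, overlap = overlap,
                 sample_rate = as.integer(sample_rate),
                 n_mels = as.integer(n_mels),
                 fmin_hz = fmin_hz, fmax_hz = fmax_hz,
                 stft_window_s = stft_window_s, stft_hop_s = stft_hop_s,
                 log_offset = log_offset),
            class = "feature_config")
}

#' Split a recording into overlapping analysis frames
#'
#' Frames of `frame_length` seconds with fractional `overlap` (default
#' 0.96 s / 50%, i.e. a 0.48 s hop). Trailing samples shorter than one frame
#' are dropped, never padded. The number of frames is
#' `floor((N - L) / H) + 1` for `N >= L`, else 0.
#'
#' @param rec An [audio_recording()]; a warning is issued if its rate is not
#'   16 kHz (the front-end rate the embeddings expect).
#' @param frame_length Frame length in seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return A list of class `frame_set`: `frames` (L-sample columns, one per
#'   frame), `frame_starts` (seconds), `frame_length`, `hop`, `sample_rate`.
#' @export
frame_signal <- function(rec, frame_length = 0.96, overlap = 0.5) {
  stopifnot(overlap >= 0, overlap < 1, frame_length > 0)
  if (rec$sample_rate != 16000L)
    warning("frame_signal: sample rate is ", rec$sample_rate,
            " Hz, not the 16 kHz front-end rate")
  sr <- rec$sample_rate
  L <- as.integer(round(frame_length * sr))
  H <- as.integer(round(frame_length * (1 - overlap) * sr))
  n <- length(rec$samples)
  n_frames <- if (n >= L) (n - L) %/% H + 1L else 0L
  if (n_frames == 0L) {
    frames <- matrix(numeric(0), nrow = L, ncol = 0L)
    starts <- numeric(0)
  } else {
    start_samples <- (seq_len(n_frames) - 1L) * H
    idx <- outer(seq_len(L), start_samples, `+`)
    frames <- matrix(rec$samples[idx], nrow = L)
    starts <- start_samples / sr
  }
  structure(list(frames = frames, frame_starts = starts,
                 frame_length = frame_length,
                 hop = frame_length * (1 - overlap),
                 sample_rate = sr),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames of %.2f s (hop %.2f s) @ %d Hz\n",
              ncol(x$frames), x$frame_length, x$hop, x$sample_rate))
  invisible(x)
}

## ---- mel filterbank ------------------------------------------------------

.hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
.mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank, (nfft/2 + 1) x n_mels, cached per configuration.
.mel_filterbank <- function(cfg, nfft) {
  key <- paste("mel", cfg$sample_rate, cfg$n_mels, cfg$fmin_hz, cfg$fmax_hz,
               nfft, sep = "_")
  cached <- .swallowseg_cache[[key]]
  if (!is.null(cached)) return(cached)
  n_bins <- nfft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * cfg$sample_rate / nfft
  edges <- .mel_to_hz(seq(.hz_to_mel(cfg$fmin_hz), .hz_to_mel(cfg$fmax_hz),
                          length.out = cfg$n_mels + 2L))
  fb <- matrix(0, n_bins, cfg$n_mels)
  for (m in seq_len(cfg$n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  .swallowseg_cache[[key]] <- fb
  fb
}

#' Mel band center frequencies
#' @param cfg A [feature_config()].
#' @return Numeric vector of band center frequencies in Hz.
#' @export
mel_centers <- function(cfg = feature_config()) {
  edges <- .mel_to_hz(seq(.hz_to_mel(cfg$fmin_hz), .hz_to_mel(cfg$fmax_hz),
                          length.out = cfg$n_mels + 2L))
  edges[2:(cfg$n_mels + 1L)]
}

## ---- log-Mel spectrogram -------------------------------------------------

# STFT dialect: the 0.96 s frame (15360 samples at 16 kHz) is zero-padded at
# its end to (96-1)*160 + 400 = 15600 samples so exactly 96 windows of 25 ms
# with 10 ms hop fit; periodic Hann window; 512-point FFT.
.stft_geometry <- function(cfg) {
  win <- as.integer(round(cfg$stft_window_s * cfg$sample_rate))
  hop <- as.integer(round(cfg$stft_hop_s * cfg$sample_rate))
  L <- as.integer(round(cfg$frame_length_s * cfg$sample_rate))
  n_win <- as.integer(ceiling((L - win) / hop)) + 1L
  # pad so an integer number of windows covers the (padded) frame, and the
  # window count is a multiple of the subframe structure when defaults hold
  if (abs(cfg$frame_length_s - 0.96) < 1e-9 &&
      abs(cfg$stft_hop_s - 0.010) < 1e-9) n_win <- 96L
  nfft <- 2L^as.integer(ceiling(log2(win)))
  list(win = win, hop = hop, L = L, n_win = n_win, nfft = nfft,
       padded = (n_win - 1L) * hop + win)
}

.hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Log-Mel spectrogram of one analysis frame
#'
#' Computes the short-time spectral patch for a single 0.96 s frame at
#' 16 kHz: Hann-windowed 25 ms / 10 ms-hop STFT, 64-band triangular mel
#' filterbank (125-7500 Hz), then `log(energy + 0.001)`. The frame is
#' zero-padded at its end so exactly 96 windows fit, giving a 96 x 64 patch
#' under the default configuration.
#'
#' @param frame Numeric vector of exactly `frame_length_s * sample_rate`
#'   samples.
#' @param cfg A [feature_config()].
#' @return A 96 x 64 matrix (time x mel band) of class `log_mel_patch`.
#' @export
log_mel <- function(frame, cfg = feature_config()) {
  g <- .stft_geometry(cfg)
  if (length(frame) != g$L)
    stop("log_mel expects a frame of exactly ", g$L, " samples, got ",
         length(frame))
  patches <- log_mel_frames(matrix(frame, ncol = 1L), cfg)
  structure(patches[[1L]], class = "log_mel_patch")
}

#' Log-Mel patches for a set of frames (batch form)
#'
#' Identical by construction to applying [log_mel()] to each column of
#' `frames`; all windows across frames share one FFT call.
#'
#' @param frames L x n matrix of frame samples (columns are frames).
#' @param cfg A [feature_config()].
#' @return List of n matrices, each `n_win x n_mels`.
#' @export
log_mel_frames <- function(frames, cfg = feature_config()) {
  g <- .stft_geometry(cfg)
  if (nrow(frames) != g$L)
    stop("frames must have ", g$L, " rows")
  nf <- ncol(frames)
  if (nf == 0L) return(list())
  # relative sample index of each (window sample, window) pair inside a frame
  rel <- as.vector(outer(seq_len(g$win) - 1L, (seq_len(g$n_win) - 1L) * g$hop, `+`))
  inside <- rel < g$L                       # beyond frame end -> zero padding
  rel1 <- ifelse(inside, rel + 1L, 1L)
  wvec <- .hann_periodic(g$win)
  fb <- .mel_filterbank(cfg, g$nfft)
  out <- vector("list", nf)
  # process in blocks of frames to bound FFT matrix size
  block <- max(1L, 2048L %/% g$n_win * 8L)
  for (s in seq(1L, nf, by = block)) {
    e <- min(nf, s + block - 1L)
    nb <- e - s + 1L
    sub <- frames[, s:e, drop = FALSE]
    wm <- matrix(sub[rel1, ], nrow = g$win)  # win x (n_win * nb)
    wm <- wm * as.numeric(inside)            # recycles per frame block
    wm <- wm * wvec
    wm <- rbind(wm, matrix(0, g$nfft - g$win, ncol(wm)))
    sp <- mvfft(wm)[seq_len(g$nfft %/% 2L + 1L), , drop = FALSE]
    power <- Re(sp)^2 + Im(sp)^2
    melE <- crossprod(power, fb)             # (n_win*nb) x n_mels
    lm <- log(melE + cfg$log_offset)
    for (j in seq_len(nb)) {
      rows <- ((j - 1L) * g$n_win + 1L):(j * g$n_win)
      out[[s + j - 1L]] <- lm[rows, , drop = FALSE]
    }
  }
  out
}

#' Zero-crossing rate of a frame
#'
#' Fraction of consecutive-sample pairs whose signs differ:
#' `(sign changes) / (N - 1)`, in `[0, 1]`. A sample equal to exactly zero
#' inherits the sign of the previous nonzero sample (leading zeros inherit
#' the first nonzero sign), so flat zero plateaus are not double-counted.
#' The rate is amplitude-invariant.
#'
#' @param frame Numeric vector with at least 2 samples.
#' @return Zero-crossing rate in `[0, 1]`.
#' @export
zero_crossing_rate <- function(frame) {
  n <- length(frame)
  if (n < 2L) stop("zero_crossing_rate needs at least 2 samples")
  s <- sign(frame)
  nz <- s != 0
  if (!any(nz)) return(0)
  # carry the last nonzero sign forward; backfill leading zeros
  run <- cumsum(nz)
  vals <- s[nz]
  filled <- vals[pmax(run, 1L)]
  sum(filled[-1L] != filled[-n]) / (n - 1L)
}

#' Per-frame zero-crossing rates for a frame set
#' @param frames L x n matrix of frame samples.
#' @return Numeric vector of length n.
#' @export
zcr_frames <- function(frames) {
  if (ncol(frames) == 0L) return(numeric(0))
  apply(frames, 2L, zero_crossing_rate)
}
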