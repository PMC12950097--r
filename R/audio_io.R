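#' Audio recording container
#'
#' A single-channel sampled waveform with its sample rate and provenance
#' metadata. This is the raw input of the segmentation pipeline.
#'
#' @param samples Numeric vector of amplitude values (dimensionless).
#' @param sample_rate Sampling rate in Hz (positive).
#' @param recording_id Opaque identifier, used to join audio with
#'   annotations and metadata.
#' @param feeding_type One of `"bottle"`, `"breast"`, `"unknown"`.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate, recording_id = "rec",
                            feeding_type = c("unknown", "bottle", "breast")) {
  feeding_type <- match.arg(feeding_type)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (!is.numeric(samples)) stop("samples must be numeric")
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.integer(round(sample_rate)),
         recording_id = as.character(recording_id),
         feeding_type = feeding_type),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording '%s'> %d samples @ %d Hz (%.2f s), feeding_type=%s\n",
              x$recording_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$feeding_type))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `audio_recording`.
#' @return Duration in seconds.
#' @export
duration <- function(rec) length(rec$samples) / rec$sample_rate

## ---- WAV (RIFF) reading and writing -------------------------------------
## No WAV codec ships with the installed R stack, so a minimal RIFF reader/
## writer is implemented here: PCM 16/24-bit and IEEE float32, mono/stereo.

.wav_u32 <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "little")
.wav_u16 <- function(con) readBin(con, "integer", 1L, size = 2L, endian = "little",
                                  signed = FALSE)

#' Load a WAV file
#'
#' Reads a RIFF/WAV file (PCM 16- or 24-bit, or IEEE float32). Multi-channel
#' audio is averaged to mono, matching the single-microphone recording setup
#' this pipeline targets.
#'
#' @param path Path to a WAV file.
#' @param recording_id Identifier for the returned recording; defaults to the
#'   file name without extension.
#' @param feeding_type Feeding type metadata to attach.
#' @return An [audio_recording()] with the file's native sample rate.
#' @export
load_audio <- function(path, recording_id = NULL, feeding_type = "unknown") {
  if (!file.exists(path)) stop("cannot read audio file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(.wav_u32(con))
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAV file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    id <- rawToChar(id)
    size <- .wav_u32(con)
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = .wav_u16(con),
        n_channels   = .wav_u16(con),
        sample_rate  = .wav_u32(con),
        byte_rate    = .wav_u32(con),
        block_align  = .wav_u16(con),
        bits         = .wav_u16(con)
      )
      extra <- size - 16L
      if (extra > 0L) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path)

  x <- .wav_decode(data_raw, fmt, path)
  if (fmt$n_channels > 1L) {
    x <- matrix(x, nrow = fmt$n_channels)
    x <- colMeans(x)
  }
  if (is.null(recording_id))
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  audio_recording(x, fmt$sample_rate, recording_id, feeding_type)
}

.wav_decode <- function(raw, fmt, path) {
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(raw, "integer", length(raw) %/% 2L, size = 2L,
            endian = "little", signed = TRUE) / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(raw) %/% 3L
    b <- as.integer(raw)
    dim(b) <- c(3L, n)
    v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(raw, "double", length(raw) %/% 4L, size = 4L, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding in %s: format=%d bits=%d",
                 path, fmt$audio_format, fmt$bits))
  }
}

#' Write a recording to a WAV file
#'
#' @param rec An [audio_recording()] (or numeric vector with `sample_rate`).
#' @param path Output path.
#' @param bit_depth 16 (PCM, default) or 32 (IEEE float).
#' @param sample_rate Required when `rec` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_audio <- function(rec, path, bit_depth = 16L, sample_rate = NULL) {
  if (is.numeric(rec)) {
    if (is.null(sample_rate)) stop("sample_rate required for a bare vector")
    rec <- audio_recording(rec, sample_rate)
  }
  x <- rec$samples
  sr <- rec$sample_rate
  if (bit_depth == 16L) {
    fmt_code <- 1L
    pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    payload <- writeBin(pcm, raw(), size = 2L, endian = "little")
  } else if (bit_depth == 32L) {
    fmt_code <- 3L
    payload <- writeBin(x, raw(), size = 4L, endian = "little")
  } else stop("bit_depth must be 16 or 32")

  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(payload)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(as.integer(sr), con, size = 4L, endian = "little")
  writeBin(as.integer(sr * bit_depth / 8L), con, size = 4L, endian = "little")
  writeBin(as.integer(bit_depth / 8L), con, size = 2L, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4L, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

## ---- Resampling and normalization ---------------------------------------

#' Resample a recording
#'
#' Rational-ratio sample-rate conversion by Kaiser-window FIR polyphase
#' interpolation/decimation (the method used to bring 44.1 kHz recordings to
#' the 16 kHz front-end rate). Filter length is `2 * 10 * max(L, M) + 1` taps
#' with a Kaiser beta of 5, cutoff at the lower of the two Nyquist
#' frequencies.
#'
#' @param rec An [audio_recording()].
#' @param target_rate Target sampling rate in Hz.
#' @return An [audio_recording()] at `target_rate`. Output length is the
#'   rounded length ratio (implementations may differ by one sample at the
#'   edges).
#' @export
resample_audio <- function(rec, target_rate) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop("target_rate must be a single positive number")
  target_rate <- as.integer(round(target_rate))
  if (target_rate == rec$sample_rate) return(rec)
  g <- .gcd(rec$sample_rate, target_rate)
  L <- target_rate %/% g     # upsampling factor
  M <- rec$sample_rate %/% g # downsampling factor
  h <- .kaiser_lowpass(L, M)
  n_out <- as.integer(round(length(rec$samples) * L / M))
  y <- upfirdn_resample(rec$samples, h, L, M, n_out)
  audio_recording(y, target_rate, rec$recording_id, rec$feeding_type)
}

.gcd <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

.kaiser_lowpass <- function(L, M) {
  half <- 10L * max(L, M)
  n <- 2L * half + 1L
  k <- seq_len(n) - 1L - half
  f0 <- 1 / max(L, M)                      # cycles/sample in upsampled domain
  hs <- f0 * .sinc(f0 * k)
  h <- hs * signal::kaiser(n, beta = 5)
  h * L / sum(hs)                          # unity DC gain after upsampling
}

.sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Peak-normalize a recording
#'
#' Scales samples so amplitudes lie in \[-1, 1\] with peak magnitude exactly 1.
#' An all-zero (silent) recording is returned unchanged.
#'
#' @param rec An [audio_recording()].
#' @return The normalized [audio_recording()].
#' @export
normalize_audio <- function(rec) {
  peak <- max(abs(rec$samples))
  if (peak == 0) return(rec)
  rec$samples <- rec$samples / peak
  rec
}

## ---- Swallow interval annotations ---------------------------------------

#' Swallow interval annotation set
#'
#' Onset/offset times (seconds, half-open `[onset, offset)`, 0-based from
#' recording start) of individual swallows. Intervals are sorted by onset and
#' overlapping intervals are merged, so a canonical set is non-overlapping.
#'
#' @param onset,offset Numeric vectors of equal length; `offset > onset`.
#' @param recording_id Identifier of the annotated recording.
#' @return A data frame of class `annotation_set` with columns `onset`,
#'   `offset`.
#' @export
annotation_set <- function(onset = numeric(), offset = numeric(),
                           recording_id = "rec") {
  if (length(onset) != length(offset))
    stop("onset and offset must have equal length")
  bad <- which(!(offset > onset))
  if (length(bad))
    stop("invalid interval (offset <= onset) at row ", bad[1L])
  if (any(onset < 0)) stop("onsets must be >= 0")
  o <- order(onset, offset)
  onset <- onset[o]; offset <- offset[o]
  # canonical merge pass over overlapping intervals
  if (length(onset) > 1L) {
    keep_on <- onset[1L]; keep_off <- offset[1L]
    on_out <- numeric(); off_out <- numeric()
    for (i in seq_along(onset)[-1L]) {
      if (onset[i] < keep_off) {
        keep_off <- max(keep_off, offset[i])
      } else {
        on_out <- c(on_out, keep_on); off_out <- c(off_out, keep_off)
        keep_on <- onset[i]; keep_off <- offset[i]
      }
    }
    onset <- c(on_out, keep_on); offset <- c(off_out, keep_off)
  }
  structure(data.frame(onset = onset, offset = offset),
            recording_id = as.character(recording_id),
            class = c("annotation_set", "data.frame"))
}

#' Read swallow annotations
#'
#' Accepts the canonical CSV dialect (header `onset_s,offset_s[,label]`) and,
#' read-only, Audacity label-track TSV (`onset<TAB>offset<TAB>text`, no
#' header).
#'
#' @param path Path to an annotation file.
#' @param recording_id Identifier; defaults to the file name.
#' @return An [annotation_set()], sorted and validated.
#' @export
read_annotations <- function(path, recording_id = NULL) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  if (is.null(recording_id))
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop("annotation file has no header: ", path)
  if (grepl("onset_s", first, fixed = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("onset_s", "offset_s") %in% names(df)))
      stop("annotation CSV must have columns onset_s, offset_s: ", path)
    onset <- as.numeric(df$onset_s); offset <- as.numeric(df$offset_s)
  } else if (grepl("\t", first, fixed = TRUE) || !grepl(",", first, fixed = TRUE)) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("Audacity label track needs >= 2 columns: ", path)
    onset <- as.numeric(df[[1L]]); offset <- as.numeric(df[[2L]])
  } else {
    stop("unrecognized annotation format (no onset_s header): ", path)
  }
  if (anyNA(onset) || anyNA(offset))
    stop("non-numeric onset/offset in ", path)
  bad <- which(!(offset > onset))
  if (length(bad))
    stop("offset <= onset at row ", bad[1L], " of ", path)
  annotation_set(onset, offset, recording_id)
}

#' Write swallow annotations
#'
#' Writes the canonical CSV dialect (`onset_s,offset_s`) at 6 decimal places,
#' so write -> read round-trips exactly at that precision.
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(onset_s = sprintf("%.6f", ann$onset),
                   offset_s = sprintf("%.6f", ann$offset))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
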