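#' Synthetic feeding-audio configuration
#'
#' Parameters of the labeled synthetic cervical-auscultation generator. The
#' generator emulates the acoustic scene of a neonatal feeding observation:
#' breathing-modulated low-frequency background noise, quasi-periodic short
#' sucking transients, and band-limited "fluid flushing" swallow bursts with
#' an asymmetric attack/decay envelope, at a calibrated event-to-background
#' SNR. Ground-truth intervals equal the burst supports exactly.
#'
#' @param duration Recording length in seconds (default 120, a two-minute
#'   feeding observation).
#' @param sample_rate Generation rate in Hz (default 44100, so the
#'   resampling front end is exercised).
#' @param swallow_rate Swallow events per second (candidate rate of the
#'   thinned point process).
#' @param swallow_duration_range Swallow duration range in seconds.
#' @param swallow_band Swallow burst frequency band in Hz.
#' @param snr_db Event-to-background RMS power ratio in dB.
#' @param suck_rate Sucking transients per second.
#' @param breathing_rate Breathing amplitude-modulation rate in Hz.
#' @param min_gap Minimum gap between swallow intervals in seconds.
#' @param confounder_rate Rate of unlabeled low-level confounder bursts
#'   (events/s), emulating quiet non-nutritive/saliva swallows; 0 disables.
#' @param confounder_level_db Confounder level relative to `snr_db` in dB
#'   (negative = quieter).
#' @param seed Integer seed; generation is fully deterministic.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration = 120, sample_rate = 44100L,
                         swallow_rate = 0.4,
                         swallow_duration_range = c(0.2, 0.8),
                         swallow_band = c(300, 3000), snr_db = 10,
                         suck_rate = 1.5, breathing_rate = 1.0,
                         min_gap = 0.2, confounder_rate = 0,
                         confounder_level_db = -6, seed = 1L) {
  stopifnot(duration > 0, sample_rate > 0, swallow_rate >= 0,
            suck_rate >= 0, breathing_rate >= 0, min_gap >= 0,
            confounder_rate >= 0,
            length(swallow_duration_range) == 2L,
            swallow_duration_range[1L] > 0,
            swallow_duration_range[1L] <= swallow_duration_range[2L],
            length(swallow_band) == 2L, swallow_band[1L] > 0,
            swallow_band[1L] < swallow_band[2L],
            swallow_band[2L] < sample_rate / 2)
  if (swallow_rate * (swallow_duration_range[2L] + min_gap) >= 0.9)
    stop("infeasible swallow density: rate x (max duration + gap) = ",
         round(swallow_rate * (swallow_duration_range[2L] + min_gap), 2),
         " is too close to 1")
  structure(list(duration = duration, sample_rate = as.integer(sample_rate),
                 swallow_rate = swallow_rate,
                 swallow_duration_range = swallow_duration_range,
                 swallow_band = swallow_band, snr_db = snr_db,
                 suck_rate = suck_rate, breathing_rate = breathing_rate,
                 min_gap = min_gap, confounder_rate = confounder_rate,
                 confounder_level_db = confounder_level_db,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Draw swallow intervals from the thinned point process
#'
#' Candidate onsets arrive as a Poisson process at `rate` with durations
#' uniform in `swallow_duration_range`; candidates are visited in onset
#' order and kept only if they start at least `min_gap` after the previous
#' kept interval's offset, end within the recording, and (optionally) keep
#' `min_gap` clearance from a set of intervals to avoid.
#'
#' @param cfg A [synth_config()].
#' @param rate Candidate event rate; defaults to `cfg$swallow_rate`.
#' @param avoid Optional [annotation_set()] the drawn intervals must not
#'   approach within `min_gap`.
#' @return An [annotation_set()] of kept intervals. Uses the current RNG
#'   state (callers seed it).
#' @export
draw_swallow_intervals <- function(cfg, rate = cfg$swallow_rate,
                                   avoid = NULL) {
  n_cand <- rpois(1L, rate * cfg$duration)
  if (n_cand == 0L) return(annotation_set())
  onset <- sort(runif(n_cand, 0, cfg$duration))
  dur <- runif(n_cand, cfg$swallow_duration_range[1L],
               cfg$swallow_duration_range[2L])
  keep_on <- numeric(); keep_off <- numeric()
  last_off <- -Inf
  for (i in seq_len(n_cand)) {
    off <- onset[i] + dur[i]
    if (onset[i] < last_off + cfg$min_gap || off > cfg$duration) next
    if (!is.null(avoid) && nrow(avoid) > 0L) {
      clash <- any(onset[i] < avoid$offset + cfg$min_gap &
                     off > avoid$onset - cfg$min_gap)
      if (clash) next
    }
    keep_on <- c(keep_on, onset[i]); keep_off <- c(keep_off, off)
    last_off <- off
  }
  if (!length(keep_on)) return(annotation_set())
  annotation_set(keep_on, keep_off)
}

# Spectrally shaped noise: white noise whose FFT is multiplied by a
# frequency-magnitude mask, returned in the time domain. Synthesis runs at
# the next power-of-two length (R's mixed-radix FFT is slow on lengths with
# large prime factors) and is truncated to n.
.shaped_noise <- function(n, sr, mask_fn) {
  n2 <- 2L^as.integer(ceiling(log2(n)))
  x <- rnorm(n2)
  X <- fft(x)
  k <- as.numeric(0:(n2 - 1L))
  f <- pmin(k, n2 - k) * sr / n2
  (Re(fft(X * mask_fn(f), inverse = TRUE)) / n2)[seq_len(n)]
}

.bandpass_mask <- function(lo, hi) {
  force(lo); force(hi)
  function(f) as.numeric(f >= lo & f <= hi)
}

# Asymmetric burst envelope: fast half-cosine attack over the first 20% of
# the event, exponential decay to ~15% of peak by the offset.
.burst_envelope <- function(m) {
  attack <- max(2L, as.integer(round(0.2 * m)))
  env <- rep(1, m)
  env[seq_len(attack)] <- 0.5 - 0.5 * cos(pi * seq_len(attack) / attack)
  decay <- exp(-(seq_len(m) - attack) / (0.45 * m))
  env[(attack + 1L):m] <- decay[(attack + 1L):m]
  env
}

#' Generate one synthetic labeled feeding recording
#'
#' Builds the background (breathing-modulated low-pass noise plus periodic
#' sucking clicks), draws swallow intervals from the thinned point process,
#' and adds one band-limited asymmetric-envelope noise burst per interval,
#' scaled so that the within-interval signal power exceeds the local
#' background power by `snr_db` dB. Unlabeled confounder bursts (if
#' configured) are added at a lower level and kept clear of the labeled
#' intervals. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param recording_id Identifier for the recording.
#' @param feeding_type Feeding type metadata.
#' @return A list of class `synth_recording`: `recording`
#'   ([audio_recording()]), `truth` ([annotation_set()]), `config_used`.
#' @export
generate_recording <- function(cfg = synth_config(), recording_id = "synth",
                               feeding_type = "bottle") {
  set.seed(cfg$seed)
  sr <- cfg$sample_rate
  n <- as.integer(round(cfg$duration * sr))

  # breathing background: low-pass filtered noise (4th-order Butterworth at
  # 900 Hz, one-pass IIR) plus a light broadband floor, amplitude-modulated
  # at the breathing rate
  white <- rnorm(n)
  bt <- signal::butter(4, 900 / (sr / 2), type = "low")
  bg <- as.numeric(signal::filter(bt, white)) + 0.03 * white
  tt <- (seq_len(n) - 1L) / sr
  if (cfg$breathing_rate > 0) {
    phase <- runif(1L, 0, 2 * pi)
    bg <- bg * (1 + 0.8 * sin(2 * pi * cfg$breathing_rate * tt + phase)) / 1.8
  }
  bg <- bg / sqrt(mean(bg^2)) * 0.05

  # quasi-periodic sucking transients (short damped band-limited clicks)
  if (cfg$suck_rate > 0) {
    period <- 1 / cfg$suck_rate
    times <- cumsum(c(runif(1L, 0, period),
                      period * (1 + 0.15 * rnorm(ceiling(cfg$duration / period) + 5L))))
    times <- times[times < cfg$duration - 0.02]
    click_len <- as.integer(round(0.008 * sr))
    bg_sd <- sqrt(mean(bg^2))
    for (tc in times) {
      i0 <- as.integer(round(tc * sr)) + 1L
      click <- .shaped_noise(click_len, sr, .bandpass_mask(1000, 6000)) *
        exp(-(seq_len(click_len) - 1L) / (0.002 * sr))
      click <- click / max(abs(click)) * 3 * bg_sd
      idx <- i0:(i0 + click_len - 1L)
      bg[idx] <- bg[idx] + click
    }
  }

  x <- bg
  pb_global <- mean(bg^2)
  truth <- draw_swallow_intervals(cfg)
  # each burst is scaled so the total within-interval power equals the
  # global background power times 10^(snr/10); calibrating against the
  # global (not local) background keeps the measured recording-level SNR
  # tight even though the breathing modulation makes the local background
  # power swing widely across the cycle
  make_burst <- function(onset, offset, snr_db) {
    i0 <- as.integer(floor(onset * sr)) + 1L
    i1 <- min(as.integer(ceiling(offset * sr)), n)
    burst <- .shaped_noise(i1 - i0 + 1L, sr,
                           .bandpass_mask(cfg$swallow_band[1L],
                                          cfg$swallow_band[2L])) *
      .burst_envelope(i1 - i0 + 1L)
    target <- max(pb_global * 10^(snr_db / 10) - mean(bg[i0:i1]^2),
                  0.25 * pb_global)
    a <- sqrt(target / mean(burst^2))
    list(idx = i0:i1, values = a * burst)
  }
  if (nrow(truth) > 0L)
    for (i in seq_len(nrow(truth))) {
      bu <- make_burst(truth$onset[i], truth$offset[i], cfg$snr_db)
      x[bu$idx] <- x[bu$idx] + bu$values
    }

  if (cfg$confounder_rate > 0) {
    conf <- draw_swallow_intervals(cfg, rate = cfg$confounder_rate,
                                   avoid = truth)
    if (nrow(conf) > 0L)
      for (i in seq_len(nrow(conf))) {
        bu <- make_burst(conf$onset[i], conf$offset[i],
                         cfg$snr_db + cfg$confounder_level_db)
        x[bu$idx] <- x[bu$idx] + bu$values
      }
  }

  peak <- max(abs(x))
  if (peak > 0) x <- x / peak * 0.9   # headroom for 16-bit PCM; SNR unchanged

  attr(truth, "recording_id") <- recording_id
  structure(list(
    recording = audio_recording(x, sr, recording_id, feeding_type),
    truth = truth,
    config_used = cfg
  ), class = "synth_recording")
}

#' Measured event-to-background SNR of a synthetic recording
#'
#' `10 log10` of the ratio of mean squared amplitude inside the truth
#' intervals to that outside them. Returns `Inf` when the background is
#' silent.
#'
#' @param srec A `synth_recording` (or a list with `recording` and `truth`).
#' @return SNR in dB.
#' @export
measure_snr <- function(srec) {
  truth <- srec$truth
  if (is.null(truth) || nrow(truth) == 0L)
    stop("cannot measure SNR: truth interval set is empty")
  x <- srec$recording$samples
  sr <- srec$recording$sample_rate
  mask <- logical(length(x))
  for (i in seq_len(nrow(truth))) {
    i0 <- as.integer(floor(truth$onset[i] * sr)) + 1L
    i1 <- min(as.integer(ceiling(truth$offset[i] * sr)), length(x))
    mask[i0:i1] <- TRUE
  }
  pe <- mean(x[mask]^2)
  pb <- mean(x[!mask]^2)
  if (pb == 0) return(Inf)
  10 * log10(pe / pb)
}

#' Generate a corpus of synthetic labeled recordings
#'
#' Writes `n` WAV + annotation-CSV pairs, a manifest CSV (`recording_id`,
#' `feeding_type`, `seed`, `n_swallows`, `duration_s`, `snr_db`) and a YAML
#' snapshot of the generator configuration. Breast-type recordings are made
#' harder, mirroring the bottle/breast difficulty gap in real feeding audio:
#' their SNR is lowered by 4 dB and unlabeled low-level confounder bursts
#' (quiet non-nutritive/saliva-swallow stand-ins) are added. This is a
#' stylized emulation, not a validated acoustic model.
#'
#' @param out_dir Output directory (created; refuses a non-empty existing
#'   directory unless `overwrite`).
#' @param n_recordings Number of recordings (>= 1).
#' @param cfg Base [synth_config()].
#' @param seed Master seed; per-recording seeds and feeding-type assignment
#'   derive from it deterministically.
#' @param bottle_fraction Fraction of bottle-fed recordings.
#' @param overwrite Allow writing into a non-empty directory.
#' @return The manifest data frame, invisibly.
#' @export
generate_corpus <- function(out_dir, n_recordings, cfg = synth_config(),
                            seed = 1L, bottle_fraction = 0.5,
                            overwrite = FALSE) {
  stopifnot(n_recordings >= 1)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite)
    stop("output directory exists and is not empty: ", out_dir,
         " (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(seed)
  rec_seeds <- sample.int(2147483646L, n_recordings)
  n_bottle <- as.integer(floor(n_recordings * bottle_fraction + 0.5))
  types <- sample(c(rep("bottle", n_bottle),
                    rep("breast", n_recordings - n_bottle)))

  manifest <- vector("list", n_recordings)
  for (i in seq_len(n_recordings)) {
    id <- sprintf("rec%03d", i)
    cfg_i <- cfg
    cfg_i$seed <- rec_seeds[i]
    if (types[i] == "breast") {
      cfg_i$snr_db <- cfg$snr_db - 4
      cfg_i$confounder_rate <- max(cfg$confounder_rate, 0.15)
    }
    srec <- generate_recording(cfg_i, recording_id = id,
                               feeding_type = types[i])
    write_audio(srec$recording, file.path(out_dir, paste0(id, ".wav")))
    write_annotations(srec$truth, file.path(out_dir, paste0(id, ".csv")))
    manifest[[i]] <- data.frame(recording_id = id, feeding_type = types[i],
                                seed = rec_seeds[i],
                                n_swallows = nrow(srec$truth),
                                duration_s = cfg$duration,
                                snr_db = cfg_i$snr_db)
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(c(unclass(cfg),
                     list(n_recordings = n_recordings, master_seed = seed,
                          bottle_fraction = bottle_fraction)),
                   file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

#' Read a corpus manifest
#' @param corpus_dir Corpus directory produced by [generate_corpus()].
#' @return The manifest data frame.
#' @export
read_manifest <- function(corpus_dir) {
  path <- file.path(corpus_dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", corpus_dir)
  read.csv(path, stringsAsFactors = FALSE)
}
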