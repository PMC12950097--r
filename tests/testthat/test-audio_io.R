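# Write a stereo PCM16 WAV by hand (independent of the package's writer) so
# the reader's channel averaging is checked against a known byte layout.
write_stereo_wav <- function(left, right, sr, path) {
  stopifnot(length(left) == length(right))
  inter <- as.vector(rbind(left, right))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(inter * 32768))))
  payload <- writeBin(pcm, raw(), size = 2L, endian = "little")
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(as.integer(sr), con, size = 4L, endian = "little")
  writeBin(as.integer(sr * 4L), con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4L, endian = "little")
  writeBin(payload, con)
  path
}

test_that("WAV write/load round-trips within 16-bit quantization", {
  set.seed(1)
  x <- runif(4410, -0.9, 0.9)
  p <- withr::local_tempfile(fileext = ".wav")
  write_audio(audio_recording(x, 44100), p)
  rec <- load_audio(p)
  expect_equal(rec$sample_rate, 44100L)
  expect_length(rec$samples, 4410)
  expect_lt(max(abs(rec$samples - x)), 2^-15)
})

test_that("a second of silence keeps its sample count and rate", {
  p <- withr::local_tempfile(fileext = ".wav")
  write_audio(audio_recording(numeric(44100), 44100), p)
  rec <- load_audio(p)
  expect_length(rec$samples, 44100)
  expect_equal(rec$sample_rate, 44100L)
  expect_true(all(rec$samples == 0))
})

test_that("stereo input is averaged to mono; identical channels are identity", {
  set.seed(2)
  x <- runif(1000, -0.5, 0.5)
  p <- withr::local_tempfile(fileext = ".wav")
  write_stereo_wav(x, x, 16000, p)
  rec <- load_audio(p)
  expect_lt(max(abs(rec$samples - x)), 2^-15)
  # distinct channels: mean of the two decoded channels
  y <- -x
  write_stereo_wav(x, y, 16000, p)
  rec2 <- load_audio(p)
  expect_lt(max(abs(rec2$samples)), 2^-15)
})

test_that("float32 WAVs round-trip and unreadable paths error", {
  x <- sin(2 * pi * 440 * (0:999) / 16000)
  p <- withr::local_tempfile(fileext = ".wav")
  write_audio(audio_recording(x, 16000), p, bit_depth = 32L)
  expect_lt(max(abs(load_audio(p)$samples - x)), 1e-6)
  expect_error(load_audio(file.path(tempdir(), "no-such-file.wav")),
               "no-such-file")
})

test_that("resampling at the native rate is the identity", {
  rec <- sine_recording(440, dur = 0.5, sr = 16000L)
  out <- resample_audio(rec, 16000)
  expect_identical(out$samples, rec$samples)
})

test_that("44.1k -> 16k resampling has the expected length ratio", {
  rec <- audio_recording(rnorm(88200), 44100)
  out <- resample_audio(rec, 16000)
  expect_lte(abs(length(out$samples) - 32000), 1)
  expect_equal(out$sample_rate, 16000L)
})

test_that("a pure tone survives resampling with its frequency intact", {
  # FFT-peak oracle: strongest bin of the resampled tone is within 1 Hz
  rec <- sine_recording(1000, dur = 2, sr = 44100L)
  out <- resample_audio(rec, 16000)
  seg <- out$samples[1001:(1000 + 16000)]   # 1 s -> 1 Hz resolution
  spec <- abs(fft(seg))[1:8000]
  peak_hz <- which.max(spec) - 1
  expect_lte(abs(peak_hz - 1000), 1)
  expect_error(resample_audio(rec, -5), "positive")
})

test_that("resampling band-limits below the target Nyquist", {
  # a 10 kHz tone is above the 8 kHz target Nyquist and must be attenuated
  rec <- sine_recording(10000, dur = 1, sr = 44100L)
  out <- resample_audio(rec, 16000)
  expect_lt(sqrt(mean(out$samples^2)), 0.01 * sqrt(mean(rec$samples^2)))
})

test_that("normalization scales the peak to 1 and guards silence", {
  rec <- audio_recording(c(0.5, -0.25), 100)
  expect_equal(normalize_audio(rec)$samples, c(1, -0.5))
  z <- audio_recording(numeric(10), 100)
  expect_identical(normalize_audio(z)$samples, numeric(10))
  # scale invariance on random signals
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(200)
    c1 <- normalize_audio(audio_recording(x, 100))$samples
    c2 <- normalize_audio(audio_recording(runif(1, 0.1, 10) * x, 100))$samples
    expect_equal(c1, c2)
    expect_equal(max(abs(c1)), 1)
  }
})

test_that("annotation CSV reading sorts, validates and round-trips", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset_s,offset_s", "1.20,1.65", "0.10,0.40"), p)
  ann <- read_annotations(p)
  expect_equal(ann$onset, c(0.10, 1.20))
  expect_equal(ann$offset, c(0.40, 1.65))

  # empty file with header
  writeLines("onset_s,offset_s", p)
  expect_equal(nrow(read_annotations(p)), 0L)

  # invalid row cites its position
  writeLines(c("onset_s,offset_s", "2.0,1.5"), p)
  expect_error(read_annotations(p), "row 1")

  # missing columns
  writeLines(c("onset_s,end", "0,1"), p)
  expect_error(read_annotations(p), "offset_s")

  # write -> read round-trip at 6 decimals
  ann <- annotation_set(c(0.1234567, 2.5), c(1.9999999, 3.25))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, p2)
  back <- read_annotations(p2)
  expect_equal(back$onset, round(ann$onset, 6))
  expect_equal(back$offset, round(ann$offset, 6))
})

test_that("Audacity label-track TSV is accepted on read", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.200000\t1.650000\tswallow", "0.100000\t0.400000\tswallow"), p)
  ann <- read_annotations(p)
  expect_equal(ann$onset, c(0.10, 1.20))
})

test_that("overlapping intervals are merged canonically", {
  ann <- annotation_set(c(0.0, 0.5, 3.0), c(1.0, 1.5, 4.0))
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$onset, c(0.0, 3.0))
  expect_equal(ann$offset, c(1.5, 4.0))
  expect_error(annotation_set(1, 1), "offset")
})
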