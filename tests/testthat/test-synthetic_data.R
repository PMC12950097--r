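# Independent re-implementation of the thinned point process for use as a
# Monte-Carlo oracle: Poisson candidates, uniform durations, greedy keep.
thinned_count_oracle <- function(cfg) {
  n_cand <- rpois(1, cfg$swallow_rate * cfg$duration)
  if (n_cand == 0) return(0L)
  on <- sort(runif(n_cand, 0, cfg$duration))
  du <- runif(n_cand, cfg$swallow_duration_range[1], cfg$swallow_duration_range[2])
  kept <- 0L; last_off <- -Inf
  for (i in seq_len(n_cand)) {
    off <- on[i] + du[i]
    if (on[i] >= last_off + cfg$min_gap && off <= cfg$duration) {
      kept <- kept + 1L; last_off <- off
    }
  }
  kept
}

test_that("generation is bitwise deterministic in its seed", {
  cfg <- synth_config(duration = 5, seed = 99)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth$onset, b$truth$onset)
  c_ <- generate_recording(synth_config(duration = 5, seed = 100))
  expect_false(identical(a$recording$samples, c_$recording$samples))
})

test_that("zero swallow rate yields background-only audio", {
  srec <- generate_recording(synth_config(duration = 5, swallow_rate = 0,
                                          seed = 3))
  expect_equal(nrow(srec$truth), 0L)
  expect_gt(sd(srec$recording$samples), 0)
  expect_error(measure_snr(srec), "empty")
})

test_that("infeasible event density is rejected at configuration time", {
  expect_error(synth_config(swallow_rate = 1.2), "infeasible")
})

test_that("the generator hits its configured SNR within 1 dB", {
  for (s in c(6, 10)) {
    srec <- generate_recording(synth_config(duration = 30, snr_db = s,
                                            seed = 40 + s))
    expect_lt(abs(measure_snr(srec) - s), 1)
  }
})

test_that("doubling the event samples raises measured SNR by ~6.02 dB", {
  srec <- generate_recording(synth_config(duration = 30, seed = 12))
  base <- measure_snr(srec)
  x <- srec$recording$samples
  sr <- srec$recording$sample_rate
  for (i in seq_len(nrow(srec$truth))) {
    idx <- (floor(srec$truth$onset[i] * sr) + 1):
      min(ceiling(srec$truth$offset[i] * sr), length(x))
    x[idx] <- 2 * x[idx]
  }
  srec$recording$samples <- x
  expect_equal(measure_snr(srec) - base, 20 * log10(2), tolerance = 0.1)
})

test_that("silent background reports infinite SNR gracefully", {
  srec <- list(recording = audio_recording(c(numeric(100), rep(0.5, 100),
                                             numeric(100)), 100),
               truth = annotation_set(1, 2))
  expect_identical(measure_snr(srec), Inf)
})

test_that("kept event counts match the Monte-Carlo thinning oracle", {
  cfg <- synth_config(duration = 120, swallow_rate = 0.4, seed = 1)
  set.seed(500)
  expected <- mean(replicate(400, thinned_count_oracle(cfg)))
  counts <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    nrow(draw_swallow_intervals(cfg))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
  # structural invariants of every draw
  set.seed(2000)
  iv <- draw_swallow_intervals(cfg)
  expect_true(all(iv$onset >= 0 & iv$offset <= cfg$duration))
  if (nrow(iv) > 1)
    expect_true(all(iv$onset[-1] - iv$offset[-nrow(iv)] >= cfg$min_gap - 1e-9))
})

test_that("labeled bursts carry more swallow-band energy than background", {
  srec <- generate_recording(synth_config(duration = 20, seed = 21))
  rec16 <- preprocess_recording(srec$recording)
  bp <- signal::butter(4, c(300, 3000) / 8000, type = "pass")
  xb <- signal::filtfilt(bp, rec16$samples)
  sr <- 16000
  for (i in seq_len(nrow(srec$truth))) {
    on <- srec$truth$onset[i]; off <- srec$truth$offset[i]
    ev <- xb[(floor(on * sr) + 1):ceiling(off * sr)]
    # equal-length background window ending one min-gap before the onset
    bg_end <- floor((on - 0.1) * sr)
    bg <- xb[max(1, bg_end - length(ev) + 1):bg_end]
    expect_gt(mean(ev^2), mean(bg^2))
  }
})

test_that("generated audio survives the full feature pipeline", {
  srec <- generate_recording(synth_config(duration = 5, seed = 77))
  p <- withr::local_tempfile(fileext = ".wav")
  write_audio(srec$recording, p)
  rec <- preprocess_recording(load_audio(p))
  ff <- frame_features(rec)
  expect_equal(ncol(ff$features), 1025L)
  expect_gt(ff$n_frames, 0L)
  expect_true(all(is.finite(ff$features)))
})

test_that("corpus generation writes a complete, reproducible layout", {
  d1 <- withr::local_tempdir()
  m1 <- generate_corpus(file.path(d1, "c"), 5, synth_config(duration = 4),
                        seed = 31, bottle_fraction = 1.0)
  files <- list.files(file.path(d1, "c"))
  expect_length(grep("\\.wav$", files), 5L)
  expect_length(grep("^rec[0-9]+\\.csv$", files), 5L)
  expect_true("manifest.csv" %in% files)
  expect_true("config.yaml" %in% files)
  expect_equal(nrow(m1), 5L)
  expect_true(all(m1$feeding_type == "bottle"))

  # regeneration with the same master seed is file-identical
  m2 <- generate_corpus(file.path(d1, "c2"), 5, synth_config(duration = 4),
                        seed = 31, bottle_fraction = 1.0)
  expect_identical(m1, m2)
  h1 <- tools::md5sum(file.path(d1, "c", "rec003.wav"))
  h2 <- tools::md5sum(file.path(d1, "c2", "rec003.wav"))
  expect_identical(unname(h1), unname(h2))

  # refuses to clobber a non-empty directory
  expect_error(generate_corpus(file.path(d1, "c"), 2,
                               synth_config(duration = 4), seed = 1),
               "overwrite")
})

test_that("breast recordings are generated at reduced SNR", {
  d <- withr::local_tempdir()
  m <- generate_corpus(file.path(d, "c"), 4, synth_config(duration = 4),
                       seed = 8, bottle_fraction = 0.5)
  expect_setequal(unique(m$feeding_type), c("bottle", "breast"))
  expect_equal(unique(m$snr_db[m$feeding_type == "breast"]), 6)
  expect_equal(unique(m$snr_db[m$feeding_type == "bottle"]), 10)
})
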