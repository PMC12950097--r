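# Shared fixtures, built once per test run and cached in tempdir().

sine_recording <- function(freq, dur = 1, sr = 16000L, amp = 0.8) {
  audio_recording(amp * sin(2 * pi * freq * (0:(dur * sr - 1)) / sr), sr)
}

# Small labeled corpus shared by pipeline/CLI/detector tests.
tiny_corpus_dir <- local({
  path <- NULL
  function() {
    if (is.null(path)) {
      p <- file.path(tempdir(), "swallowseg-tiny-corpus")
      if (!dir.exists(p))
        generate_corpus(p, 10, synth_config(duration = 30), seed = 202,
                        bottle_fraction = 0.5)
      path <<- p
    }
    path
  }
})

# Detector fitted once on the tiny corpus (short training budget).
tiny_detector <- local({
  det <- NULL
  function() {
    if (is.null(det)) {
      rc <- default_run_config()
      rc$head$max_epochs <- 15L
      rc$head$seed <- 5L
      rc$split$seed <- 5L
      det <<- cmd_train(tiny_corpus_dir(),
                        file.path(tempdir(), "swallowseg-tiny-model.rds"),
                        config = rc, quiet = TRUE)
    }
    det
  }
})
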