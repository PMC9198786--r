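test_that("noiseless waveforms are recovered exactly with no drops", {
  rr <- simulate_rr(mouse_spectral_model(), 15, seed = 41)
  wf <- synth_waveform(rr, drift_amplitude = 0, noise_sd = 0)
  det <- detect_beats(wf)
  expect_equal(n_beats(det), n_beats(rr))
  expect_equal(attr(det, "dropped"), 0L)
  expect_lte(max(abs(det$beat_times - rr$beat_times)), 1 / wf$sample_rate)
})

test_that("detection at 5% noise keeps sensitivity and PPV above 0.99", {
  m <- mouse_spectral_model()
  sens <- ppv <- numeric(100)
  for (s in seq_len(100)) {
    rr <- simulate_rr(m, 10, seed = 500 + s)
    wf <- synth_waveform(rr, pulse_amplitude = 1, noise_sd = 0.05,
                         seed = 900 + s)
    det <- detect_beats(wf)
    res <- match_beats(det$beat_times, rr$beat_times, tol = 0.02)
    sens[s] <- res$sensitivity
    ppv[s] <- res$ppv
  }
  expect_gte(mean(sens), 0.99)
  expect_gte(mean(ppv), 0.99)
})

test_that("pure-noise waveforms raise a detection failure in >= 95% of seeds", {
  m <- mouse_spectral_model()
  fails <- 0L
  for (s in seq_len(100)) {
    rr <- simulate_rr(m, 5, seed = 1500 + s)
    wf <- synth_waveform(rr, pulse_amplitude = 0, drift_amplitude = 0,
                         noise_sd = 1, seed = 1900 + s)
    failed <- tryCatch(
      { detect_beats(wf, detector_params(threshold_k = 4)); FALSE },
      error = function(e) TRUE
    )
    fails <- fails + failed
  }
  expect_gte(fails, 95L)
})

test_that("no two detected beats are closer than the refractory period", {
  m <- mouse_spectral_model()
  pars <- detector_params(refractory = 0.05)
  for (s in 1:10) {
    rr <- simulate_rr(m, 8, seed = 2100 + s)
    wf <- synth_waveform(rr, noise_sd = 0.1, seed = 2200 + s)
    det <- tryCatch(detect_beats(wf, pars), error = function(e) NULL)
    if (!is.null(det)) expect_gte(min(det$intervals), pars$refractory)
  }
})

test_that("detection is invariant to offset and positive gain", {
  rr <- simulate_rr(mouse_spectral_model(), 10, seed = 43)
  wf <- synth_waveform(rr, noise_sd = 0.03, seed = 44)
  det0 <- detect_beats(wf)
  scaled <- pulse_waveform(17 * wf$samples + 250, wf$sample_rate,
                           wf$start_time)
  det1 <- detect_beats(scaled)
  expect_equal(det0$beat_times, det1$beat_times, tolerance = 1e-9)
})

test_that("end-to-end detection preserves the generating spectral peak", {
  m <- hf_only_mouse(1.5)
  freqs <- default_freq_grid()
  acc <- numeric(length(freqs))
  n_ok <- 0
  for (s in 1:30) {
    rr <- simulate_rr(m, 15, seed = 3000 + s)
    wf <- synth_waveform(rr, noise_sd = 0.05, seed = 3100 + s)
    det <- detect_beats(wf)
    p <- normalize_periodogram(lomb_scargle(det, freqs))
    acc <- acc + p$power
    n_ok <- n_ok + 1
  }
  peak <- freqs[which.max(acc / n_ok)]
  expect_lte(abs(peak - 1.5), 0.025 + 1e-9)
})
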