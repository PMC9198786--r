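test_that("rr_series enforces strictly increasing beat times", {
  expect_error(rr_series(c(0, 0.1, 0.1)), "strictly increasing")
  expect_error(rr_series(0.5), "at least two")
  rr <- rr_series(c(0, 0.1, 0.25))
  expect_equal(rr$intervals, c(0.1, 0.15))
  expect_equal(rr_duration(rr), 0.25)
})

test_that("prefix truncation is nested", {
  rr <- simulate_rr(mouse_spectral_model(), 30, seed = 1)
  a <- truncate_rr(truncate_rr(rr, 20), 5)
  b <- truncate_rr(rr, 5)
  expect_identical(a$beat_times, b$beat_times)
  expect_lte(rr_duration(b), 5)
  expect_error(truncate_rr(rr, 0.01), "fewer than two beats")
})

test_that("a zero-variance model yields perfectly regular beats", {
  m <- spectral_model(0.8, 2, 0.08, 0.08, 5e-4, 1e-3,
                      mean_rr = 0.1, sd_rr = 0)
  rr <- simulate_rr(m, 10, seed = 3)
  expect_equal(rr$intervals, rep(0.1, length(rr$intervals)), tolerance = 1e-12)
})

test_that("beat count and interval mean match the model", {
  m <- mouse_spectral_model()
  rr <- simulate_rr(m, 60, seed = 4)
  expect_gt(n_beats(rr), 560)
  expect_lt(n_beats(rr), 640)
  se <- stats::sd(rr$intervals) / sqrt(length(rr$intervals))
  expect_lt(abs(mean(rr$intervals) - m$mean_rr), 3 * se + 1e-3)
  # record spans to within one mean interval of the requested duration
  expect_gte(rr_duration(rr), 60 - max(rr$intervals))
})

test_that("simulation is a deterministic function of (model, duration, seed)", {
  m <- mouse_spectral_model()
  a <- simulate_rr(m, 20, seed = 99)
  b <- simulate_rr(m, 20, seed = 99)
  expect_identical(a$beat_times, b$beat_times)
  c <- simulate_rr(m, 20, seed = 100)
  expect_false(identical(a$beat_times, c$beat_times))
})

test_that("invalid durations and runaway variability are errors", {
  m <- mouse_spectral_model()
  expect_error(simulate_rr(m, 0.3, seed = 1), "too short")
  wild <- spectral_model(0.8, 2, 0.08, 0.08, 5e-4, 1e-3,
                         mean_rr = 0.1, sd_rr = 0.09)
  expect_error(simulate_rr(wild, 30, seed = 1), "sd_rr")
})

test_that("an HF-only model puts the averaged periodogram peak at f2", {
  m <- hf_only_mouse(1.5)
  freqs <- default_freq_grid()
  set.seed(11)
  mean_p <- rowMeans(replicate(200, {
    normalize_periodogram(lomb_scargle(simulate_rr(m, 20), freqs))$power
  }))
  peak <- freqs[which.max(mean_p)]
  expect_lte(abs(peak - 1.5), 0.025 + 1e-9)
})

test_that("mouse records rescaled by kappa match human records in distribution", {
  # an 8x faster heart makes a T-second mouse record spectrally equivalent
  # to an 8T-second human record once the frequency axis is divided by 8
  mouse <- mouse_spectral_model()
  human <- human_spectral_model()
  lf_frac <- function(rr, edges, fr) {
    bp <- band_powers(lomb_scargle(rr, fr), edges)
    bp$band_power[1] / sum(bp$band_power[c(1, 3)])
  }
  set.seed(21)
  f_mouse <- replicate(200, lf_frac(simulate_rr(mouse, 16),
                                    c(0.4, 1.2, 1.6, 2.4),
                                    seq(0.2, 2.8, by = 0.025)))
  f_human <- replicate(200, lf_frac(simulate_rr(human, 128),
                                    c(0.05, 0.15, 0.2, 0.3),
                                    seq(0.025, 0.35, by = 0.025 / 8)))
  ks <- suppressWarnings(stats::ks.test(f_mouse, f_human))
  expect_gt(ks$p.value, 0.01)
})
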