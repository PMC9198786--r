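test_that("a small sinusoidal modulation is located on the grid", {
  # intervals = mean + eps * sin(2*pi*0.5*t) at slightly jittered beat times
  set.seed(51)
  n <- 120
  t <- cumsum(runif(n, 0.45, 0.55))
  iv <- 0.5 + 0.02 * sin(2 * pi * 0.5 * t)
  rr <- rr_series(cumsum(c(0, iv)))
  freqs <- seq(0.05, 0.9, by = 0.025)
  p <- lomb_scargle(rr, freqs)
  expect_equal(freqs[which.max(p$power)], 0.5)
})

test_that("constant intervals give all-zero power with a degenerate flag", {
  rr <- rr_series(seq(0, 2, by = 0.1))
  expect_warning(p <- lomb_scargle(rr, seq(0.1, 2, by = 0.1)),
                 "zero variance")
  expect_true(p$degenerate)
  expect_equal(p$power, rep(0, length(p$freqs)))
})

test_that("even sampling reproduces the classical DFT periodogram", {
  set.seed(52)
  for (rep in 1:5) {
    n <- 64
    dt <- runif(1, 0.05, 0.5)
    t <- (0:(n - 1)) * dt
    y <- rnorm(n)
    k <- 1:(n / 2 - 1)
    freqs <- k / (n * dt)
    pl <- lomb_scargle_points(t, y, freqs)
    pd <- dft_periodogram(y)
    ratio <- pl / pd
    expect_lte(max(abs(ratio / stats::median(ratio) - 1)), 1e-8)
  }
})

test_that("tau-offset implementation matches the least-squares oracle", {
  set.seed(53)
  freqs <- seq(0.05, 2, by = 0.05)
  for (rep in 1:50) {
    s <- random_uneven_series()
    pl <- lomb_scargle_points(s$times, s$values, freqs)
    po <- ls_oracle_lm(s$times, s$values, freqs)
    expect_lte(max(abs(pl - po) / pmax(po, 1e-10)), 1e-6)
  }
})

test_that("power is invariant to interval offsets and time shifts", {
  rr <- simulate_rr(mouse_spectral_model(), 20, seed = 54)
  freqs <- default_freq_grid()
  p0 <- lomb_scargle(rr, freqs)$power
  shifted <- rr_series(rr$beat_times + 123.4)
  expect_equal(lomb_scargle(shifted, freqs)$power, p0, tolerance = 1e-9)
  t_left <- rr$beat_times[-length(rr$beat_times)]
  p_off <- lomb_scargle_points(t_left, rr$intervals + 5, freqs)
  expect_equal(p_off, p0, tolerance = 1e-9)
})

test_that("input validation matches the contract", {
  rr <- rr_series(c(0, 0.1, 0.2, 0.31))  # 3 intervals
  expect_error(lomb_scargle(rr, c(0.5, 1)), "insufficient")
  rr5 <- simulate_rr(mouse_spectral_model(), 2, seed = 55)
  expect_error(lomb_scargle(rr5, c(0.5, 0.2)), "increasing")
  expect_error(lomb_scargle(rr5, c(-0.5, 0.2)), "positive")
  expect_warning(p <- lomb_scargle(rr5, c(1, 20)), "Nyquist")
  expect_length(p$power, 2L)  # over-Nyquist grid warns but still computes
})

test_that("periodogram metadata records the record it came from", {
  rr <- simulate_rr(mouse_spectral_model(), 12, seed = 56)
  p <- lomb_scargle(rr)
  expect_equal(p$n_beats, n_beats(rr))
  expect_equal(p$record_duration, rr_duration(rr))
  expect_false(p$normalized)
  expect_true(all(p$power >= 0))
})
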