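# Independent oracles used across the suite.

# Least-squares spectral oracle: at each frequency, fit
# y ~ cos(2*pi*f*t) + sin(2*pi*f*t) by lm.fit on the mean-centred values;
# the Lomb-Scargle power equals half the residual-sum-of-squares reduction,
# divided by the sample variance (Scargle normalization).  This shares no
# code with the package's tau-offset implementation.
ls_oracle_lm <- function(times, values, freqs) {
  y <- values - mean(values)
  rss0 <- sum(y^2)
  v <- stats::var(values)
  vapply(freqs, function(f) {
    x <- cbind(cos(2 * pi * f * times), sin(2 * pi * f * times))
    fit <- stats::lm.fit(x, y)
    0.5 * (rss0 - sum(fit$residuals^2)) / v
  }, numeric(1))
}

# Classical periodogram |DFT|^2 / N of a mean-centred evenly sampled series,
# evaluated at the Fourier frequencies k/(N*dt), k = 1..N/2-1.
dft_periodogram <- function(y) {
  n <- length(y)
  k <- seq_len(n %/% 2 - 1L)
  abs(stats::fft(y - mean(y)))[k + 1L]^2 / n
}

# Random uneven sampling fixture
random_uneven_series <- function(n = 60, span = 30) {
  t <- sort(stats::runif(n, 0, span))
  y <- stats::rnorm(n, 0.1, 0.01)
  list(times = t, values = y)
}

# Ground-truth beat matching: true positives within tol of a truth beat
match_beats <- function(detected, truth, tol) {
  tp <- sum(vapply(detected, function(t) any(abs(truth - t) <= tol),
                   logical(1)))
  list(sensitivity = tp / length(truth), ppv = tp / length(detected))
}

# HF-only mouse model with the HF peak inside the analysis grid
hf_only_mouse <- function(f2 = 1.5) {
  spectral_model(f1 = 0.8, f2 = f2, c1 = 0.08, c2 = 0.08,
                 sigma1_sq = 0, sigma2_sq = 1e-3,
                 mean_rr = 0.1, sd_rr = 0.006, scale_kappa = 8)
}

lf_only_mouse <- function(f1 = 0.8) {
  spectral_model(f1 = f1, f2 = 2.5, c1 = 0.08, c2 = 0.08,
                 sigma1_sq = 1e-3, sigma2_sq = 0,
                 mean_rr = 0.1, sd_rr = 0.006, scale_kappa = 8)
}
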