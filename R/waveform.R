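#' Pulse waveform container
#'
#' A uniformly sampled pressure-like trace in arbitrary units, emulating the
#' volume-pressure-recording (VPR) signal of a tail-cuff plethysmograph.
#'
#' @param samples numeric vector of samples (arbitrary units), finite.
#' @param sample_rate sampling rate (Hz), positive.
#' @param start_time time of the first sample (s).
#' @return An object of class `pulse_waveform`.
#' @export
pulse_waveform <- function(samples, sample_rate, start_time = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 2L)
  if (any(!is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be positive")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         start_time = start_time),
    class = "pulse_waveform"
  )
}

#' Sample times of a pulse waveform
#' @param wf a `pulse_waveform`.
#' @return Numeric vector of sample times (s).
#' @export
waveform_times <- function(wf) {
  stopifnot(inherits(wf, "pulse_waveform"))
  wf$start_time + (seq_along(wf$samples) - 1L) / wf$sample_rate
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf("Pulse waveform: %d samples at %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' Synthesise a VPR-like pulse waveform from an RR series
#'
#' Places one Gaussian pressure pulse at every beat time, adds a slow
#' sinusoidal baseline drift and white Gaussian noise.  The noiseless,
#' drift-free waveform has its local maxima at the beat times (to within one
#' sample), which makes the output a ground-truthed test bed for
#' [detect_beats()].
#'
#' The Gaussian pulse standard deviation is `pulse_width / 4`, so
#' `pulse_width` spans about 95% of the pulse mass; requiring
#' `pulse_width < min(interval)` keeps adjacent pulses from merging.
#'
#' @param rr an [rr_series()] giving the ground-truth beat times.
#' @param pulse_width nominal pulse width (s); must be below the smallest
#'   inter-beat interval.
#' @param pulse_amplitude pulse height (arbitrary units).
#' @param drift_amplitude amplitude of the sinusoidal baseline drift (AU).
#' @param drift_freq drift frequency (Hz); slow relative to the heart rate.
#' @param noise_sd standard deviation of additive white noise (AU).
#' @param sample_rate output sampling rate (Hz); at least `10 / pulse_width`.
#' @param seed integer seed for the noise; `NULL` consumes the current RNG
#'   stream.
#' @return A [pulse_waveform()] spanning the RR record (plus half a pulse
#'   width of padding at each end).
#' @export
#' @examples
#' rr <- simulate_rr(mouse_spectral_model(), 10, seed = 2)
#' wf <- synth_waveform(rr, seed = 3)
#' print(wf)
synth_waveform <- function(rr, pulse_width = 0.04, pulse_amplitude = 1,
                           drift_amplitude = 0.1, drift_freq = 0.2,
                           noise_sd = 0.02, sample_rate = 500,
                           seed = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (pulse_width <= 0) stop("`pulse_width` must be positive")
  if (pulse_width >= min(rr$intervals)) {
    stop(sprintf(
      "`pulse_width` (%.4g s) must be below the minimum interval (%.4g s); pulses would merge",
      pulse_width, min(rr$intervals)
    ))
  }
  if (sample_rate < 10 / pulse_width) {
    stop(sprintf("`sample_rate` must be at least 10 / pulse_width = %.3g Hz",
                 10 / pulse_width))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  pad <- pulse_width / 2
  t0 <- rr$beat_times[1L] - pad
  t1 <- rr$beat_times[length(rr$beat_times)] + pad
  t <- seq(t0, t1, by = 1 / sample_rate)
  sig <- numeric(length(t))
  sd_pulse <- pulse_width / 4
  # pulses have negligible mass beyond 5 SD; only fill a local window each
  half_win <- 5 * sd_pulse
  for (bt in rr$beat_times) {
    i0 <- max(1L, ceiling((bt - half_win - t0) * sample_rate) + 1L)
    i1 <- min(length(t), floor((bt + half_win - t0) * sample_rate) + 1L)
    idx <- i0:i1
    sig[idx] <- sig[idx] +
      pulse_amplitude * exp(-(t[idx] - bt)^2 / (2 * sd_pulse^2))
  }
  drift <- drift_amplitude * sin(2 * pi * drift_freq * t)
  noise <- if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
  pulse_waveform(sig + drift + noise, sample_rate, start_time = t0)
}
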