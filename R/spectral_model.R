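#' Bimodal Gaussian RR-fluctuation spectrum
#'
#' Parameters of the two-peak (LF + HF) Gaussian power spectrum used to
#' generate RR-interval fluctuations, in the style of McSharry-type synthetic
#' heartbeat models, together with the target interval mean and spread and a
#' species frequency-scaling factor.
#'
#' The target one-sided power spectral density is
#' \deqn{S(f) = \frac{\sigma_1^2}{\sqrt{2\pi c_1^2}}
#'   e^{-(f-f_1)^2 / 2 c_1^2} +
#'   \frac{\sigma_2^2}{\sqrt{2\pi c_2^2}} e^{-(f-f_2)^2 / 2 c_2^2}}
#' so that \eqn{\sigma_1^2} and \eqn{\sigma_2^2} are the total LF and HF
#' powers (units s^2) and \eqn{c_1}, \eqn{c_2} the Gaussian widths (Hz).
#'
#' `scale_kappa` rescales a human-referenced parameterisation to another
#' species: frequencies and widths are multiplied by `scale_kappa` and the
#' mean interval is divided by it.  A mouse heart beats roughly eight times
#' faster than a human heart, hence the mouse default `scale_kappa = 8`.
#'
#' @param f1,f2 LF and HF peak centre frequencies (Hz), `f1 < f2`.
#' @param c1,c2 LF and HF Gaussian widths (Hz), both positive.
#' @param sigma1_sq,sigma2_sq LF and HF total powers (s^2), non-negative.
#' @param mean_rr mean inter-beat interval (s), positive.
#' @param sd_rr target standard deviation of the intervals (s),
#'   `0 <= sd_rr < mean_rr`.
#' @param scale_kappa species frequency-scaling factor already applied to the
#'   stored values (1 = human reference, 8 = mouse); recorded for provenance.
#' @return An object of class `spectral_model` (a named list of the fields
#'   above).
#' @seealso [mouse_spectral_model()], [human_spectral_model()],
#'   [scale_spectral_model()], [target_spectrum()], [simulate_rr()]
#' @export
#' @examples
#' m <- mouse_spectral_model()
#' target_spectrum(m, seq(0, 3, by = 0.01))[1:5]
spectral_model <- function(f1, f2, c1, c2, sigma1_sq, sigma2_sq,
                           mean_rr, sd_rr, scale_kappa = 1) {
  stopifnot(is.numeric(f1), is.numeric(f2), length(f1) == 1L, length(f2) == 1L)
  if (!(f1 < f2)) {
    stop("`f1` must be strictly less than `f2` (LF peak below HF peak)")
  }
  if (c1 <= 0 || c2 <= 0) {
    stop("Gaussian widths `c1` and `c2` must be positive")
  }
  if (sigma1_sq < 0 || sigma2_sq < 0) {
    stop("band powers `sigma1_sq` and `sigma2_sq` must be non-negative")
  }
  if (mean_rr <= 0) stop("`mean_rr` must be positive")
  if (sd_rr < 0) stop("`sd_rr` must be non-negative")
  if (sd_rr >= mean_rr) {
    stop("`sd_rr` must be smaller than `mean_rr` to keep intervals positive")
  }
  if (scale_kappa <= 0) stop("`scale_kappa` must be positive")
  structure(
    list(
      f1 = f1, f2 = f2, c1 = c1, c2 = c2,
      sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
      mean_rr = mean_rr, sd_rr = sd_rr, scale_kappa = scale_kappa
    ),
    class = "spectral_model"
  )
}

#' Human-referenced default spectral model
#'
#' LF peak at 0.1 Hz, HF (respiratory) peak at 0.25 Hz, widths 0.01 Hz and an
#' LF/HF power ratio of 0.5 — the customary defaults of the bimodal Gaussian
#' RR spectrum — with a 0.8 s mean interval (75 bpm).
#'
#' @param mean_rr mean inter-beat interval (s).
#' @param sd_rr target interval standard deviation (s).
#' @param sigma2_sq HF power (s^2); LF power is `lf_hf_ratio * sigma2_sq`.
#' @param lf_hf_ratio LF/HF power ratio.
#' @return A `spectral_model`.
#' @export
human_spectral_model <- function(mean_rr = 0.8, sd_rr = 0.048,
                                 sigma2_sq = 1e-3, lf_hf_ratio = 0.5) {
  spectral_model(
    f1 = 0.1, f2 = 0.25, c1 = 0.01, c2 = 0.01,
    sigma1_sq = lf_hf_ratio * sigma2_sq, sigma2_sq = sigma2_sq,
    mean_rr = mean_rr, sd_rr = sd_rr, scale_kappa = 1
  )
}

#' Mouse default spectral model
#'
#' The human-referenced model rescaled by `kappa = 8` (mouse heart rate is
#' roughly eight times the human rate): LF peak 0.8 Hz, HF peak 2.0 Hz,
#' widths 0.08 Hz, mean interval 0.1 s (600 bpm) and interval SD 6 ms.
#'
#' @param kappa species frequency-scaling factor.
#' @param sd_rr target interval standard deviation after scaling (s).
#' @inheritParams human_spectral_model
#' @return A `spectral_model`.
#' @export
mouse_spectral_model <- function(kappa = 8, sd_rr = 0.006,
                                 sigma2_sq = 1e-3, lf_hf_ratio = 0.5) {
  m <- scale_spectral_model(
    human_spectral_model(sigma2_sq = sigma2_sq, lf_hf_ratio = lf_hf_ratio),
    kappa
  )
  m$sd_rr <- sd_rr
  m
}

#' Rescale a spectral model to another species
#'
#' Multiplies the peak frequencies and widths by `kappa` and divides the mean
#' interval by `kappa`; the interval SD is divided by `kappa` as well so the
#' coefficient of variation is preserved.  Powers are unchanged.
#'
#' @param model a `spectral_model`.
#' @param kappa frequency-scaling factor (> 0).
#' @return A `spectral_model` with `scale_kappa` multiplied by `kappa`.
#' @export
scale_spectral_model <- function(model, kappa) {
  stopifnot(inherits(model, "spectral_model"))
  if (kappa <= 0) stop("`kappa` must be positive")
  spectral_model(
    f1 = model$f1 * kappa, f2 = model$f2 * kappa,
    c1 = model$c1 * kappa, c2 = model$c2 * kappa,
    sigma1_sq = model$sigma1_sq, sigma2_sq = model$sigma2_sq,
    mean_rr = model$mean_rr / kappa, sd_rr = model$sd_rr / kappa,
    scale_kappa = model$scale_kappa * kappa
  )
}

#' Evaluate the target RR-fluctuation spectrum
#'
#' @param model a `spectral_model`.
#' @param freqs non-negative, strictly increasing frequency grid (Hz).
#' @return Numeric vector of power spectral density values (s^2/Hz), one per
#'   frequency, all non-negative.
#' @export
#' @examples
#' target_spectrum(human_spectral_model(), c(0.05, 0.1, 0.25))
target_spectrum <- function(model, freqs) {
  stopifnot(inherits(model, "spectral_model"), is.numeric(freqs))
  if (length(freqs) == 0L) stop("`freqs` must be non-empty")
  if (any(freqs < 0)) stop("`freqs` must be non-negative")
  if (length(freqs) > 1L && any(diff(freqs) <= 0)) {
    stop("`freqs` must be strictly increasing")
  }
  gauss <- function(sigma_sq, centre, width) {
    sigma_sq / sqrt(2 * pi * width^2) *
      exp(-(freqs - centre)^2 / (2 * width^2))
  }
  gauss(model$sigma1_sq, model$f1, model$c1) +
    gauss(model$sigma2_sq, model$f2, model$c2)
}

#' @export
print.spectral_model <- function(x, ...) {
  cat("Bimodal Gaussian RR spectrum model\n")
  cat(sprintf("  LF: f1 = %.4g Hz (width %.4g Hz, power %.4g s^2)\n",
              x$f1, x$c1, x$sigma1_sq))
  cat(sprintf("  HF: f2 = %.4g Hz (width %.4g Hz, power %.4g s^2)\n",
              x$f2, x$c2, x$sigma2_sq))
  cat(sprintf("  mean RR %.4g s (%.0f bpm), SD %.4g s, kappa = %.3g\n",
              x$mean_rr, 60 / x$mean_rr, x$sd_rr, x$scale_kappa))
  invisible(x)
}
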