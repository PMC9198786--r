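#' Default frequency grid for mouse HRV periodograms
#'
#' 0.05 to 2.0 Hz in steps of 0.025 Hz: covers the 0.1--1.9 Hz analysis
#' bands with at least eight grid points per 0.2 Hz band.
#'
#' @param fmin,fmax,step grid limits and spacing (Hz).
#' @return Increasing numeric vector of frequencies (Hz).
#' @export
default_freq_grid <- function(fmin = 0.05, fmax = 2.0, step = 0.025) {
  seq(fmin, fmax, by = step)
}

#' Default HRV band edges
#'
#' Ten contiguous 0.2 Hz-wide bands spanning 0--2 Hz, so band centres fall at
#' 0.1, 0.3, ..., 1.9 Hz — the bandings HRV power is reported in.
#'
#' @return Numeric vector of 11 band edges (Hz).
#' @export
default_band_edges <- function() seq(0, 2, by = 0.2)

new_periodogram <- function(freqs, power, normalized, record_duration,
                            n_beats, degenerate = FALSE,
                            display_scaled = FALSE) {
  structure(
    list(freqs = freqs, power = power, normalized = normalized,
         display_scaled = display_scaled, degenerate = degenerate,
         record_duration = record_duration, n_beats = n_beats),
    class = "periodogram"
  )
}

#' Lomb--Scargle periodogram of an RR series
#'
#' Computes the classical Scargle periodogram (with the per-frequency time
#' offset tau that makes the sine and cosine bases orthogonal) of the
#' mean-centred inter-beat intervals located at their beat times.  This
#' least-squares spectral estimator is valid for the inherently uneven
#' sampling of a tachogram.  Output power uses Scargle's variance
#' normalization (division by the sample variance of the intervals) and is
#' not unit-sum normalized; see [normalize_periodogram()].
#'
#' @param rr an [rr_series()] with at least 4 intervals.
#' @param freqs positive, strictly increasing frequency grid (Hz).  A grid
#'   extending beyond the pseudo-Nyquist frequency `0.5 / median(interval)`
#'   triggers a warning but is allowed.
#' @param time_ref where an interval is located on the time axis: at its
#'   left beat time (default) or at the midpoint of its two beats.
#' @return A `periodogram` object with fields `freqs`, `power` (non-negative,
#'   arbitrary units), `normalized` (FALSE here), `degenerate` (TRUE when
#'   the intervals have zero variance, in which case power is all zero and a
#'   warning is issued), `record_duration` (s) and `n_beats`.
#' @export
#' @examples
#' rr <- simulate_rr(mouse_spectral_model(), 30, seed = 6)
#' p <- lomb_scargle(rr, default_freq_grid())
#' p$freqs[which.max(p$power)]
lomb_scargle <- function(rr, freqs = default_freq_grid(),
                         time_ref = c("left", "midpoint")) {
  stopifnot(inherits(rr, "rr_series"), is.numeric(freqs))
  time_ref <- match.arg(time_ref)
  if (length(rr$intervals) < 4L) {
    stop("insufficient data: Lomb-Scargle needs at least 4 intervals")
  }
  if (any(freqs <= 0)) stop("`freqs` must be positive")
  if (length(freqs) > 1L && any(diff(freqs) <= 0)) {
    stop("`freqs` must be strictly increasing")
  }
  pseudo_nyquist <- 0.5 / stats::median(rr$intervals)
  if (max(freqs) > pseudo_nyquist) {
    warning(sprintf(
      "frequency grid extends beyond the pseudo-Nyquist frequency %.3g Hz",
      pseudo_nyquist
    ))
  }

  y <- rr$intervals
  t <- switch(time_ref,
    left = rr$beat_times[-length(rr$beat_times)],
    midpoint = (rr$beat_times[-1L] + rr$beat_times[-length(rr$beat_times)]) / 2
  )
  dur <- rr_duration(rr)
  nb <- n_beats(rr)

  # relative tolerance: accumulated floating error in beat times must not
  # masquerade as heart-rate variability
  if (stats::sd(y) <= 1e-10 * max(abs(y))) {
    warning("intervals have zero variance; returning an all-zero periodogram")
    return(new_periodogram(freqs, rep(0, length(freqs)), FALSE, dur, nb,
                           degenerate = TRUE))
  }

  new_periodogram(freqs, lomb_scargle_points(t, y, freqs), FALSE, dur, nb)
}

#' Low-level Lomb--Scargle power for arbitrary samples
#'
#' The classical Scargle estimator on an arbitrary (possibly uneven) set of
#' sample times and values: the values are mean-centred, the per-frequency
#' time offset tau orthogonalises the sine and cosine bases, and the power
#' is divided by the sample variance of the values (Scargle's variance
#' normalization).  [lomb_scargle()] wraps this for RR series; the direct
#' entry point is useful for cross-checks against reference periodograms.
#'
#' @param times numeric sample times (s), any spacing.
#' @param values numeric sample values, same length, non-constant.
#' @param freqs positive frequencies (Hz) at which to evaluate.
#' @return Numeric vector of non-negative power values, one per frequency.
#' @export
lomb_scargle_points <- function(times, values, freqs) {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 4L)
  if (any(freqs <= 0)) stop("`freqs` must be positive")
  v <- stats::var(values)
  if (v == 0) stop("`values` must not be constant")
  yc <- values - mean(values)
  omega <- 2 * pi * freqs
  # n_freq x n_time trig matrices
  wt <- outer(omega, times)
  s2 <- rowSums(sin(2 * wt))
  c2 <- rowSums(cos(2 * wt))
  tau <- atan2(s2, c2) / (2 * omega)
  arg <- wt - omega * tau
  ca <- cos(arg)
  sa <- sin(arg)
  yc_c <- as.vector(ca %*% yc)
  yc_s <- as.vector(sa %*% yc)
  pmax(0.5 * (yc_c^2 / rowSums(ca^2) + yc_s^2 / rowSums(sa^2)) / v, 0)
}

#' Normalize a periodogram
#'
#' Unit-sum normalization: the power values are divided by their total so
#' they sum to one, which puts periodograms of records of different lengths
#' and variances on a common scale.  With `display_scale = TRUE` the result
#' is additionally rescaled so its maximum is one (used only when plotting
#' stacked surfaces; the flag is recorded on the object).
#'
#' An all-zero periodogram (degenerate input) is returned unchanged with its
#' `degenerate` flag set.
#'
#' @param p a `periodogram`.
#' @param display_scale also rescale so the maximum is 1 (display only).
#' @return A `periodogram` with `normalized = TRUE` (idempotent).
#' @export
normalize_periodogram <- function(p, display_scale = FALSE) {
  stopifnot(inherits(p, "periodogram"))
  total <- sum(p$power)
  if (total <= 0) {
    p$degenerate <- TRUE
    p$normalized <- TRUE
    return(p)
  }
  p$power <- p$power / total
  if (display_scale) {
    p$power <- p$power / max(p$power)
    p$display_scaled <- TRUE
  }
  p$normalized <- TRUE
  p
}

#' Integrate periodogram power over contiguous frequency bands
#'
#' Band power is the trapezoidal integral of the power curve over each
#' `[edge_i, edge_{i+1})` interval, with linear interpolation of the power at
#' interior band edges.  Bands extending beyond the frequency grid are
#' clipped to the grid span (the default bands start at 0 Hz while the
#' default grid starts at 0.05 Hz); a band wholly outside the grid is an
#' error.
#'
#' @param p a `periodogram`.
#' @param edges increasing numeric vector of band edges (Hz), length >= 2.
#' @param meta labels to attach (subject, treatment, temperature).
#' @return An object of class `band_power_vector` with fields `band_centres`
#'   (interval midpoints, Hz), `band_power` (non-negative), and `meta`.
#' @export
#' @examples
#' rr <- simulate_rr(mouse_spectral_model(), 30, seed = 7)
#' bp <- band_powers(lomb_scargle(rr))
#' round(bp$band_power, 4)
band_powers <- function(p, edges = default_band_edges(), meta = list()) {
  stopifnot(inherits(p, "periodogram"), is.numeric(edges))
  if (length(edges) < 2L) stop("need at least two band edges")
  if (any(diff(edges) <= 0)) stop("`edges` must be strictly increasing")
  fmin <- p$freqs[1L]
  fmax <- p$freqs[length(p$freqs)]
  centres <- (edges[-length(edges)] + edges[-1L]) / 2
  pw <- numeric(length(centres))
  for (i in seq_along(centres)) {
    lo <- edges[i]
    hi <- edges[i + 1L]
    if (hi <= fmin || lo >= fmax) {
      stop(sprintf("band [%.3g, %.3g) Hz lies outside the frequency grid span [%.3g, %.3g] Hz",
                   lo, hi, fmin, fmax))
    }
    lo <- max(lo, fmin)
    hi <- min(hi, fmax)
    xs <- c(lo, p$freqs[p$freqs > lo & p$freqs < hi], hi)
    ys <- stats::approx(p$freqs, p$power, xout = xs)$y
    pw[i] <- trapz(xs, ys)
  }
  structure(
    list(band_centres = centres, band_power = pw, meta = meta),
    class = "band_power_vector"
  )
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf(
    "Lomb-Scargle periodogram: %d frequencies %.3g-%.3g Hz (%d beats, %.2f s)\n",
    length(x$freqs), min(x$freqs), max(x$freqs), x$n_beats, x$record_duration
  ))
  flags <- c(if (x$normalized) "unit-sum normalized",
             if (x$display_scaled) "display-scaled",
             if (x$degenerate) "degenerate (zero variance)")
  if (length(flags)) cat(" ", paste(flags, collapse = ", "), "\n")
  cat(sprintf("  peak at %.3g Hz\n", x$freqs[which.max(x$power)]))
  invisible(x)
}

#' @export
plot.periodogram <- function(x, ..., xlab = "frequency (Hz)",
                             ylab = "power (AU)", type = "l") {
  graphics::plot(x$freqs, x$power, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
print.band_power_vector <- function(x, ...) {
  cat("HRV band powers (AU):\n")
  v <- x$band_power
  names(v) <- sprintf("%.1f Hz", x$band_centres)
  print(signif(v, 4))
  invisible(x)
}
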