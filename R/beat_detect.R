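#' Beat-detector parameters
#'
#' Tuning knobs for [detect_beats()].  Defaults target lightly sedated mice
#' (heart rate envelope 200--1200 bpm, i.e. intervals 0.05--0.3 s).
#'
#' @param baseline_window moving-average window (s) for baseline removal;
#'   long relative to a beat so pulses survive detrending.
#' @param smooth_window moving-average smoothing window (s); short relative
#'   to a pulse.
#' @param refractory minimum beat-to-beat spacing (s); when two candidate
#'   peaks are closer, the larger is kept.
#' @param threshold_k detection threshold as a multiple of the detrended
#'   signal's robust spread (median absolute deviation, scaled by 1.4826 to
#'   be consistent with the Gaussian SD).
#' @param interval_min,interval_max plausibility gate (s) on inter-beat
#'   intervals.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(baseline_window = 0.5, smooth_window = 0.004,
                            refractory = 0.05, threshold_k = 3,
                            interval_min = 0.05, interval_max = 0.3) {
  if (baseline_window <= 0 || smooth_window <= 0) {
    stop("windows must be positive")
  }
  if (refractory <= 0) stop("`refractory` must be positive")
  if (threshold_k <= 0) stop("`threshold_k` must be positive")
  if (interval_min >= interval_max) {
    stop("`interval_min` must be below `interval_max`")
  }
  structure(
    list(baseline_window = baseline_window, smooth_window = smooth_window,
         refractory = refractory, threshold_k = threshold_k,
         interval_min = interval_min, interval_max = interval_max),
    class = "detector_params"
  )
}

#' Detect beats in a pulse waveform
#'
#' Extracts beat times from a uniformly sampled pressure trace: the signal is
#' detrended by subtracting a moving-average baseline, smoothed, and local
#' maxima exceeding `threshold_k` times the robust spread (MAD x 1.4826) are
#' taken as candidate beats.  The refractory period is enforced by keeping
#' the larger of any two candidates closer than `refractory`.  Peak times are
#' refined by parabolic interpolation through the three samples around each
#' maximum, giving sub-sample precision.
#'
#' Intervals outside `[interval_min, interval_max]` are treated as artefacts:
#' a too-short interval causes the smaller-amplitude beat of the pair to be
#' removed; a too-long interval (a missed beat) is counted but the
#' surrounding beats are retained.  The total artefact count is returned in
#' the `dropped` attribute of the result.
#'
#' Because the threshold is relative and the baseline is subtracted,
#' detection is invariant to adding a constant offset or applying a positive
#' gain to the waveform.
#'
#' @param waveform a [pulse_waveform()].
#' @param params a [detector_params()].
#' @return An [rr_series()] of detected beats, with attribute `dropped`
#'   giving the artefact-interval count.  Fewer than two surviving beats is
#'   an error (detection failure), never an empty result.
#' @export
#' @examples
#' rr <- simulate_rr(mouse_spectral_model(), 10, seed = 4)
#' wf <- synth_waveform(rr, noise_sd = 0.05, seed = 5)
#' det <- detect_beats(wf)
#' n_beats(det); n_beats(rr)
detect_beats <- function(waveform, params = detector_params()) {
  stopifnot(inherits(waveform, "pulse_waveform"),
            inherits(params, "detector_params"))
  fs <- waveform$sample_rate
  x <- waveform$samples
  n <- length(x)
  if (n / fs < 3 * params$interval_min) {
    stop("waveform too short: need at least three expected beats")
  }

  detrended <- x - running_mean(x, window_samples(params$baseline_window, fs))
  s <- running_mean(detrended, window_samples(params$smooth_window, fs))

  spread <- stats::mad(s)
  if (spread == 0) spread <- stats::sd(s)
  thr <- params$threshold_k * spread

  is_peak <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] &
                 s[2:(n - 1)] >= s[3:n], FALSE)
  cand <- which(is_peak & s > thr)
  if (length(cand) < 2L) {
    stop("beat detection failed: fewer than two candidate beats above threshold")
  }

  # refractory: greedy acceptance in decreasing amplitude order
  ord <- cand[order(s[cand], decreasing = TRUE)]
  refr_samp <- params$refractory * fs
  keep <- logical(0)
  kept_idx <- integer(0)
  for (i in ord) {
    if (!length(kept_idx) || all(abs(kept_idx - i) >= refr_samp)) {
      kept_idx <- c(kept_idx, i)
    }
  }
  kept_idx <- sort(kept_idx)

  times <- waveform$start_time + (kept_idx - 1L) / fs +
    parabolic_offset(s, kept_idx) / fs
  amps <- s[kept_idx]

  # interval plausibility gate
  dropped <- 0L
  repeat {
    iv <- diff(times)
    short <- which(iv < params$interval_min)
    if (!length(short)) break
    j <- short[1L]
    rm <- if (amps[j] < amps[j + 1L]) j else j + 1L
    times <- times[-rm]
    amps <- amps[-rm]
    dropped <- dropped + 1L
    if (length(times) < 2L) {
      stop("beat detection failed: fewer than two beats survive the interval gate")
    }
  }
  dropped <- dropped + sum(diff(times) > params$interval_max)

  if (length(times) < 2L) {
    stop("beat detection failed: fewer than two beats survive the interval gate")
  }
  out <- rr_series(times)
  attr(out, "dropped") <- dropped
  out
}

window_samples <- function(window_s, fs) {
  k <- max(1L, round(window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

# centred running mean with edge correction (partial windows at the ends)
running_mean <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# sub-sample peak refinement: vertex of the parabola through
# (i-1, i, i+1); offset clamped to half a sample
parabolic_offset <- function(s, idx) {
  n <- length(s)
  off <- numeric(length(idx))
  ok <- idx > 1L & idx < n
  i <- idx[ok]
  denom <- s[i - 1L] - 2 * s[i] + s[i + 1L]
  d <- ifelse(denom < 0, 0.5 * (s[i - 1L] - s[i + 1L]) / denom, 0)
  off[ok] <- pmax(-0.5, pmin(0.5, d))
  off
}
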