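#' RR (inter-beat interval) series
#'
#' The unevenly sampled signal that frequency-domain HRV operates on: a
#' strictly increasing sequence of beat times (seconds from record start)
#' with the derived successive inter-beat intervals.
#'
#' @param beat_times strictly increasing numeric vector of beat times (s);
#'   at least two beats.
#' @param meta named list of free-form labels (e.g. `subject_id`,
#'   `treatment`, `temp_c` ambient temperature).
#' @return An object of class `rr_series` with elements `beat_times`,
#'   `intervals` (`diff(beat_times)`) and `meta`.
#' @seealso [simulate_rr()], [detect_beats()], [lomb_scargle()]
#' @export
#' @examples
#' rr <- rr_series(c(0, 0.1, 0.21, 0.3))
#' rr$intervals
rr_series <- function(beat_times, meta = list()) {
  stopifnot(is.numeric(beat_times))
  if (length(beat_times) < 2L) {
    stop("an RR series needs at least two beat times")
  }
  if (any(!is.finite(beat_times))) stop("beat times must be finite")
  intervals <- diff(beat_times)
  if (any(intervals <= 0)) {
    bad <- which(intervals <= 0)[1L] + 1L
    stop(sprintf("beat times must be strictly increasing (violated at beat %d)",
                 bad))
  }
  structure(
    list(beat_times = as.numeric(beat_times),
         intervals = as.numeric(intervals),
         meta = meta),
    class = "rr_series"
  )
}

#' Record duration of an RR series
#'
#' @param rr an `rr_series`.
#' @return Last beat time minus first beat time (s).
#' @export
rr_duration <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  rr$beat_times[length(rr$beat_times)] - rr$beat_times[1L]
}

#' Truncate an RR series to a prefix of given duration
#'
#' Keeps all beats within `duration` seconds of the first beat.  Prefix
#' truncation is nested: truncating to `d` then to `d' < d` equals
#' truncating directly to `d'`.
#'
#' @param rr an `rr_series`.
#' @param duration prefix length (s), positive.
#' @return An `rr_series` spanning at most `duration` seconds; errors if
#'   fewer than two beats survive.
#' @export
truncate_rr <- function(rr, duration) {
  stopifnot(inherits(rr, "rr_series"), duration > 0)
  keep <- rr$beat_times - rr$beat_times[1L] <= duration
  if (sum(keep) < 2L) {
    stop(sprintf("truncation to %.3g s leaves fewer than two beats", duration))
  }
  rr_series(rr$beat_times[keep], meta = rr$meta)
}

#' Number of beats in an RR series
#' @param rr an `rr_series`.
#' @return Integer beat count.
#' @export
n_beats <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  length(rr$beat_times)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf(
    "RR series: %d beats over %.3f s (mean interval %.4f s, %.0f bpm)\n",
    n_beats(x), rr_duration(x), mean(x$intervals), 60 / mean(x$intervals)
  ))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.rr_series <- function(object, ...) {
  iv <- object$intervals
  out <- list(
    n_beats = n_beats(object),
    duration_s = rr_duration(object),
    mean_rr_s = mean(iv),
    sd_rr_s = stats::sd(iv),
    min_rr_s = min(iv),
    max_rr_s = max(iv),
    mean_hr_bpm = 60 / mean(iv)
  )
  class(out) <- "summary.rr_series"
  out
}

#' @export
print.summary.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d beats, %.3f s\n", x$n_beats, x$duration_s))
  cat(sprintf("  intervals: mean %.4f s, SD %.4f s, range [%.4f, %.4f] s\n",
              x$mean_rr_s, x$sd_rr_s, x$min_rr_s, x$max_rr_s))
  cat(sprintf("  mean heart rate: %.1f bpm\n", x$mean_hr_bpm))
  invisible(x)
}
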