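#' Configuration for the record-length convergence study
#'
#' Defines the Monte-Carlo experiment asking how short an RR record can be
#' while still yielding a stable HRV periodogram: `n_sims` records of
#' `reference_duration` are simulated; each is prefix-truncated to every
#' length in `durations` and the normalized Lomb--Scargle periodogram of
#' each truncation is averaged across simulations.
#'
#' @param n_sims number of simulated records (default 3000, the full-scale
#'   study size; 300 reproduces the qualitative convergence shape at a tenth
#'   of the cost).
#' @param durations increasing grid of record lengths (s); the default
#'   2, 4, ..., 64 s spans the "8 s of mouse is like 1 min of human" regime.
#' @param model the generating [spectral_model()].
#' @param freqs common frequency grid for all periodograms.
#' @param reference_duration full record length (s); must be at least
#'   `max(durations)`.
#' @param seed integer master seed; the whole study is a deterministic
#'   function of the config.
#' @param beat_budget_cap warn when `n_sims * reference_duration / mean_rr`
#'   exceeds this (a runaway-cost guard).
#' @return An object of class `duration_study_config`.
#' @export
duration_study_config <- function(n_sims = 3000,
                                  durations = c(2, 4, 8, 16, 32, 64),
                                  model = mouse_spectral_model(),
                                  freqs = default_freq_grid(),
                                  reference_duration = max(durations),
                                  seed = 1,
                                  beat_budget_cap = 1e7) {
  if (n_sims < 1) stop("`n_sims` must be at least 1")
  if (any(diff(durations) <= 0)) stop("`durations` must be increasing")
  if (max(durations) > reference_duration) {
    stop("`reference_duration` must be at least max(durations)")
  }
  stopifnot(inherits(model, "spectral_model"))
  structure(
    list(n_sims = as.integer(n_sims), durations = durations, model = model,
         freqs = freqs, reference_duration = reference_duration,
         seed = as.integer(seed), beat_budget_cap = beat_budget_cap),
    class = "duration_study_config"
  )
}

#' Run the record-length convergence study
#'
#' For each of `n_sims` simulations one reference-length RR record is
#' generated and prefix-truncated to every duration in the grid (prefixes
#' are nested, so shorter records are contained in longer ones, giving
#' low-variance convergence curves); each truncation's unit-sum normalized
#' Lomb--Scargle periodogram is computed on the common frequency grid.  The
#' surface rows are the per-duration means over simulations.
#'
#' A duration whose truncations yield fewer than 4 intervals is flagged
#' invalid (its row is NA) rather than silently dropped.  A zero-variance
#' model (`sd_rr = 0`) yields degenerate all-zero rows, flagged.
#'
#' @param config a [duration_study_config()].
#' @return An object of class `stacked_periodogram_surface` with fields
#'   `durations`, `freqs`, `mean_power` (durations x freqs; each valid row
#'   sums to 1), `dispersion` (per-duration, per-frequency SD across
#'   simulations), `median_l1` (per-duration median of the L1 distance
#'   between each simulation's truncated periodogram and that same
#'   simulation's reference periodogram), `row_valid`, `row_degenerate`,
#'   `n_sims` and `seed`.
#' @export
#' @examples
#' cfg <- duration_study_config(n_sims = 20, durations = c(4, 16, 64),
#'                              seed = 42)
#' surf <- run_duration_study(cfg)
#' convergence_curve(surf)
run_duration_study <- function(config) {
  stopifnot(inherits(config, "duration_study_config"))
  budget <- config$n_sims * config$reference_duration / config$model$mean_rr
  if (budget > config$beat_budget_cap) {
    warning(sprintf("study simulates ~%.3g beats, above the cap of %.3g",
                    budget, config$beat_budget_cap))
  }
  nd <- length(config$durations)
  nf <- length(config$freqs)
  sum_p <- matrix(0, nd, nf)
  sum_p2 <- matrix(0, nd, nf)
  l1_ref <- matrix(NA_real_, nd, config$n_sims)
  n_valid <- integer(nd)
  n_degen <- integer(nd)

  set.seed(config$seed)
  for (s in seq_len(config$n_sims)) {
    rr <- simulate_rr(config$model, config$reference_duration)
    pg <- matrix(NA_real_, nd, nf)
    for (d in seq_len(nd)) {
      tr <- tryCatch(truncate_rr(rr, config$durations[d]),
                     error = function(e) NULL)
      if (is.null(tr) || length(tr$intervals) < 4L) next
      p <- suppressWarnings(
        normalize_periodogram(lomb_scargle(tr, config$freqs))
      )
      if (p$degenerate) n_degen[d] <- n_degen[d] + 1L
      pg[d, ] <- p$power
      n_valid[d] <- n_valid[d] + 1L
    }
    ok <- !is.na(pg[, 1L])
    sum_p[ok, ] <- sum_p[ok, ] + pg[ok, , drop = FALSE]
    sum_p2[ok, ] <- sum_p2[ok, ] + pg[ok, , drop = FALSE]^2
    if (ok[nd]) {
      l1_ref[ok, s] <- rowSums(abs(
        pg[ok, , drop = FALSE] -
          matrix(pg[nd, ], sum(ok), nf, byrow = TRUE)
      ))
    }
  }

  row_valid <- n_valid == config$n_sims
  mean_power <- sum_p / n_valid
  mean_power[!row_valid, ] <- NA_real_
  disp <- sqrt(pmax(sum_p2 / n_valid - mean_power^2, 0))
  disp[!row_valid, ] <- NA_real_
  structure(
    list(durations = config$durations, freqs = config$freqs,
         mean_power = mean_power, dispersion = disp,
         median_l1 = apply(l1_ref, 1L, stats::median, na.rm = TRUE),
         row_valid = row_valid,
         row_degenerate = n_degen == config$n_sims,
         n_sims = config$n_sims, seed = config$seed),
    class = "stacked_periodogram_surface"
  )
}

#' Convergence curve of a stacked-periodogram surface
#'
#' Quantifies how the mean periodogram at each record length diverges from
#' the reference (longest-duration) mean periodogram: the L1 distance
#' between unit-sum rows, bounded in \[0, 2\].  The value at the reference
#' duration is identically 0.
#'
#' @param surface a `stacked_periodogram_surface` whose last row is the
#'   reference.
#' @return Named numeric vector of divergences, one per duration; invalid
#'   rows propagate as `NA`.
#' @export
convergence_curve <- function(surface) {
  stopifnot(inherits(surface, "stacked_periodogram_surface"))
  ref <- surface$mean_power[nrow(surface$mean_power), ]
  div <- apply(surface$mean_power, 1L, function(row) sum(abs(row - ref)))
  names(div) <- sprintf("%gs", surface$durations)
  div
}

#' @export
print.stacked_periodogram_surface <- function(x, ...) {
  cat(sprintf(
    "Stacked periodogram surface: %d durations (%g-%g s) x %d frequencies, %d simulations\n",
    length(x$durations), min(x$durations), max(x$durations),
    length(x$freqs), x$n_sims
  ))
  if (any(!x$row_valid)) {
    cat("  invalid rows:", paste(x$durations[!x$row_valid], collapse = ", "),
        "s\n")
  }
  if (any(x$row_degenerate)) {
    cat("  degenerate (zero-spectrum) rows present\n")
  }
  cat("  mean-row L1 divergence from reference:\n")
  print(signif(convergence_curve(x), 3))
  invisible(x)
}

#' @export
plot.stacked_periodogram_surface <- function(x, ...,
                                             xlab = "frequency (Hz)",
                                             ylab = "record duration (s)") {
  z <- t(x$mean_power)
  graphics::image(x = x$freqs, y = seq_along(x$durations), z = z,
                  xlab = xlab, ylab = ylab, yaxt = "n",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::axis(2, at = seq_along(x$durations), labels = x$durations)
  invisible(x)
}
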