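#' Two-group MANOVA on HRV band-power vectors
#'
#' Compares the multivariate band-power profiles of two treatment groups
#' (e.g. control vs drug) with Wilks' lambda,
#' \deqn{\Lambda = \det(E) / \det(E + H)}
#' where \eqn{E} is the pooled within-group and \eqn{H} the between-group
#' cross-product matrix.  Significance uses Rao's F approximation, which is
#' exact for two groups (where Wilks' lambda is equivalent to Hotelling's
#' T-squared).  Per-band univariate one-way ANOVA follow-ups are always
#' reported alongside the multivariate test (they are not gated on
#' multivariate significance; interpret them accordingly).
#'
#' @param data a data frame with one row per record: a `treatment` column
#'   (exactly two levels) and one numeric column per frequency band.
#'   Columns named `subject_id` and `temp_c` are treated as metadata and
#'   ignored.
#' @param group_col name of the grouping column.
#' @param band_cols names of the band-power columns; default every numeric
#'   column except the metadata columns.
#' @return An object of class `hrv_manova`: `wilks_lambda`, `f_approx`,
#'   `df1`, `df2`, `p_value`, and `univariate` (a data frame of per-band F
#'   and p).
#' @export
#' @examples
#' d <- simulate_band_power_study(n_per_group = 12, effect_size = 1, seed = 8)
#' fit <- manova_two_group(d)
#' fit
manova_two_group <- function(data, group_col = "treatment",
                             band_cols = NULL) {
  stopifnot(is.data.frame(data))
  if (!group_col %in% names(data)) {
    stop(sprintf("grouping column '%s' not found", group_col))
  }
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2L) {
    stop(sprintf("need exactly two groups, found %d", nlevels(g)))
  }
  if (any(table(g) == 0L)) stop("one group is empty")
  if (is.null(band_cols)) {
    meta <- c(group_col, "subject_id", "temp_c")
    band_cols <- names(data)[vapply(data, is.numeric, logical(1)) &
                               !names(data) %in% meta]
  }
  if (!length(band_cols)) stop("no band-power columns found")
  x <- as.matrix(data[band_cols])
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p + 2L) {
    stop(sprintf(
      "rank deficiency: need more than p + 2 = %d observations for %d bands, have %d",
      p + 2L, p, n
    ))
  }

  grand <- colMeans(x)
  e <- matrix(0, p, p)
  h <- matrix(0, p, p)
  for (lev in levels(g)) {
    xg <- x[g == lev, , drop = FALSE]
    mg <- colMeans(xg)
    e <- e + crossprod(sweep(xg, 2L, mg))
    h <- h + nrow(xg) * tcrossprod(mg - grand)
  }

  zero_var <- diag(e) <= 0
  if (any(zero_var)) {
    stop("within-group cross-product matrix is singular; offending bands: ",
         paste(band_cols[zero_var], collapse = ", "))
  }
  det_e <- det(e)
  det_t <- det(e + h)
  if (det_e <= 0 || !is.finite(det_e)) {
    stop("within-group cross-product matrix is singular ",
         "(collinear band-power columns)")
  }
  lambda <- det_e / det_t

  # Rao's F approximation (exact here: two groups)
  ng <- 2L
  q <- ng - 1L
  v <- n - ng
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- s * (v - (p - q + 1) / 2) - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  f_approx <- (1 - lam_s) / lam_s * df2 / df1
  p_value <- stats::pf(f_approx, df1, df2, lower.tail = FALSE)

  uni <- t(vapply(seq_len(p), function(j) {
    univariate_f(x[, j], g)
  }, numeric(2)))
  univariate <- data.frame(band = band_cols, F = uni[, 1L], p = uni[, 2L],
                           row.names = NULL)

  structure(
    list(wilks_lambda = lambda, f_approx = f_approx, df1 = df1, df2 = df2,
         p_value = p_value, univariate = univariate,
         n = n, n_bands = p, groups = levels(g)),
    class = "hrv_manova"
  )
}

# one-way ANOVA F and p for a single response
univariate_f <- function(y, g) {
  n <- length(y)
  k <- nlevels(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- k - 1L
  df2 <- n - k
  if (ssw <= 0) {
    f <- if (ssb > 0) Inf else 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
  }
  c(f, stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' @export
print.hrv_manova <- function(x, ...) {
  cat(sprintf("Two-group MANOVA (%s vs %s) on %d bands, n = %d\n",
              x$groups[1L], x$groups[2L], x$n_bands, x$n))
  cat(sprintf("  Wilks' lambda = %.4f, approx F(%g, %g) = %.3f, p = %.4g\n",
              x$wilks_lambda, x$df1, x$df2, x$f_approx, x$p_value))
  invisible(x)
}

#' @export
summary.hrv_manova <- function(object, ...) {
  print(object)
  cat("Univariate per-band follow-ups (one-way ANOVA):\n")
  u <- object$univariate
  u$F <- signif(u$F, 4)
  u$p <- signif(u$p, 4)
  print(u, row.names = FALSE)
  invisible(object)
}

#' All-pairs cell-mean contrasts over a factorial grid
#'
#' Forms every unordered pair of cell means over the cross of the given
#' factors (e.g. 6 ambient temperatures x 2 treatments gives
#' `choose(12, 2) = 66` comparisons), using pooled-variance standard errors
#' and a two-sided t reference, then appends Benjamini--Hochberg adjusted
#' p-values.  Cells with fewer than two observations are dropped with a
#' warning (and the comparison count shrinks accordingly).
#'
#' Cell means are simple pooled-variance means, not mixed-model estimated
#' marginal means: the comparison grid and the multiplicity correction are
#' the analysis machinery of interest here; standard errors from a
#' repeated-measures fit would differ.
#'
#' @param data a data frame of scalar observations.
#' @param value_col name of the numeric response column.
#' @param factor_cols character vector of factor column names whose cross
#'   defines the cells.
#' @return A data frame of class `pairwise_contrasts`: `cell_a`, `cell_b`,
#'   `diff` (mean A minus mean B), `se`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
#' @examples
#' d <- expand.grid(temp_c = 31:36, treatment = c("control", "drug"),
#'                  rep = 1:5)
#' set.seed(9)
#' d$value <- rnorm(nrow(d))
#' nrow(pairwise_cell_comparisons(d))  # 66
pairwise_cell_comparisons <- function(data, value_col = "value",
                                      factor_cols = c("temp_c", "treatment")) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(value_col, factor_cols), names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  y <- data[[value_col]]
  if (!is.numeric(y)) stop(sprintf("'%s' must be numeric", value_col))
  cell <- interaction(data[factor_cols], sep = ":", drop = TRUE)

  counts <- table(cell)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("dropping cells with fewer than two observations: ",
            paste(small, collapse = ", "))
    keep <- !cell %in% small
    y <- y[keep]
    cell <- droplevels(cell[keep])
    counts <- table(cell)
  }
  k <- nlevels(cell)
  if (k < 2L) stop("need at least two non-empty cells to compare")

  means <- tapply(y, cell, mean)
  ssw <- sum(tapply(y, cell, function(v) sum((v - mean(v))^2)))
  df <- length(y) - k
  mse <- ssw / df
  ns <- as.numeric(counts)

  pairs <- utils::combn(k, 2L)
  a <- pairs[1L, ]
  b <- pairs[2L, ]
  diffs <- means[a] - means[b]
  se <- sqrt(mse * (1 / ns[a] + 1 / ns[b]))
  tval <- diffs / se
  p_raw <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)

  out <- data.frame(
    cell_a = levels(cell)[a], cell_b = levels(cell)[b],
    diff = as.numeric(diffs), se = se, t = as.numeric(tval), df = df,
    p_raw = p_raw, p_adj = bh_adjust(p_raw),
    row.names = NULL
  )
  class(out) <- c("pairwise_contrasts", "data.frame")
  out
}

#' Benjamini--Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate control: with the p-values sorted ascending,
#' the adjusted value at rank i is `min over j >= i of p_(j) * m / j`,
#' capped at 1 and returned in the original order.  The procedure is
#' monotone (order-preserving) and idempotent on its own output.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  ranked <- p_values[o]
  adj <- rev(cummin(rev(ranked * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Simulate a two-group factorial band-power dataset
#'
#' Generates the control-vs-drug x ambient-temperature factorial structure
#' of HRV band-power vectors used to exercise the comparison machinery.
#' Every record's band powers are a common baseline plus independent
#' Gaussian noise; the drug group receives an additive mean shift of
#' `effect_size` noise-SD units in every band except the spared one (by
#' default the 0.5 Hz band, mimicking a treatment effect that leaves one
#' banding untouched).
#'
#' @param n_per_group records per treatment group.
#' @param temps ambient temperature levels (deg C) cycled over records.
#' @param band_centres band centre frequencies (Hz) naming the columns.
#' @param effect_size drug-group mean shift in units of `sd`.
#' @param spared_band band centre (Hz) that receives no shift; `NA` shifts
#'   every band.
#' @param baseline common mean band power (AU).
#' @param sd noise standard deviation (AU).
#' @param seed integer seed; `NULL` consumes the current RNG stream.
#' @return A data frame: `subject_id`, `treatment`, `temp_c`, then one
#'   numeric column per band named `b<centre>`.
#' @export
#' @examples
#' d <- simulate_band_power_study(n_per_group = 6, seed = 10)
#' names(d)
simulate_band_power_study <- function(n_per_group = 15,
                                      temps = 31:36,
                                      band_centres = seq(0.1, 1.9, by = 0.2),
                                      effect_size = 0.8,
                                      spared_band = 0.5,
                                      baseline = 10, sd = 1,
                                      seed = NULL) {
  if (n_per_group < 2L) stop("need at least two records per group")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- length(band_centres)
  n <- 2L * n_per_group
  treatment <- rep(c("control", "drug"), each = n_per_group)
  shift <- rep(effect_size * sd, p)
  if (!is.na(spared_band)) {
    shift[abs(band_centres - spared_band) < 1e-9] <- 0
  }
  x <- matrix(stats::rnorm(n * p, baseline, sd), n, p)
  x[treatment == "drug", ] <- sweep(
    x[treatment == "drug", , drop = FALSE], 2L, shift, `+`
  )
  out <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    treatment = treatment,
    temp_c = rep_len(temps, n),
    stringsAsFactors = FALSE
  )
  bands <- as.data.frame(x)
  names(bands) <- sprintf("b%.1f", band_centres)
  cbind(out, bands)
}
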