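#' Working concentration after dilution
#'
#' @param stock stock concentration (mg/ml), positive.
#' @param dilution_factor fold dilution (>= 1); 100 means a 1:100 dilution.
#' @return Working concentration (mg/ml): `stock / dilution_factor`.
#' @export
#' @examples
#' dilution_concentration(20, 100)  # 0.2 mg/ml
dilution_concentration <- function(stock, dilution_factor) {
  if (!is.numeric(stock) || stock <= 0) {
    stop("`stock` must be a positive concentration (mg/ml)")
  }
  if (!is.numeric(dilution_factor) || dilution_factor < 1) {
    stop("`dilution_factor` must be at least 1")
  }
  stock / dilution_factor
}

#' Dose specification for a one-compartment concentration estimate
#'
#' @param dose_per_kg administered dose (ug/kg), positive.
#' @param vd_per_kg volume of distribution (l/kg), positive.
#' @param molar_mass compound molar mass (g/mol), positive.  Caller-supplied:
#'   the bundled example configuration carries 678.8 g/mol for the TRPV4
#'   antagonist GSK2193874 (vendor datasheet value).
#' @return An object of class `dose_spec`.
#' @export
dose_spec <- function(dose_per_kg, vd_per_kg, molar_mass) {
  vals <- c(dose_per_kg = dose_per_kg, vd_per_kg = vd_per_kg,
            molar_mass = molar_mass)
  if (any(!is.numeric(vals)) || any(vals <= 0)) {
    stop("all dose-spec fields must be positive")
  }
  structure(as.list(vals), class = "dose_spec")
}

#' Estimate plasma concentration from dose and volume of distribution
#'
#' One-compartment, instantaneous-distribution estimate: the plasma molar
#' concentration is `(dose / Vd) / molar_mass`.  With dose in ug/kg and Vd
#' in l/kg this gives ug/l, which divided by the molar mass (g/mol) yields
#' nmol/l (nM).  A 300 ug/kg dose with Vd between 1 and 10 l/kg and molar
#' mass 678.8 g/mol brackets roughly 40--400 nM.
#'
#' The estimate is dimensionally consistent: rescaling dose and Vd by the
#' same per-mass unit leaves the concentration unchanged.
#'
#' @param spec a [dose_spec()].
#' @param sig_figs significant figures for the rounded value (>= 1).
#' @return A list with `nM` (rounded to `sig_figs` significant figures) and
#'   `nM_unrounded`.
#' @export
#' @examples
#' estimate_plasma_concentration(dose_spec(300, 1, 678.8), sig_figs = 1)
estimate_plasma_concentration <- function(spec, sig_figs = 1) {
  stopifnot(inherits(spec, "dose_spec"))
  if (!is.numeric(sig_figs) || sig_figs < 1) {
    stop("`sig_figs` must be at least 1")
  }
  # ug/l divided by g/mol = nmol/l
  conc_nM <- (spec$dose_per_kg / spec$vd_per_kg) / spec$molar_mass * 1e3
  list(nM = signif(conc_nM, sig_figs), nM_unrounded = conc_nM)
}
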