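#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of corrected OD against standard
#' concentration, used to express FRAP results as Fe(2+) equivalents
#' (FeSO4.7H2O standards, 0.09-1.2 mM) and Folin-Ciocalteu results as
#' gallic acid equivalents (12.5-1000 ug/mL standards).
#'
#' @param standards data frame (or tibble) with columns `concentration`
#'   and `od` (corrected OD), one row per standard well.
#' @param analyte label, e.g. `"FeSO4"` or `"gallic_acid"`.
#' @return object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `range_low`, `range_high`, `analyte`.
#' @export
fit_linear_calibration <- function(standards, analyte = "analyte") {
  standards <- as.data.frame(standards)
  if (!all(c("concentration", "od") %in% names(standards))) {
    stop_phytoscreen("standards need 'concentration' and 'od' columns",
                     "calibration_error")
  }
  conc <- standards$concentration
  if (length(unique(conc)) < 2) {
    stop_phytoscreen("need at least 2 distinct standard concentrations",
                     "calibration_error")
  }
  fit <- stats::lm(od ~ concentration, data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (abs(slope) < 1e-12) {
    stop_phytoscreen("calibration slope is zero", "calibration_error")
  }
  tss <- sum((standards$od - mean(standards$od))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(
    list(analyte = analyte,
         slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         range_low = min(conc), range_high = max(conc)),
    class = "calibration_curve"
  )
}

#' Invert a calibration curve for a sample OD
#'
#' Returns the equivalent concentration `(od - intercept) / slope` in the
#' curve's units, flagging values outside the calibrated range.
#'
#' @param sample_od corrected absorbance(s).
#' @param curve a [fit_linear_calibration()] result.
#' @return tibble with `concentration` and logical `in_range`.
#' @export
equivalent_concentration <- function(sample_od, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (sample_od - curve$intercept) / curve$slope
  tibble::tibble(
    concentration = conc,
    in_range = conc >= curve$range_low & conc <= curve$range_high
  )
}

MOLAR_MASS_FE <- 55.845  # g/mol, elemental iron

#' Convert a well-equivalent concentration to a dry-weight basis
#'
#' Screening wells contain extract at a known concentration (100 ug/mL).
#' Equivalents measured per volume of well are therefore converted to
#' equivalents per mass of dry extract by dividing by the extract mass in
#' the same volume; any dilution factor cancels in the ratio.
#'
#' \describe{
#'   \item{FRAP}{input in mM Fe(2+) equivalents; output ug Fe per mg dry
#'     extract, via the molar mass of elemental iron
#'     (mM x 55.845 = ug Fe/mL, then / (mg extract/mL)).}
#'   \item{TPC}{input in ug gallic acid equivalents per mL; output mg GAE
#'     per g dry extract.}
#' }
#'
#' @param conc_in_well equivalent concentration in the well (mM Fe(2+) for
#'   FRAP, ug/mL GAE for TPC).
#' @param mode `"frap"` or `"tpc"`.
#' @param well_concentration extract concentration in the well, ug/mL.
#' @param molar_mass molar mass used for the FRAP conversion (g/mol).
#' @return value in ug Fe/mg DW (FRAP) or mg GAE/g DW (TPC).
#' @export
to_dry_weight_basis <- function(conc_in_well,
                                mode = c("frap", "tpc"),
                                well_concentration = 100,
                                molar_mass = MOLAR_MASS_FE) {
  mode <- match.arg(mode)
  if (!is.numeric(well_concentration) || length(well_concentration) != 1 ||
      !is.finite(well_concentration) || well_concentration <= 0) {
    stop_phytoscreen("well_concentration (ug/mL) must be a positive number",
                     "config_error")
  }
  if (mode == "frap") {
    # mM * (ug/umol) = ug Fe per mL; extract is well_concentration ug/mL;
    # ug Fe / ug extract * 1000 = ug Fe / mg extract
    ug_fe_per_ml <- conc_in_well * molar_mass
    ug_fe_per_ml / well_concentration * 1000
  } else {
    # ug GAE/mL over ug extract/mL = ug GAE/ug = mg/mg; * 1000 = mg GAE/g
    conc_in_well / well_concentration * 1000
  }
}

#' Percent change between two conditions
#'
#' `(treated - control) / control * 100`. Used to compare assay readouts
#' between cultivation conditions (e.g. FRAP under reduced temperature vs
#' the standard-temperature control).
#'
#' @param treated,control values in the same units.
#' @param digits rounding (half away from zero) applied to the result;
#'   `NULL` for no rounding. Whole-percent reporting uses `digits = 0`.
#' @return percent change.
#' @export
percent_change <- function(treated, control, digits = NULL) {
  if (any(control == 0)) {
    stop_phytoscreen("control value is zero", "degenerate_error")
  }
  pc <- (treated - control) / control * 100
  if (!is.null(digits)) pc <- round_half_up(pc, digits)
  pc
}
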