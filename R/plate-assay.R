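#' Assay specification
#'
#' Describes one screening assay: which inhibition formula it uses, the
#' read wavelength, and the extract concentration in the well. Screening
#' assays are run at a single concentration of 100 ug/mL per well.
#'
#' Hyaluronidase and collagenase assays are blank-referenced (the reaction
#' signal is read against an enzyme-free blank); DPPH, tyrosinase and
#' lipoxygenase are control-referenced (signal loss relative to a
#' no-extract control).
#'
#' @param name assay name, one of `"DPPH"`, `"hyaluronidase"`,
#'   `"tyrosinase"`, `"lipoxygenase"`, `"collagenase"`, `"FRAP"`, `"TPC"`.
#' @param assay_id identifier; defaults to `name`.
#' @param formula_variant `"control_referenced"` or `"blank_referenced"`;
#'   defaults to the convention for `name`.
#' @param wavelength read wavelength in nm (optional metadata).
#' @param well_concentration extract concentration in the well, ug/mL.
#' @return an object of class `assay_spec`.
#' @export
assay_spec <- function(name,
                       assay_id = name,
                       formula_variant = NULL,
                       wavelength = NA_real_,
                       well_concentration = 100) {
  known <- c("DPPH", "hyaluronidase", "tyrosinase", "lipoxygenase",
             "collagenase", "FRAP", "TPC")
  if (!name %in% known) {
    stop_phytoscreen(sprintf("unknown assay name '%s'", name), "config_error")
  }
  default_variant <- if (name %in% c("hyaluronidase", "collagenase")) {
    "blank_referenced"
  } else {
    "control_referenced"
  }
  formula_variant <- formula_variant %||% default_variant
  formula_variant <- match.arg(formula_variant,
                               c("control_referenced", "blank_referenced"))
  if (!is.numeric(well_concentration) || well_concentration <= 0) {
    stop_phytoscreen("well_concentration must be > 0", "config_error")
  }
  structure(
    list(assay_id = assay_id, name = name,
         formula_variant = formula_variant,
         wavelength = wavelength,
         well_concentration = well_concentration),
    class = "assay_spec"
  )
}

#' Corrected optical density
#'
#' Plate reads are taken twice per well (before and after the colour
#' reaction); the corrected OD is the first read minus the second. The
#' sign is preserved: wells whose signal increases give a negative value.
#'
#' @param od_first,od_second absorbance readings (AU).
#' @return `od_first - od_second`, vectorised.
#' @export
corrected_od <- function(od_first, od_second) {
  if (!all(is.finite(od_first)) || !all(is.finite(od_second))) {
    stop_phytoscreen("non-finite OD reading", "invalid_reading_error")
  }
  od_first - od_second
}

#' Control-referenced inhibition percentage
#'
#' \%I = (OD_control - OD_sample) / OD_control x 100, used for DPPH,
#' tyrosinase and lipoxygenase. Inputs are corrected ODs.
#'
#' @param od_sample,od_control corrected absorbances.
#' @return percent inhibition (may be negative or exceed 100).
#' @export
inhibition_control_referenced <- function(od_sample, od_control) {
  if (any(od_control == 0)) {
    stop_phytoscreen("control OD is zero", "degenerate_control_error")
  }
  (od_control - od_sample) / od_control * 100
}

#' Blank-referenced inhibition percentage
#'
#' Used for the hyaluronidase and collagenase assays, where the reaction
#' is read against an enzyme-free blank. Two parses of the formula are
#' provided:
#' \describe{
#'   \item{`"literal"`}{\%I = OD_sample / (OD_blank - OD_control) x 100
#'     (the default).}
#'   \item{`"normalized"`}{\%I = (OD_sample - OD_control) /
#'     (OD_blank - OD_control) x 100, the conventional normalized form.}
#' }
#' The intended reading of the published expression is ambiguous, so the
#' choice is exposed rather than asserted.
#'
#' @param od_sample,od_control,od_blank corrected absorbances.
#' @param variant `"literal"` or `"normalized"`.
#' @return percent inhibition.
#' @export
inhibition_blank_referenced <- function(od_sample, od_control, od_blank,
                                        variant = c("literal", "normalized")) {
  variant <- match.arg(variant)
  if (any(od_blank == od_control)) {
    stop_phytoscreen("blank OD equals control OD", "degenerate_denominator_error")
  }
  num <- switch(variant,
                literal = od_sample,
                normalized = od_sample - od_control)
  num / (od_blank - od_control) * 100
}

#' Technical-replicate statistics
#'
#' Summarises per-well inhibition percentages into mean, sample SD
#' (n - 1 denominator) and SEM = SD / sqrt(n). A single replicate has no
#' defined SD; it is reported as 0 with `sd_defined = FALSE`, and SEM 0.
#'
#' @param values numeric vector of percent inhibition, one per replicate.
#' @return list with `mean`, `sd`, `sem`, `n`, `sd_defined`.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0) {
    stop_phytoscreen("no replicate values", "no_replicates_error")
  }
  n <- length(values)
  m <- mean(values)
  if (n == 1) {
    list(mean = m, sd = 0, sem = 0, n = 1L, sd_defined = FALSE)
  } else {
    s <- stats::sd(values)
    list(mean = m, sd = s, sem = s / sqrt(n), n = as.integer(n),
         sd_defined = TRUE)
  }
}

#' Process a plate of well readings into per-extract inhibition results
#'
#' Corrects every well's OD pair, averages the control (and blank, when the
#' assay is blank-referenced) corrected ODs across the plate, computes
#' per-well inhibition for each sample well under the assay's formula, and
#' aggregates technical replicates per extract.
#'
#' @param readings a data frame of well readings with columns `plate_id`,
#'   `well`, `role` (`sample`/`control`/`blank`/`standard`), `extract_id`,
#'   `assay_id`, `od_first`, `od_second`.
#' @param spec an [assay_spec()].
#' @param blank_variant parse of the blank-referenced formula, see
#'   [inhibition_blank_referenced()].
#' @return a tibble with one row per extract: `extract_id`, `assay_id`,
#'   `mean_inhibition`, `sd`, `sem`, `n_replicates`.
#' @export
process_plate <- function(readings, spec,
                          blank_variant = c("literal", "normalized")) {
  blank_variant <- match.arg(blank_variant)
  stopifnot(inherits(spec, "assay_spec"))
  readings <- tibble::as_tibble(readings)
  required <- c("well", "role", "extract_id", "assay_id",
                "od_first", "od_second")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols)) {
    stop_phytoscreen(
      paste("plate table missing columns:",
            paste(missing_cols, collapse = ", ")),
      "validation_error"
    )
  }
  known <- readings$assay_id %in% spec$assay_id
  if (!all(known)) {
    stop_phytoscreen(
      sprintf("readings carry assay_id not matching spec '%s'", spec$assay_id),
      "config_error"
    )
  }
  readings$corrected <- corrected_od(readings$od_first, readings$od_second)

  controls <- readings$corrected[readings$role == "control"]
  if (length(controls) == 0) {
    stop_phytoscreen("plate has no control wells", "layout_error")
  }
  od_control <- mean(controls)

  od_blank <- NA_real_
  if (spec$formula_variant == "blank_referenced") {
    blanks <- readings$corrected[readings$role == "blank"]
    if (length(blanks) == 0) {
      stop_phytoscreen("blank-referenced assay but plate has no blank wells",
                       "layout_error")
    }
    od_blank <- mean(blanks)
  }

  samples <- readings[readings$role == "sample", , drop = FALSE]
  if (nrow(samples) == 0) {
    stop_phytoscreen("plate has no sample wells", "layout_error")
  }
  samples$inhibition <- if (spec$formula_variant == "control_referenced") {
    inhibition_control_referenced(samples$corrected, od_control)
  } else {
    inhibition_blank_referenced(samples$corrected, od_control, od_blank,
                                variant = blank_variant)
  }

  out <- lapply(split(samples, samples$extract_id), function(df) {
    st <- aggregate_replicates(df$inhibition)
    tibble::tibble(extract_id = df$extract_id[1],
                   assay_id = spec$assay_id,
                   mean_inhibition = st$mean, sd = st$sd, sem = st$sem,
                   n_replicates = st$n)
  })
  out <- dplyr::bind_rows(out)
  out[order(out$extract_id), , drop = FALSE]
}
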