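#' Published screening tables bundled with the package
#'
#' Accessors for the study's printed data tables, shipped as plain CSV
#' under `inst/extdata` and parsed by the package's validated readers:
#'
#' - `screening_grades()`: plus-grades of the 18 shortlisted species (two
#'   extracts each, five assays) plus the two assay reference rows, with
#'   the printed extract and species scores alongside for cross-checking.
#' - `innovation_rubric()`: market/patent/literature sub-scores and the
#'   printed innovation score for each species.
#' - `cultivation_results()`: antioxidant and anti-inflammatory readouts
#'   (mean and SEM of three technical replicates) of indoor-grown borage
#'   under standard temperature, reduced temperature, and reduced
#'   temperature plus water stress.
#' - `study_funnel_retention()`: the candidate counts remaining after each
#'   stage of the species-selection funnel, starting from the 1614
#'   IECIC-listed botanical candidates.
#'
#' @return a tibble (an integer vector for `study_funnel_retention()`).
#' @name study_tables
NULL

#' @rdname study_tables
#' @export
screening_grades <- function() {
  read_grades_csv(system.file("extdata", "bioactivity_grades.csv",
                              package = "phytoscreen", mustWork = TRUE))
}

#' @rdname study_tables
#' @export
innovation_rubric <- function() {
  read_rubric_csv(system.file("extdata", "innovation_rubric.csv",
                              package = "phytoscreen", mustWork = TRUE))
}

#' @rdname study_tables
#' @export
cultivation_results <- function() {
  read_checked_csv(system.file("extdata", "cultivation_results.csv",
                               package = "phytoscreen", mustWork = TRUE),
                   c("condition", "measure", "value", "sem", "units"))
}

#' @rdname study_tables
#' @export
study_funnel_retention <- function() {
  c(1614L, 1532L, 1509L, 415L, 415L, 177L, 64L, 18L)
}
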