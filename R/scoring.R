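GRADE_LEVELS <- c("-", "+", "++", "+++", "++++", "n.d.")

#' Normalize grade symbols
#'
#' Accepts both the ASCII hyphen-minus and the Unicode minus sign for the
#' negative grade, plus `nd`/`ND` spellings of "not determined", and
#' returns canonical symbols (`-`, `+`, `++`, `+++`, `++++`, `n.d.`).
#'
#' @param x character vector of grade symbols.
#' @return canonical character vector.
#' @export
normalize_grade <- function(x) {
  x <- trimws(as.character(x))
  x[x == "−"] <- "-"
  x[tolower(x) %in% c("nd", "n.d", "n.d.")] <- "n.d."
  bad <- !(x %in% GRADE_LEVELS)
  if (any(bad)) {
    stop_phytoscreen(
      sprintf("invalid grade symbol(s): %s",
              paste(unique(x[bad]), collapse = ", ")),
      "validation_error"
    )
  }
  x
}

#' Points carried by a plus-grade
#'
#' One point per `+`; `-` carries 0; `n.d.` carries `NA` and contributes
#' neither points nor an assay to the score denominator.
#'
#' @param grade character vector of (canonical or raw) grade symbols.
#' @return integer vector of points, `NA` for `n.d.`.
#' @export
grade_points <- function(grade) {
  grade <- normalize_grade(grade)
  pts <- c("-" = 0L, "+" = 1L, "++" = 2L, "+++" = 3L, "++++" = 4L,
           "n.d." = NA_integer_)
  unname(pts[grade])
}

#' Semi-quantitative grade from percent inhibition
#'
#' 20-point bins, closed on the left so the boundary values fall in the
#' upper bin: below 20 is `-`, \[20, 40) is `+`, \[40, 60) is `++`,
#' \[60, 80) is `+++`, and 80 or more is `++++`. Negative inhibition
#' grades as `-`.
#'
#' @param mean_inhibition percent inhibition (replicate mean).
#' @return character vector of grade symbols.
#' @export
grade_from_percent <- function(mean_inhibition) {
  if (!all(is.finite(mean_inhibition))) {
    stop_phytoscreen("non-finite inhibition value", "invalid_error")
  }
  cut_points <- c(-Inf, 20, 40, 60, 80, Inf)
  as.character(cut(mean_inhibition, cut_points,
                   labels = GRADE_LEVELS[1:5], right = FALSE))
}

#' Extract-level bioactivity score
#'
#' Sums grade points over the determined assays and normalizes by the
#' maximum achievable (4 points per determined assay), scaled to 0-100 and
#' rounded half-up to one decimal. `n.d.` assays are excluded from both
#' numerator and denominator, so a four-assay extract is scored out of 16
#' and a three-assay extract out of 12.
#'
#' @param grades character vector of grade symbols for one extract.
#' @return score in \[0, 100\], one decimal.
#' @export
extract_bioactivity_score <- function(grades) {
  pts <- grade_points(grades)
  determined <- !is.na(pts)
  if (!any(determined)) {
    stop_phytoscreen("all assays are n.d.; extract is unscorable",
                     "unscorable_error")
  }
  raw <- sum(pts[determined])
  round_half_up(100 * raw / (4 * sum(determined)), 1)
}

#' Species-level bioactivity score
#'
#' Mean of the per-extract scores (hydroalcoholic and propylene glycol
#' extracts of the same plant), rounded half-up to an integer. A species
#' with a single extract passes that extract's score through.
#'
#' @param extract_scores numeric vector of one or two extract scores.
#' @return integer score in \[0, 100\].
#' @export
species_bioactivity_score <- function(extract_scores) {
  if (length(extract_scores) == 0) {
    stop_phytoscreen("no extract scores", "unscorable_error")
  }
  as.integer(round_half_up(mean(extract_scores)))
}

#' Innovation score from rubric sub-scores
#'
#' Three expert sub-scores (market presence, patent coverage, literature
#' documentation), each 0-3, are summed (max 9) and normalized to 0-100,
#' rounded half-up. The attainable values are exactly
#' \{0, 11, 22, 33, 44, 56, 67, 78, 89, 100\}.
#'
#' @param market,patent,literature integer sub-scores in 0-3 (vectorised).
#' @return integer score(s) in \[0, 100\].
#' @export
innovation_score <- function(market, patent, literature) {
  sub <- cbind(market, patent, literature)
  if (!all(sub %in% 0:3)) {
    stop_phytoscreen("rubric sub-scores must be integers in 0..3",
                     "validation_error")
  }
  as.integer(round_half_up(100 * (market + patent + literature) / 9))
}

ASSAY_COLUMNS <- c("dpph", "hyaluronidase", "tyrosinase",
                   "lipoxygenase", "collagenase")

#' Score a table of extract grade rows
#'
#' Takes a long grade table (one row per extract, one column per assay
#' holding grade symbols) and computes per-extract bioactivity scores and
#' per-species averages. When the table carries `printed_extract_score` /
#' `printed_species_score` columns, computed values are compared against
#' them and any mismatch is reported as a warning (not altered): the
#' published table contains a small number of rows whose printed scores do
#' not follow the stated rule.
#'
#' @param grades data frame with columns `species`, `extract` (`HA`/`PG`
#'   or a reference label) and the five assay columns
#'   `dpph`, `hyaluronidase`, `tyrosinase`, `lipoxygenase`, `collagenase`.
#' @return list with `extracts` (tibble: species, extract, score) and
#'   `species` (tibble: species, bioactivity_score).
#' @export
score_bioactivity_table <- function(grades) {
  grades <- tibble::as_tibble(grades)
  missing_cols <- setdiff(c("species", "extract", ASSAY_COLUMNS), names(grades))
  if (length(missing_cols)) {
    stop_phytoscreen(
      paste("grade table missing columns:",
            paste(missing_cols, collapse = ", ")),
      "validation_error"
    )
  }
  grades$score <- vapply(seq_len(nrow(grades)), function(i) {
    extract_bioactivity_score(unlist(grades[i, ASSAY_COLUMNS]))
  }, numeric(1))

  extracts <- grades[, c("species", "extract", "score")]
  species <- dplyr::summarise(
    dplyr::group_by(grades, .data$species),
    bioactivity_score = species_bioactivity_score(.data$score),
    .groups = "drop"
  )

  if ("printed_extract_score" %in% names(grades)) {
    off <- which(!is.na(grades$printed_extract_score) &
                   abs(grades$printed_extract_score - grades$score) > 1e-9)
    for (i in off) {
      warning(sprintf(
        "extract score for %s (%s) computed as %.1f but printed as %.1f",
        grades$species[i], grades$extract[i],
        grades$score[i], grades$printed_extract_score[i]
      ), call. = FALSE)
    }
  }
  if ("printed_species_score" %in% names(grades)) {
    printed <- dplyr::summarise(
      dplyr::group_by(grades, .data$species),
      printed = .data$printed_species_score[1], .groups = "drop"
    )
    cmp <- dplyr::left_join(species, printed, by = "species")
    off <- which(!is.na(cmp$printed) &
                   cmp$printed != cmp$bioactivity_score)
    for (i in off) {
      warning(sprintf(
        "species score for %s computed as %d but printed as %d",
        cmp$species[i], cmp$bioactivity_score[i], as.integer(cmp$printed[i])
      ), call. = FALSE)
    }
  }
  list(extracts = extracts, species = species)
}

#' Score an innovation rubric table
#'
#' @param rubric data frame with columns `species`, `market`, `patent`,
#'   `literature`.
#' @return tibble with `species`, `innovation_score`.
#' @export
score_innovation_table <- function(rubric) {
  rubric <- tibble::as_tibble(rubric)
  missing_cols <- setdiff(c("species", "market", "patent", "literature"),
                          names(rubric))
  if (length(missing_cols)) {
    stop_phytoscreen(
      paste("rubric table missing columns:",
            paste(missing_cols, collapse = ", ")),
      "validation_error"
    )
  }
  tibble::tibble(
    species = rubric$species,
    innovation_score = innovation_score(rubric$market, rubric$patent,
                                        rubric$literature)
  )
}
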