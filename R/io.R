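read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop_phytoscreen(sprintf("file not found: %s", path), "io_error")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      stop_phytoscreen(sprintf("cannot parse %s: %s", path,
                               conditionMessage(e)), "validation_error")
    }
  )
  if (nrow(df) == 0) {
    stop_phytoscreen(sprintf("empty input: %s", path), "empty_input_error")
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_phytoscreen(
      sprintf("%s missing columns: %s", path,
              paste(missing_cols, collapse = ", ")),
      "validation_error"
    )
  }
  df
}

#' Read a grade table CSV
#'
#' One row per extract; one column per assay holding plus-grade symbols.
#' Both the ASCII hyphen-minus and the Unicode minus sign are accepted as
#' the negative grade; invalid symbols raise an error naming the row and
#' column.
#'
#' @param path CSV path.
#' @return validated tibble with canonical grade symbols.
#' @export
read_grades_csv <- function(path) {
  df <- read_checked_csv(path, c("species", "extract", ASSAY_COLUMNS))
  for (col in ASSAY_COLUMNS) {
    vals <- as.character(df[[col]])
    for (i in seq_along(vals)) {
      ok <- tryCatch({ normalize_grade(vals[i]); TRUE },
                     phytoscreen_error = function(e) FALSE)
      if (!ok) {
        stop_phytoscreen(
          sprintf("%s: invalid grade '%s' at row %d, column '%s'",
                  path, vals[i], i, col),
          "validation_error"
        )
      }
    }
    df[[col]] <- normalize_grade(vals)
  }
  df
}

#' Read an innovation rubric CSV
#'
#' @param path CSV with columns `species`, `market`, `patent`,
#'   `literature` (each sub-score an integer 0-3).
#' @return validated tibble.
#' @export
read_rubric_csv <- function(path) {
  df <- read_checked_csv(path, c("species", "market", "patent", "literature"))
  for (col in c("market", "patent", "literature")) {
    bad <- which(!(df[[col]] %in% 0:3))
    if (length(bad)) {
      stop_phytoscreen(
        sprintf("%s: sub-score out of 0..3 at row %d, column '%s'",
                path, bad[1], col),
        "validation_error"
      )
    }
  }
  df
}

#' Read a candidate registry CSV
#'
#' @param path CSV with a `botanical_name` column and one column per
#'   funnel attribute.
#' @return validated tibble.
#' @export
read_registry_csv <- function(path) {
  read_checked_csv(path, "botanical_name")
}

#' Read a long-format plate CSV
#'
#' @param path CSV with columns `plate_id`, `well`, `role`, `extract_id`,
#'   `assay_id`, `od_first`, `od_second`.
#' @return validated tibble.
#' @export
read_plate_csv <- function(path) {
  df <- read_checked_csv(path, c("plate_id", "well", "role", "extract_id",
                                 "assay_id", "od_first", "od_second"))
  # control/blank wells carry no extract; empty cells come back as NA
  df$extract_id <- as.character(df$extract_id)
  df$extract_id[is.na(df$extract_id)] <- ""
  roles <- c("sample", "control", "blank", "standard")
  bad <- which(!df$role %in% roles)
  if (length(bad)) {
    stop_phytoscreen(
      sprintf("%s: invalid role '%s' at row %d", path, df$role[bad[1]], bad[1]),
      "validation_error"
    )
  }
  for (col in c("od_first", "od_second")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop_phytoscreen(
        sprintf("%s: non-finite %s at row %d", path, col, bad[1]),
        "validation_error"
      )
    }
  }
  dup <- duplicated(df[, c("plate_id", "well")])
  if (any(dup)) {
    stop_phytoscreen(
      sprintf("%s: duplicate well %s on plate %s",
              path, df$well[dup][1], df$plate_id[dup][1]),
      "validation_error"
    )
  }
  df
}

#' Write a tibble as CSV
#'
#' Plain UTF-8 comma-separated output with a header row; the counterpart
#' readers parse it back to equal records.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Run the screening analysis end to end
#'
#' Scores a grade table and an innovation rubric, joins them into species
#' profiles, applies the dual-score thresholds, and (optionally) runs a
#' candidate funnel. Inputs may be file paths or in-memory data frames.
#'
#' @param grades grade table (path or data frame), see [read_grades_csv()].
#' @param rubric innovation rubric (path or data frame).
#' @param policy a [threshold_policy()].
#' @param registry optional candidate registry (path or data frame).
#' @param funnel_rules rules used when `registry` is given.
#' @param unknown_policy unknown-attribute policy for the funnel.
#' @param out_dir optional directory; when given, writes
#'   `extract_scores.csv`, `species_profiles.csv`, `scatter.csv`,
#'   `shortlist.csv`, `report.json` (and `funnel_audit.csv` when a
#'   registry is supplied).
#' @return list with `extracts`, `profiles` (species, bioactivity,
#'   innovation, quadrant), `shortlist`, `scatter`, and `funnel`
#'   (`NULL` without a registry).
#' @export
run_pipeline <- function(grades, rubric,
                         policy = threshold_policy(),
                         registry = NULL,
                         funnel_rules = default_funnel_rules(),
                         unknown_policy = "drop",
                         out_dir = NULL) {
  if (is.character(grades)) grades <- read_grades_csv(grades)
  if (is.character(rubric)) rubric <- read_rubric_csv(rubric)
  if ("is_reference" %in% names(grades)) {
    grades <- grades[!grades$is_reference | is.na(grades$is_reference), ,
                     drop = FALSE]
  }

  bio <- score_bioactivity_table(grades)
  innov <- score_innovation_table(rubric)
  profiles <- dplyr::inner_join(bio$species, innov, by = "species")
  report <- prioritize(profiles, policy)

  funnel_out <- NULL
  if (!is.null(registry)) {
    if (is.character(registry)) registry <- read_registry_csv(registry)
    funnel_out <- apply_funnel(registry, funnel_rules,
                               unknown_policy = unknown_policy)
  }

  result <- list(
    extracts = bio$extracts,
    profiles = report$profiles,
    shortlist = report$shortlist,
    scatter = scatter_export(profiles),
    funnel = funnel_out
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(result$extracts, file.path(out_dir, "extract_scores.csv"))
    write_table_csv(result$profiles, file.path(out_dir, "species_profiles.csv"))
    write_table_csv(result$scatter, file.path(out_dir, "scatter.csv"))
    write_table_csv(tibble::tibble(species = result$shortlist),
                    file.path(out_dir, "shortlist.csv"))
    json <- list(
      thresholds = list(min_innovation = policy$min_innovation,
                        min_bioactivity = policy$min_bioactivity),
      shortlist = result$shortlist,
      n_species = nrow(result$profiles)
    )
    if (!is.null(funnel_out)) {
      json$funnel_counts <- funnel_out$counts
      write_table_csv(funnel_out$audit, file.path(out_dir, "funnel_audit.csv"))
    }
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
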