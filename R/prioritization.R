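#' Dual-score threshold policy
#'
#' Default thresholds shortlist species with innovation score >= 60 and
#' bioactivity score >= 40. Both comparisons are inclusive: a species
#' sitting exactly on a threshold is retained.
#'
#' @param min_innovation minimum innovation score (0-100).
#' @param min_bioactivity minimum bioactivity score (0-100).
#' @return object of class `threshold_policy`.
#' @export
threshold_policy <- function(min_innovation = 60, min_bioactivity = 40) {
  if (min_innovation < 0 || min_innovation > 100 ||
      min_bioactivity < 0 || min_bioactivity > 100) {
    stop_phytoscreen("thresholds must lie in [0, 100]", "config_error")
  }
  structure(list(min_innovation = min_innovation,
                 min_bioactivity = min_bioactivity),
            class = "threshold_policy")
}

#' Classify species into scatter quadrants
#'
#' Positions each species in the bioactivity (x) vs innovation (y) plane
#' relative to the policy thresholds. The upper-right quadrant (both
#' scores at or above threshold) holds the prioritized candidates.
#'
#' @param bioactivity,innovation numeric score vectors (0-100).
#' @param policy a [threshold_policy()].
#' @return character vector among `upper-right`, `upper-left`,
#'   `lower-right`, `lower-left`.
#' @export
classify_quadrant <- function(bioactivity, innovation,
                              policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  hi_b <- bioactivity >= policy$min_bioactivity
  hi_i <- innovation >= policy$min_innovation
  dplyr::case_when(
    hi_i & hi_b ~ "upper-right",
    hi_i & !hi_b ~ "upper-left",
    !hi_i & hi_b ~ "lower-right",
    TRUE ~ "lower-left"
  )
}

#' Shortlist species passing both thresholds
#'
#' Returns the upper-right quadrant members ordered by innovation score
#' (descending), then bioactivity score (descending), then species name.
#'
#' @param profiles data frame with columns `species`, `bioactivity_score`,
#'   `innovation_score`.
#' @param policy a [threshold_policy()].
#' @return character vector of species names (possibly empty).
#' @export
shortlist <- function(profiles, policy = threshold_policy()) {
  profiles <- tibble::as_tibble(profiles)
  if (nrow(profiles) == 0) return(character(0))
  q <- classify_quadrant(profiles$bioactivity_score,
                         profiles$innovation_score, policy)
  keep <- profiles[q == "upper-right", , drop = FALSE]
  keep <- keep[order(-keep$innovation_score, -keep$bioactivity_score,
                     keep$species), , drop = FALSE]
  keep$species
}

#' Full prioritization report
#'
#' @param profiles data frame with `species`, `bioactivity_score`,
#'   `innovation_score`.
#' @param policy a [threshold_policy()].
#' @return list with `profiles` (input plus `quadrant` column),
#'   `shortlist` and `policy`.
#' @export
prioritize <- function(profiles, policy = threshold_policy()) {
  profiles <- tibble::as_tibble(profiles)
  profiles$quadrant <- if (nrow(profiles)) {
    classify_quadrant(profiles$bioactivity_score,
                      profiles$innovation_score, policy)
  } else {
    character(0)
  }
  list(profiles = profiles,
       shortlist = shortlist(profiles, policy),
       policy = policy)
}

#' Plot-ready scatter table
#'
#' Lossless mapping of score profiles onto plotting axes: x is the
#' bioactivity score, y the innovation score, both on \[0, 100\].
#'
#' @param profiles data frame with `species`, `bioactivity_score`,
#'   `innovation_score`.
#' @return tibble with `species`, `x`, `y`.
#' @export
scatter_export <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  tibble::tibble(species = profiles$species,
                 x = profiles$bioactivity_score,
                 y = profiles$innovation_score)
}
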