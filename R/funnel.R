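DISTRIBUTION_LEVELS <- c("extremely_rare", "rare", "uncommon",
                         "common", "very_common")

#' Declarative predicates for funnel rules
#'
#' Small composable predicate language over candidate attributes, used to
#' express each funnel stage's keep condition:
#' \describe{
#'   \item{`flag_equals(attr, value)`}{logical attribute equals `value`.}
#'   \item{`ordinal_at_least(attr, level, levels)`}{ordinal attribute sits
#'     at or above `level` in the ordering `levels` (defaults to the
#'     distribution-class ordering extremely_rare < rare < uncommon <
#'     common < very_common).}
#'   \item{`in_set(attr, values, universe)`}{attribute is one of `values`;
#'     `universe` (optional) lists all possible values, which lets the
#'     registry simulator sample failing assignments.}
#'   \item{`pred_all(...)`, `pred_any(...)`, `pred_not(p)`}{boolean combinators.}
#' }
#' Predicates evaluate to `NA` when a referenced attribute is missing or
#' `NA`; [apply_funnel()]'s unknown policy decides what `NA` means.
#'
#' @param attr attribute (column) name.
#' @param value,values,level expected value(s) / minimum ordinal level.
#' @param universe all possible values of the attribute (optional).
#' @param levels ordinal ordering, low to high.
#' @param ...,p component predicates.
#' @return a `funnel_predicate` object.
#' @name funnel_predicates
NULL

new_predicate <- function(type, ...) {
  structure(list(type = type, ...), class = "funnel_predicate")
}

#' @rdname funnel_predicates
#' @export
flag_equals <- function(attr, value) {
  new_predicate("flag_equals", attr = attr, value = value)
}

#' @rdname funnel_predicates
#' @export
ordinal_at_least <- function(attr, level, levels = DISTRIBUTION_LEVELS) {
  if (!level %in% levels) {
    stop_phytoscreen(sprintf("level '%s' not in ordering", level),
                     "config_error")
  }
  new_predicate("ordinal_at_least", attr = attr, level = level,
                levels = levels)
}

#' @rdname funnel_predicates
#' @export
in_set <- function(attr, values, universe = NULL) {
  new_predicate("in_set", attr = attr, values = values, universe = universe)
}

#' @rdname funnel_predicates
#' @export
pred_all <- function(...) new_predicate("pred_all", parts = list(...))

#' @rdname funnel_predicates
#' @export
pred_any <- function(...) new_predicate("pred_any", parts = list(...))

#' @rdname funnel_predicates
#' @export
pred_not <- function(p) new_predicate("pred_not", part = p)

pred_attr_value <- function(record, attr) {
  if (!attr %in% names(record)) return(NULL)
  record[[attr]]
}

#' Evaluate a predicate on one candidate record
#'
#' @param pred a `funnel_predicate`.
#' @param record a one-row data frame or named list of attributes.
#' @return `TRUE`, `FALSE`, or `NA` (unknown attribute or value).
#' @export
eval_predicate <- function(pred, record) {
  stopifnot(inherits(pred, "funnel_predicate"))
  switch(pred$type,
    flag_equals = {
      v <- pred_attr_value(record, pred$attr)
      if (is.null(v) || is.na(v)) NA else identical(as.logical(v), pred$value)
    },
    ordinal_at_least = {
      v <- pred_attr_value(record, pred$attr)
      if (is.null(v) || is.na(v)) return(NA)
      if (!v %in% pred$levels) return(NA)
      match(v, pred$levels) >= match(pred$level, pred$levels)
    },
    in_set = {
      v <- pred_attr_value(record, pred$attr)
      if (is.null(v) || is.na(v)) NA else v %in% pred$values
    },
    pred_all = {
      vals <- vapply(pred$parts, eval_predicate, logical(1), record = record)
      if (any(vals %in% FALSE)) FALSE else if (anyNA(vals)) NA else TRUE
    },
    pred_any = {
      vals <- vapply(pred$parts, eval_predicate, logical(1), record = record)
      if (any(vals %in% TRUE)) TRUE else if (anyNA(vals)) NA else FALSE
    },
    pred_not = {
      v <- eval_predicate(pred$part, record)
      if (is.na(v)) NA else !v
    },
    stop_phytoscreen(sprintf("unknown predicate type '%s'", pred$type),
                     "config_error")
  )
}

#' Construct a funnel stage rule
#'
#' @param stage_name label for the stage.
#' @param keep a `funnel_predicate`; records for which it is `TRUE` pass
#'   to the next stage.
#' @return a `filter_rule` object.
#' @export
filter_rule <- function(stage_name, keep) {
  stopifnot(is.character(stage_name), inherits(keep, "funnel_predicate"))
  structure(list(stage_name = stage_name, keep = keep),
            class = "filter_rule")
}

#' Default candidate-selection funnel
#'
#' The ordered rule set used for the species-selection study, starting
#' from a registry of plants listed for cosmetic use in the Chinese
#' regulatory framework (IECIC):
#' \enumerate{
#'   \item drop species prohibited or restricted under the European
#'     cosmetic regulation;
#'   \item drop species on any CITES appendix;
#'   \item keep species present in mainland France;
#'   \item drop species protected in the French national inventory (INPN)
#'     — a stage that may legitimately remove nothing;
#'   \item keep species whose distribution class is common or very common;
#'   \item keep species retained by the bibliographic innovation review
#'     (expert flag);
#'   \item keep species with a feasible supply chain that are not
#'     invasive (expert flags).
#' }
#'
#' @return list of [filter_rule()]s, in order.
#' @export
default_funnel_rules <- function() {
  list(
    filter_rule("eu_regulation",
                flag_equals("eu_prohibited_or_restricted", FALSE)),
    filter_rule("cites", in_set("cites_appendix", "none",
                                universe = c("none", "I", "II", "III"))),
    filter_rule("mainland_france",
                flag_equals("present_mainland_france", TRUE)),
    filter_rule("inpn_protection", flag_equals("inpn_protected", FALSE)),
    filter_rule("distribution",
                ordinal_at_least("distribution_class", "common")),
    filter_rule("innovation_review",
                flag_equals("innovation_retained", TRUE)),
    filter_rule("supply_chain",
                pred_all(flag_equals("supply_feasible", TRUE),
                       flag_equals("invasive", FALSE)))
  )
}

#' Apply an ordered funnel of filter rules
#'
#' Evaluates every record against the rules in order; a record is dropped
#' at its first failing stage and never evaluated further (short-circuit).
#' Unknown (`NA`) predicate outcomes are resolved by `unknown_policy`:
#' `"drop"` (precautionary default — treat unknown as failing), `"keep"`,
#' or `"strict"` (raise a schema error).
#'
#' @param records data frame, one row per candidate, with an identifier
#'   column `botanical_name` and one column per attribute.
#' @param rules ordered list of [filter_rule()]s.
#' @param unknown_policy `"drop"`, `"keep"` or `"strict"`.
#' @return a `funnel_report` list: `stages` (tibble with `order`, `stage`,
#'   `n_in`, `n_out`), `audit` (tibble with `botanical_name`,
#'   `first_drop_stage` (`NA` if retained), `retained`), `retained`
#'   (character vector), `counts` (input count followed by each stage's
#'   output count).
#' @export
apply_funnel <- function(records, rules,
                         unknown_policy = c("drop", "keep", "strict")) {
  unknown_policy <- match.arg(unknown_policy)
  records <- tibble::as_tibble(records)
  if (!"botanical_name" %in% names(records)) {
    stop_phytoscreen("records need a 'botanical_name' column",
                     "validation_error")
  }
  if (length(rules) == 0) {
    stop_phytoscreen("funnel needs at least one rule", "config_error")
  }
  stopifnot(all(vapply(rules, inherits, logical(1), "filter_rule")))

  n <- nrow(records)
  alive <- rep(TRUE, n)
  first_drop <- rep(NA_character_, n)
  stages <- vector("list", length(rules))

  for (k in seq_along(rules)) {
    rule <- rules[[k]]
    n_in <- sum(alive)
    for (i in which(alive)) {
      keep <- eval_predicate(rule$keep, records[i, , drop = FALSE])
      if (is.na(keep)) {
        keep <- switch(unknown_policy,
          drop = FALSE,
          keep = TRUE,
          strict = stop_phytoscreen(
            sprintf("unknown attribute value at stage '%s' for record '%s'",
                    rule$stage_name, records$botanical_name[i]),
            "schema_error")
        )
      }
      if (!keep) {
        alive[i] <- FALSE
        first_drop[i] <- rule$stage_name
      }
    }
    stages[[k]] <- tibble::tibble(order = k, stage = rule$stage_name,
                                  n_in = n_in, n_out = sum(alive))
  }

  stages <- dplyr::bind_rows(stages)
  structure(
    list(
      stages = stages,
      audit = tibble::tibble(botanical_name = records$botanical_name,
                             first_drop_stage = first_drop,
                             retained = alive),
      retained = records$botanical_name[alive],
      counts = c(n, stages$n_out)
    ),
    class = "funnel_report"
  )
}
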