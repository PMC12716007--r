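# A minimal plate table built in code: three replicate sample wells per
# extract, plus control (and optionally blank) wells, all with constant
# corrected ODs (od_second fixed at 0.1).
make_plate <- function(sample_ods, control_od = 1.0, blank_od = NULL,
                       assay_id = "DPPH") {
  rows <- list()
  add <- function(role, extract_id, corrected) {
    tibble::tibble(plate_id = "P1", well = "", role = role,
                   extract_id = extract_id, assay_id = assay_id,
                   od_first = 0.1 + corrected, od_second = 0.1)
  }
  for (k in seq_len(3)) rows[[length(rows) + 1]] <- add("control", "", control_od)
  if (!is.null(blank_od)) {
    for (k in seq_len(3)) rows[[length(rows) + 1]] <- add("blank", "", blank_od)
  }
  for (ex in names(sample_ods)) {
    for (k in seq_len(3)) rows[[length(rows) + 1]] <- add("sample", ex, sample_ods[[ex]])
  }
  out <- dplyr::bind_rows(rows)
  out$well <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_len(nrow(out))]
  out
}

# Independent normal-equations least-squares oracle.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# A small three-stage funnel over plain flags, for count fixtures.
toy_rules <- function() {
  list(
    filter_rule("stage_a", flag_equals("a", TRUE)),
    filter_rule("stage_b", flag_equals("b", TRUE)),
    filter_rule("stage_c", flag_equals("c", TRUE))
  )
}

ASSAY_COLUMNS_TEST <- c("dpph", "hyaluronidase", "tyrosinase",
                        "lipoxygenase", "collagenase")
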