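WELL_POSITIONS <- as.vector(outer(LETTERS[1:8], 1:12, paste0))

implied_sample_od <- function(true_inhibition, control_od, blank_od,
                              formula_variant, blank_variant) {
  if (formula_variant == "control_referenced") {
    control_od * (1 - true_inhibition / 100)
  } else if (blank_variant == "literal") {
    true_inhibition / 100 * (blank_od - control_od)
  } else {
    control_od + true_inhibition / 100 * (blank_od - control_od)
  }
}

#' Simulate a screening plate with known true inhibition
#'
#' Generates well readings whose corrected ODs are the exact inverse of
#' the chosen inhibition formula at the requested true inhibition, plus
#' additive Gaussian noise on every measured well (samples, controls and
#' blanks). Each corrected OD is split into a read pair with the second
#' read fixed at a baseline constant, so [corrected_od()] recovers it
#' exactly. With `noise_sd = 0` the plate round-trips through
#' [process_plate()] to the true inhibition exactly.
#'
#' @param true_inhibition named numeric vector: true percent inhibition
#'   per extract (names become `extract_id`s).
#' @param control_od true corrected OD of control wells (AU).
#' @param blank_od true corrected OD of blank wells (AU); required for
#'   blank-referenced assays.
#' @param noise_sd additive Gaussian noise SD on corrected OD (AU).
#' @param n_replicates technical replicates per extract (and for the
#'   control/blank wells).
#' @param seed integer seed; the simulation is deterministic given it.
#' @param assay an [assay_spec()]; its `formula_variant` decides the
#'   inverse formula.
#' @param blank_variant parse of the blank-referenced formula.
#' @param baseline_od constant second read (AU).
#' @return tibble of well readings accepted by [process_plate()].
#' @export
generate_plate <- function(true_inhibition,
                           control_od = 1.0,
                           blank_od = NA_real_,
                           noise_sd = 0.01,
                           n_replicates = 3,
                           seed = 1L,
                           assay = assay_spec("DPPH"),
                           blank_variant = c("literal", "normalized"),
                           baseline_od = 0.1) {
  blank_variant <- match.arg(blank_variant)
  stopifnot(inherits(assay, "assay_spec"))
  if (noise_sd < 0 || n_replicates < 1) {
    stop_phytoscreen("noise_sd must be >= 0 and n_replicates >= 1",
                     "spec_error")
  }
  if (is.null(names(true_inhibition))) {
    names(true_inhibition) <- sprintf("extract_%02d",
                                      seq_along(true_inhibition))
  }
  blank_ref <- assay$formula_variant == "blank_referenced"
  if (blank_ref && !is.finite(blank_od)) {
    stop_phytoscreen("blank_od required for a blank-referenced assay",
                     "spec_error")
  }

  sample_true <- implied_sample_od(true_inhibition, control_od, blank_od,
                                   assay$formula_variant, blank_variant)
  if (blank_ref && any(sample_true < 0)) {
    stop_phytoscreen(
      "true inhibition implies a negative sample OD under the blank-referenced geometry",
      "spec_error"
    )
  }

  roles <- c(rep("control", n_replicates),
             if (blank_ref) rep("blank", n_replicates),
             rep("sample", n_replicates * length(true_inhibition)))
  extract_ids <- c(rep("", n_replicates),
                   if (blank_ref) rep("", n_replicates),
                   rep(names(true_inhibition), each = n_replicates))
  true_od <- c(rep(control_od, n_replicates),
               if (blank_ref) rep(blank_od, n_replicates),
               rep(sample_true, each = n_replicates))
  n_wells <- length(roles)
  if (n_wells > length(WELL_POSITIONS)) {
    stop_phytoscreen("layout exceeds a 96-well plate", "spec_error")
  }

  set.seed(seed)
  corrected <- true_od + stats::rnorm(n_wells, 0, noise_sd)
  tibble::tibble(
    plate_id = "sim_plate",
    well = WELL_POSITIONS[seq_len(n_wells)],
    role = roles,
    extract_id = extract_ids,
    assay_id = assay$assay_id,
    od_first = baseline_od + corrected,
    od_second = baseline_od
  )
}

sample_predicate <- function(pred, pass) {
  switch(pred$type,
    flag_equals = {
      v <- if (pass) pred$value else !pred$value
      stats::setNames(list(v), pred$attr)
    },
    ordinal_at_least = {
      k <- match(pred$level, pred$levels)
      pool <- if (pass) pred$levels[k:length(pred$levels)] else pred$levels[seq_len(k - 1)]
      if (length(pool) == 0) {
        stop_phytoscreen("ordinal predicate cannot be failed: no lower levels",
                         "spec_error")
      }
      stats::setNames(list(pool[sample.int(length(pool), 1)]), pred$attr)
    },
    in_set = {
      pool <- if (pass) pred$values else setdiff(pred$universe, pred$values)
      if (length(pool) == 0) {
        stop_phytoscreen(
          sprintf("in_set predicate on '%s' needs a universe to sample a %s value",
                  pred$attr, if (pass) "passing" else "failing"),
          "spec_error"
        )
      }
      stats::setNames(list(pool[sample.int(length(pool), 1)]), pred$attr)
    },
    pred_all = {
      if (pass) {
        do.call(c, lapply(pred$parts, sample_predicate, pass = TRUE))
      } else {
        fail_k <- sample.int(length(pred$parts), 1)
        out <- lapply(seq_along(pred$parts), function(j) {
          sample_predicate(pred$parts[[j]], pass = j != fail_k)
        })
        do.call(c, out)
      }
    },
    pred_any = {
      if (pass) {
        pass_k <- sample.int(length(pred$parts), 1)
        out <- lapply(seq_along(pred$parts), function(j) {
          sample_predicate(pred$parts[[j]], pass = j == pass_k)
        })
        do.call(c, out)
      } else {
        do.call(c, lapply(pred$parts, sample_predicate, pass = FALSE))
      }
    },
    pred_not = sample_predicate(pred$part, !pass),
    stop_phytoscreen(sprintf("cannot sample predicate type '%s'", pred$type),
                     "spec_error")
  )
}

#' Simulate a candidate registry with prescribed funnel retention
#'
#' Constructs attribute assignments so that [apply_funnel()] with the
#' given rules reproduces `retention_targets` exactly: record j survives
#' stage i iff j is within the stage's target count, and its attributes
#' are sampled to pass every stage before its first failing one. Record
#' order is then shuffled (deterministically per seed).
#'
#' @param retention_targets integer vector: total records followed by the
#'   output count of each stage; non-increasing, length = `length(rules) + 1`.
#' @param rules ordered list of [filter_rule()]s.
#' @param seed integer seed.
#' @return tibble of candidate records for [apply_funnel()].
#' @export
generate_registry <- function(retention_targets,
                              rules = default_funnel_rules(),
                              seed = 1L) {
  k <- length(rules)
  if (length(retention_targets) != k + 1) {
    stop_phytoscreen("retention_targets must have one count per stage plus the input count",
                     "spec_error")
  }
  if (any(diff(retention_targets) > 0) || any(retention_targets < 0)) {
    stop_phytoscreen("retention_targets must be non-increasing and non-negative",
                     "spec_error")
  }
  n <- retention_targets[1]
  set.seed(seed)

  rows <- lapply(seq_len(n), function(j) {
    # first stage whose output budget excludes record j (0 = retained)
    fail_stage <- 0L
    for (i in seq_len(k)) {
      if (j > retention_targets[i + 1]) { fail_stage <- i; break }
    }
    attrs <- list(iecic_listed = TRUE)
    upto <- if (fail_stage == 0L) k else fail_stage
    for (i in seq_len(upto)) {
      attrs <- utils::modifyList(
        attrs,
        sample_predicate(rules[[i]]$keep, pass = i != fail_stage)
      )
    }
    tibble::as_tibble(attrs)
  })
  records <- dplyr::bind_rows(rows)
  records <- tibble::add_column(
    records,
    botanical_name = sprintf("species_%05d", seq_len(n)),
    .before = 1
  )
  records[sample.int(n), , drop = FALSE]
}

#' Simulate a grade panel and innovation rubric
#'
#' Random plus-grades (including a fraction of `n.d.` entries, while
#' guaranteeing at least one determined assay per extract) over the five
#' screening assays for two extracts per species, plus uniform random
#' rubric sub-scores. Intended for property tests of score bounds and
#' monotonicity.
#'
#' @param n_species number of species to simulate.
#' @param seed integer seed.
#' @param p_nd probability an assay result is `n.d.`.
#' @return list with `grades` and `rubric` tibbles.
#' @export
generate_grade_panel <- function(n_species, seed = 1L, p_nd = 0.15) {
  set.seed(seed)
  symbols <- GRADE_LEVELS[1:5]
  extracts <- expand.grid(extract = c("HA", "PG"),
                          species = sprintf("species_%03d", seq_len(n_species)),
                          stringsAsFactors = FALSE)[, c("species", "extract")]
  g <- matrix("", nrow = nrow(extracts), ncol = length(ASSAY_COLUMNS))
  for (r in seq_len(nrow(extracts))) {
    nd <- stats::runif(length(ASSAY_COLUMNS)) < p_nd
    if (all(nd)) nd[sample.int(length(nd), 1)] <- FALSE
    g[r, ] <- ifelse(nd, "n.d.",
                     symbols[sample.int(length(symbols),
                                        length(ASSAY_COLUMNS), replace = TRUE)])
  }
  colnames(g) <- ASSAY_COLUMNS
  grades <- dplyr::bind_cols(tibble::as_tibble(extracts), tibble::as_tibble(g))
  rubric <- tibble::tibble(
    species = sprintf("species_%03d", seq_len(n_species)),
    market = sample(0:3, n_species, replace = TRUE),
    patent = sample(0:3, n_species, replace = TRUE),
    literature = sample(0:3, n_species, replace = TRUE)
  )
  list(grades = grades, rubric = rubric)
}
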