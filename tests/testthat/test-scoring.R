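test_that("grade bins are 20-point intervals, closed on the left", {
  expect_equal(grade_from_percent(40.3), "++")
  expect_equal(grade_from_percent(36.7), "+")
  expect_equal(grade_from_percent(15), "-")
  expect_equal(grade_from_percent(-12), "-")
  # boundary values fall in the upper bin
  expect_equal(grade_from_percent(c(20, 40, 60, 80)),
               c("+", "++", "+++", "++++"))
  expect_equal(grade_from_percent(c(19.999, 39.999, 79.999, 120)),
               c("-", "+", "+++", "++++"))
  expect_error(grade_from_percent(NaN), class = "invalid_error")
})

test_that("grade symbols normalize and carry one point per plus", {
  expect_equal(grade_points(c("-", "+", "++", "+++", "++++")), 0:4)
  expect_true(is.na(grade_points("n.d.")))
  # Unicode minus and nd spellings are accepted
  expect_equal(normalize_grade("−"), "-")
  expect_equal(normalize_grade(c("nd", "N.D.")), c("n.d.", "n.d."))
  expect_error(normalize_grade("+++++"), class = "validation_error")
})

test_that("extract score normalizes points by 4 x determined assays", {
  expect_equal(extract_bioactivity_score(c("++++", "++++", "-", "-", "-")), 40.0)
  expect_equal(extract_bioactivity_score(c("++++", "n.d.", "-", "++", "-")), 37.5)
  expect_equal(extract_bioactivity_score(c("++++", "n.d.", "++", "+", "n.d.")), 58.3)
  expect_equal(extract_bioactivity_score(c("-", "n.d.", "+", "-", "n.d.")), 8.3)
  expect_error(extract_bioactivity_score(rep("n.d.", 5)),
               class = "unscorable_error")
})

test_that("species score is the half-up rounded mean of extract scores", {
  expect_equal(species_bioactivity_score(c(40.0, 35.0)), 38L)
  expect_equal(species_bioactivity_score(c(37.5, 43.8)), 41L)
  expect_equal(species_bioactivity_score(50.0), 50L)
  expect_error(species_bioactivity_score(numeric(0)),
               class = "unscorable_error")
})

test_that("innovation score normalizes the 0-9 rubric total to 0-100", {
  expect_equal(innovation_score(0, 1, 1), 22L)
  expect_equal(innovation_score(3, 3, 1), 78L)
  expect_equal(innovation_score(0, 0, 0), 0L)
  expect_equal(innovation_score(3, 3, 3), 100L)
  expect_error(innovation_score(4, 0, 0), class = "validation_error")
  expect_error(innovation_score(-1, 0, 0), class = "validation_error")
})

test_that("innovation score attains exactly ten values over all rubrics", {
  combos <- expand.grid(m = 0:3, p = 0:3, l = 0:3)
  scores <- innovation_score(combos$m, combos$p, combos$l)
  expect_setequal(unique(scores), c(0, 11, 22, 33, 44, 56, 67, 78, 89, 100))
  # strictly increasing in the rubric total
  by_total <- vapply(0:9, function(k) innovation_score(min(k, 3),
                                                       min(max(k - 3, 0), 3),
                                                       min(max(k - 6, 0), 3)),
                     integer(1))
  expect_true(all(diff(by_total) > 0))
})

test_that("extract scores are bounded with the extremes characterized", {
  expect_equal(extract_bioactivity_score(rep("++++", 5)), 100)
  expect_equal(extract_bioactivity_score(c("++++", "n.d.", "++++")), 100)
  expect_equal(extract_bioactivity_score(rep("-", 5)), 0)
  panel <- generate_grade_panel(60, seed = 33)
  for (i in seq_len(nrow(panel$grades))) {
    s <- extract_bioactivity_score(unlist(panel$grades[i, ASSAY_COLUMNS_TEST]))
    expect_gte(s, 0); expect_lte(s, 100)
  }
})

test_that("upgrading one grade never lowers the extract score", {
  up <- c("-" = "+", "+" = "++", "++" = "+++", "+++" = "++++")
  set.seed(17)
  panel <- generate_grade_panel(150, seed = 17)
  g <- as.matrix(panel$grades[, ASSAY_COLUMNS_TEST])
  for (i in seq_len(nrow(g))) {
    row <- g[i, ]
    upgradable <- which(row %in% names(up))
    if (length(upgradable)) {
      j <- upgradable[sample.int(length(upgradable), 1)]
      bumped <- row; bumped[j] <- up[[row[j]]]
      expect_gte(extract_bioactivity_score(bumped),
                 extract_bioactivity_score(row))
    }
    # marking a negative assay as not-determined never lowers the score
    negs <- which(row == "-")
    if (length(negs) && sum(row != "n.d.") > 1) {
      masked <- row; masked[negs[1]] <- "n.d."
      expect_gte(extract_bioactivity_score(masked),
                 extract_bioactivity_score(row))
    }
  }
})

test_that("table scorer flags rows whose printed score departs from the rule", {
  grades <- tibble::tibble(
    species = c("A", "A"), extract = c("HA", "PG"),
    dpph = c("++++", "+++"), hyaluronidase = c("++++", "++++"),
    tyrosinase = c("-", "-"), lipoxygenase = c("-", "-"),
    collagenase = c("-", "-"),
    printed_extract_score = c(40, 30),  # PG should be 35
    printed_species_score = c(38, 38)
  )
  expect_warning(score_bioactivity_table(grades), "printed as 30")
})
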