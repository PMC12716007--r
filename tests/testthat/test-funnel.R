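test_that("builtin predicates evaluate keep/drop/unknown semantics", {
  rec <- list(flag = TRUE, dist = "common", app = "II")
  expect_true(eval_predicate(flag_equals("flag", TRUE), rec))
  expect_false(eval_predicate(flag_equals("flag", FALSE), rec))
  expect_true(is.na(eval_predicate(flag_equals("missing", TRUE), rec)))

  p <- ordinal_at_least("dist", "common")
  expect_true(eval_predicate(p, rec))
  expect_false(eval_predicate(p, list(dist = "uncommon")))
  expect_true(eval_predicate(p, list(dist = "very_common")))
  expect_true(is.na(eval_predicate(p, list(dist = "weird"))))

  expect_false(eval_predicate(in_set("app", "none"), rec))
  expect_true(eval_predicate(in_set("app", c("I", "II")), rec))

  expect_false(eval_predicate(pred_not(flag_equals("flag", TRUE)), rec))
  expect_true(eval_predicate(pred_any(flag_equals("flag", FALSE),
                                      in_set("app", "II")), rec))
})

test_that("conjunction equals sequential application of its parts", {
  p1 <- flag_equals("a", TRUE); p2 <- in_set("s", c("x", "y"))
  both <- pred_all(p1, p2)
  cases <- expand.grid(a = c(TRUE, FALSE), s = c("x", "z"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    rec <- as.list(cases[i, ])
    expect_equal(eval_predicate(both, rec),
                 eval_predicate(p1, rec) && eval_predicate(p2, rec))
  }
})

test_that("funnel drops each record at its first failing stage", {
  # 10 records built so stages retain 7, then 5, then 2
  records <- tibble::tibble(
    botanical_name = sprintf("sp%02d", 1:10),
    a = rep(c(TRUE, FALSE), c(7, 3)),
    b = rep(c(TRUE, FALSE, TRUE), c(5, 2, 3)),
    c = rep(c(TRUE, FALSE), c(2, 8))
  )
  rep <- apply_funnel(records, toy_rules())
  expect_equal(rep$counts, c(10, 7, 5, 2))
  expect_equal(rep$stages$n_in, c(10, 7, 5))
  expect_equal(rep$stages$n_out, c(7, 5, 2))
  # short-circuit: records failing stage_a are attributed to it even though
  # they would also fail later stages
  expect_equal(rep$audit$first_drop_stage[8:10], rep("stage_a", 3))
  # audit is exhaustive: retained xor exactly one first-drop stage
  expect_true(all(xor(rep$audit$retained, !is.na(rep$audit$first_drop_stage))))
  expect_equal(sum(rep$audit$retained), 2)
})

test_that("stage counts are non-increasing on arbitrary registries", {
  for (seed in 1:3) {
    reg <- generate_registry(c(40, 30, 22, 15, 15, 9, 5, 2),
                             default_funnel_rules(), seed = seed)
    rep <- apply_funnel(reg, default_funnel_rules())
    expect_true(all(diff(rep$counts) <= 0))
  }
})

test_that("reordering independent stages preserves the final retained set", {
  records <- tibble::tibble(
    botanical_name = sprintf("sp%02d", 1:12),
    a = sample(c(TRUE, FALSE), 12, replace = TRUE),
    b = sample(c(TRUE, FALSE), 12, replace = TRUE),
    c = sample(c(TRUE, FALSE), 12, replace = TRUE)
  )
  r1 <- apply_funnel(records, toy_rules())
  r2 <- apply_funnel(records, toy_rules()[c(2, 1, 3)])
  expect_setequal(r1$retained, r2$retained)
})

test_that("unknown attribute values follow the configured policy", {
  records <- tibble::tibble(botanical_name = c("known", "unknown"),
                            a = c(TRUE, NA), b = TRUE, c = TRUE)
  drop <- apply_funnel(records, toy_rules(), unknown_policy = "drop")
  expect_equal(drop$retained, "known")
  expect_equal(drop$audit$first_drop_stage[2], "stage_a")
  keep <- apply_funnel(records, toy_rules(), unknown_policy = "keep")
  expect_setequal(keep$retained, c("known", "unknown"))
  expect_error(apply_funnel(records, toy_rules(), unknown_policy = "strict"),
               class = "schema_error")
})

test_that("a stage may legitimately remove nothing", {
  records <- tibble::tibble(botanical_name = c("x", "y"),
                            a = TRUE, b = TRUE, c = c(TRUE, FALSE))
  rep <- apply_funnel(records, toy_rules())
  expect_equal(rep$stages$n_in[2], rep$stages$n_out[2])
  expect_equal(rep$counts, c(2, 2, 2, 1))
})

test_that("funnel input validation rejects malformed calls", {
  expect_error(apply_funnel(tibble::tibble(x = 1), toy_rules()),
               class = "validation_error")
  expect_error(apply_funnel(tibble::tibble(botanical_name = "a"), list()),
               class = "config_error")
})
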