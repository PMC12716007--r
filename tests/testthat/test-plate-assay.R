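test_that("corrected OD is the signed difference of the two reads", {
  expect_equal(corrected_od(1.2, 0.4), 0.8)
  expect_equal(corrected_od(0.5, 0.5), 0.0)
  expect_equal(corrected_od(0.3, 0.5), -0.2)
  expect_error(corrected_od(NA_real_, 1), class = "invalid_reading_error")
  expect_error(corrected_od(1, Inf), class = "invalid_reading_error")
})

test_that("corrected OD is antisymmetric in its arguments", {
  set.seed(11)
  a <- runif(50, 0, 3); b <- runif(50, 0, 3)
  expect_equal(corrected_od(a, b), -corrected_od(b, a))
})

test_that("control-referenced inhibition matches its defining formula", {
  expect_equal(inhibition_control_referenced(0.6, 1.0), 40.0)
  expect_equal(inhibition_control_referenced(1.0, 1.0), 0.0)
  expect_equal(inhibition_control_referenced(0.0, 1.0), 100.0)
  expect_error(inhibition_control_referenced(0.5, 0),
               class = "degenerate_control_error")
})

test_that("control-referenced inhibition is strictly decreasing in sample OD", {
  od <- seq(0, 2, by = 0.05)
  inh <- inhibition_control_referenced(od, 0.8)
  expect_true(all(diff(inh) < 0))
})

test_that("blank-referenced inhibition supports both formula parses", {
  # literal parse: OD_sample / (OD_blank - OD_control)
  expect_equal(inhibition_blank_referenced(0.4, 0.2, 1.0), 50.0)
  expect_equal(inhibition_blank_referenced(0.0, 0.2, 1.0), 0.0)
  # normalized parse, hand evaluation: (0.4 - 0.2) / (1.0 - 0.2) * 100 = 25
  expect_equal(
    inhibition_blank_referenced(0.4, 0.2, 1.0, variant = "normalized"),
    25.0
  )
  expect_error(inhibition_blank_referenced(0.4, 1.0, 1.0),
               class = "degenerate_denominator_error")
})

test_that("replicate aggregation reports mean, sample SD and SEM", {
  st <- aggregate_replicates(c(10, 20, 30))
  expect_equal(st$mean, 20)
  expect_equal(st$sd, 10)
  expect_equal(st$sem, 10 / sqrt(3))
  expect_equal(st$sem, 5.7735, tolerance = 1e-4)
  expect_equal(st$n, 3L)

  one <- aggregate_replicates(40.3)
  expect_equal(one$mean, 40.3)
  expect_false(one$sd_defined)
  expect_equal(one$sem, 0)
  expect_equal(one$n, 1L)

  const <- aggregate_replicates(c(5, 5, 5))
  expect_equal(const$mean, 5)
  expect_equal(const$sd, 0)
  expect_equal(const$sem, 0)

  expect_error(aggregate_replicates(numeric(0)), class = "no_replicates_error")
})

test_that("aggregating k copies of x gives mean x and SD 0", {
  set.seed(7)
  for (x in runif(10, -20, 120)) {
    st <- aggregate_replicates(rep(x, 4))
    expect_equal(st$mean, x)
    expect_equal(st$sd, 0)
  }
})

test_that("process_plate computes per-extract inhibition against plate means", {
  plate <- make_plate(list(ext1 = 0.6), control_od = 1.0)
  res <- process_plate(plate, assay_spec("DPPH"))
  expect_equal(res$mean_inhibition, 40.0)
  expect_equal(res$sd, 0)
  expect_equal(res$n_replicates, 3L)
})

test_that("process_plate enforces plate layout preconditions", {
  plate <- make_plate(list(ext1 = 0.6))
  no_control <- plate[plate$role != "control", ]
  expect_error(process_plate(no_control, assay_spec("DPPH")),
               class = "layout_error")
  # blank-referenced assay needs blank wells
  hy_plate <- make_plate(list(ext1 = 0.6), assay_id = "hyaluronidase")
  expect_error(process_plate(hy_plate, assay_spec("hyaluronidase")),
               class = "layout_error")
  no_samples <- plate[plate$role != "sample", ]
  expect_error(process_plate(no_samples, assay_spec("DPPH")),
               class = "layout_error")
  wrong <- plate; wrong$assay_id <- "other"
  expect_error(process_plate(wrong, assay_spec("DPPH")),
               class = "config_error")
})

test_that("noisy synthetic plate is recovered within 3 SEM of truth", {
  plate <- generate_plate(c(ext = 50), control_od = 1.0, noise_sd = 0.01,
                          n_replicates = 3, seed = 42,
                          assay = assay_spec("DPPH"))
  res <- process_plate(plate, assay_spec("DPPH"))
  expect_lt(abs(res$mean_inhibition - 50), 3 * max(res$sem, 1e-6))
})

test_that("assay specs default to the field's formula conventions", {
  expect_equal(assay_spec("hyaluronidase")$formula_variant, "blank_referenced")
  expect_equal(assay_spec("collagenase")$formula_variant, "blank_referenced")
  expect_equal(assay_spec("DPPH")$formula_variant, "control_referenced")
  expect_equal(assay_spec("tyrosinase")$formula_variant, "control_referenced")
  expect_equal(assay_spec("lipoxygenase")$formula_variant, "control_referenced")
  expect_error(assay_spec("unknown-assay"), class = "config_error")
  expect_error(assay_spec("DPPH", well_concentration = -1),
               class = "config_error")
})
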