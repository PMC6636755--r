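test_that("the linear-consistency oracle recovers hidden cost constants", {
  # extraction surgery: fit on the 0% and 1% rows
  ext <- linear_consistency_oracle(c(0, 0.01), c(2540223, 2545417),
                                   precision = c(0, 1))
  expect_equal(ext$slope, 519400)
  expect_true(ext$snapped)
  # held-out prediction: the 2% row
  expect_equal(round_jpy(ext$intercept + 0.02 * ext$slope), 2550611)

  # RFT: the print-rounding band admits a unique round tariff value
  rft <- linear_consistency_oracle(c(0, 0.0356), c(2115300, 2145037),
                                   precision = c(0, 1))
  expect_equal(rft$slope, 835300)
  expect_equal(rft$slope_raw, 29737 / 0.0356)
  expect_true(abs(rft$slope - rft$slope_raw) <= rft$halfwidth)
  expect_equal(round_jpy(rft$intercept + 0.10 * rft$slope), 2198830)

  # DPC RFT: no unique round value in the band -> raw fit retained
  rft_dpc <- linear_consistency_oracle(c(0, 0.0356), c(2078040, 2104146),
                                       precision = c(0, 1))
  expect_false(rft_dpc$snapped)
  expect_equal(rft_dpc$slope, 26106 / 0.0356)

  flat <- linear_consistency_oracle(c(0, 0.5), c(1000, 1000), precision = 0)
  expect_equal(flat$slope, 0)
  expect_error(linear_consistency_oracle(c(0.2, 0.2), c(1, 2)),
               "degenerate fit")
})

test_that("every derived constant reproduces a held-out published cell", {
  k <- fx$constants
  # RFT (FFS): derived from the 0% row and base; predicts the 10% cell
  expect_equal(round_jpy(2115300 + 0.10 * k$c_rft_ffs), 2198830)
  # RFT (DPC): predicts the DPC 10% cell
  expect_equal(round_jpy(2078040 + 0.10 * k$c_rft_dpc), 2151371)
  # extraction: predicts the 2% cells under both tariff modes
  expect_equal(round_jpy(2540223 + 0.02 * k$c_extraction), 2550611)
  expect_equal(round_jpy(2513643 + 0.02 * k$c_extraction), 2524031)
  # labour slope: derived from the 2 h and 4 h rows; predicts the 6 h cell
  grand_6h <- total_cost(scenario_ffs(), "MRgFUS")$total +
    k$mrgfus_labour_fixed_2018 + 6 * k$mrgfus_labour_slope_2018
  expect_equal(round_jpy(grand_6h), 3490008)
  # stay tiers: derived from the 2- and 10-day rows; the published 10-day
  # difference cell is reproduced
  diff_10d <- run_one_way(scenario_ffs(),
                          dsa_parameter("dbs_post_hospital_days", 8,
                                        10))$difference[2]
  expect_equal(round_jpy(diff_10d), -441200)
})

test_that("every fixture value carries a provenance tag", {
  prov <- fx$provenance
  expect_true(all(prov$provenance %in% c("printed", "derived")))
  expect_true(all(nzchar(prov$name)))
  expect_false(any(is.na(prov$value)))
  # all derived constants document their anchors
  derived <- prov[prov$provenance == "derived", ]
  expect_true(all(nzchar(derived$anchors_used)))
  # headline derived constants are present
  expect_true(all(c("c_rft_ffs", "c_rft_dpc", "c_extraction",
                    "mrgfus_labour_slope_2018") %in% prov$name))
})

test_that("rerunning the model on the fixture reproduces the published
           stage cells used in its own calibration", {
  res <- run_scenario(scenario_ffs())
  expect_equal(round_jpy(unname(unlist(res[1:2, c("pre", "procedure", "post")]))),
               c(50610, 50610, 2032440, 2310833, 61987, 183974))
  resd <- run_scenario(scenario_dpc())
  expect_equal(round_jpy(unname(unlist(resd[1:2, c("pre", "procedure", "post")]))),
               c(25950, 25950, 2026140, 2307173, 52056, 185714))
})

test_that("the synthetic catalog generator is seed-deterministic", {
  a <- generate_synthetic_catalog(123, n_items = 8)
  b <- generate_synthetic_catalog(123, n_items = 8)
  expect_identical(a$catalog$items, b$catalog$items)
  expect_identical(a$truth, b$truth)
  c2 <- generate_synthetic_catalog(124, n_items = 8)
  expect_false(identical(a$catalog$items, c2$catalog$items))
})

test_that("a one-item, no-event synthetic catalog has its item cost as the
           truth total", {
  syn <- generate_synthetic_catalog(9, n_items = 1,
                                    event_probabilities = numeric(0),
                                    n_premiums = 0)
  item <- syn$catalog$items[syn$catalog$items$item_id == "proc_a_item1", ]
  expect_equal(syn$truth$proc_A$total, item$unit_cost * item$quantity)
})

test_that("generator input validation", {
  expect_error(generate_synthetic_catalog(1, n_items = 0), "n_items")
  expect_error(generate_synthetic_catalog(1, cost_range = c(10, 1)),
               "cost_range")
  expect_error(generate_synthetic_catalog(1, event_probabilities = 1.5),
               "\\[0, 1\\]")
})
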