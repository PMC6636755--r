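test_that("stage costs reproduce the published per-stage subtotals", {
  sc <- scenario_ffs()
  expect_equal(stage_cost(sc, "MRgFUS", "pre"), 50610)
  expect_equal(stage_cost(sc, "MRgFUS", "procedure"), 2032440)
  expect_equal(stage_cost(sc, "unilateral_DBS", "pre"), 50610)
  expect_equal(stage_cost(sc, "unilateral_DBS", "procedure"), 2310833)
  # post stage before the event weight: stay plus remaining bundle
  expect_equal(stage_cost(sc, "unilateral_DBS", "post"), 178780)
  empty <- procedure_model("empty")
  expect_equal(stage_cost(sc, empty, "pre"), 0)
})

test_that("expected event cost is probability times the referenced total", {
  sc <- scenario_ffs()
  rft <- sc$procedures$MRgFUS$events[[1]]
  expect_equal(expected_event_cost(sc, rft), 0.0356 * 835300)
  expect_equal(expected_event_cost(sc, rft), 29736.68)
  ext <- sc$procedures$unilateral_DBS$events[[1]]
  expect_equal(expected_event_cost(sc, ext), 5194)
  none <- downstream_event("never", 0, "RFT")
  expect_equal(expected_event_cost(sc, none), 0)
  expect_error(expected_event_cost(sc, downstream_event("x", 0.5, "nope")),
               "unknown procedure")
})

test_that("total cost sums stages with events allocated to post", {
  sc <- scenario_ffs()
  m <- total_cost(sc, "MRgFUS")
  expect_equal(m$pre, 50610)
  expect_equal(m$procedure, 2032440)
  expect_equal(m$post, 61986.68)
  expect_equal(m$total, 2145036.68)
  expect_equal(round_jpy(m$total), 2145037)
  d <- total_cost(sc, "unilateral_DBS")
  expect_equal(d$total, 2545417)
  dpc <- total_cost(scenario_dpc(), "MRgFUS")
  expect_equal(round_jpy(dpc$total), 2104146)
})

test_that("breakdown total equals the exact stage sum", {
  for (sc in list(scenario_ffs(), scenario_dpc())) {
    for (p in names(sc$procedures)) {
      bd <- total_cost(sc, p)
      expect_identical(bd$total, bd$pre + bd$procedure + bd$post)
    }
  }
})

test_that("cost difference is exact, signed and antisymmetric", {
  sc <- scenario_ffs()
  a <- total_cost(sc, "MRgFUS")
  b <- total_cost(sc, "unilateral_DBS")
  expect_equal(round_jpy(cost_difference(a, b)), -400380)
  expect_equal(cost_difference(a, a), 0)
  expect_equal(cost_difference(a, b), -cost_difference(b, a))
})

test_that("totals are affine in every event probability with slope equal to
           the referenced procedure's total", {
  sc <- scenario_ffs()
  t_ref <- total_cost(sc, "RFT")$total
  at_p <- function(p) {
    s <- calibrated_scenario("FFS", overrides = list(rft_proportion = p),
                             fixture = fx)
    total_cost(s, "MRgFUS")$total
  }
  t0 <- at_p(0); t_half <- at_p(0.5); t1 <- at_p(1)
  expect_equal(t1 - t0, t_ref)
  # three-point collinearity, exact
  expect_equal(t_half, (t0 + t1) / 2)
  expect_equal(at_p(0.0356), t0 + 0.0356 * t_ref)
})

test_that("model totals equal an independent brute-force item loop on random
           synthetic catalogs", {
  for (seed in 1:100) {
    syn <- generate_synthetic_catalog(seed, n_items = sample(1:12, 1))
    cfg <- scenario_config("FFS")
    sc <- build_scenario(cfg, syn$catalog, syn$procedures)
    for (p in c("proc_A", "proc_B")) {
      bd <- total_cost(sc, p)
      expect_equal(bd$total, syn$truth[[p]]$total, tolerance = 1e-9)
      expect_lt(abs(bd$total - syn$truth[[p]]$total), 1e-6)
    }
  }
})

test_that("self-referencing and deep event trees are rejected", {
  expect_error(procedure_model("A", events = list(
    downstream_event("loop", 0.1, "A"))), "reference itself")
  cat <- tiny_catalog()
  procs <- list(
    a = procedure_model("a", items = "mri",
                        events = list(downstream_event("e", 0.1, "b"))),
    b = procedure_model("b", items = "fee",
                        events = list(downstream_event("e2", 0.1, "c"))),
    c = procedure_model("c", items = "drug"))
  expect_error(build_scenario(scenario_config("FFS"), cat, procs),
               "depth 1")
  expect_error(downstream_event("bad", 1.2, "x"), "in \\[0, 1\\]")
})
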