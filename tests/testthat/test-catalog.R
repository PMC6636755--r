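test_that("catalog construction validates its invariants", {
  cat <- tiny_catalog()
  expect_s3_class(cat, "cma_catalog")
  expect_equal(nrow(cat$items), 5)

  bad <- cat$items
  bad$unit_cost[1] <- -1
  expect_error(catalog(bad), "negative or missing unit_cost")

  dup <- rbind(cat$items, cost_item("mri", "again", "pre", "imaging", 1, 1,
                                    "FFS"))
  expect_error(catalog(dup), "duplicate item id")

  dangling <- rbind(cat$items,
                    cost_item("orphan_premium", "premium", "pre", "premium",
                              100, 1, "FFS", parent_item = "nonexistent"))
  expect_error(catalog(dangling), "premium item 'orphan_premium'")

  expect_error(catalog(cat$items[, -5]), "missing columns: unit_cost")
  expect_error(cost_item("x", "x", "pre", "imaging", 10, -2),
               "quantity must be")
})

test_that("catalogs round-trip through CSV and JSON", {
  cat <- tiny_catalog()
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_catalog(cat, csv)
  write_catalog(cat, json)
  back_csv <- read_catalog(csv)
  back_json <- read_catalog(json)
  expect_equal(back_csv$items, cat$items)
  expect_equal(back_json$items, cat$items)
  expect_equal(back_json$schedules$stay$fee_per_day,
               cat$schedules$stay$fee_per_day)
  expect_equal(back_json$schedules$stay$day_to, cat$schedules$stay$day_to)
  expect_equal(back_json$currency_year, cat$currency_year)
  unlink(c(csv, json))
})

test_that("round-trip is the identity on random synthetic catalogs", {
  for (seed in 1:5) {
    syn <- generate_synthetic_catalog(seed, n_items = 6)
    path <- tempfile(fileext = ".json")
    write_catalog(syn$catalog, path)
    back <- read_catalog(path)
    expect_equal(back$items, syn$catalog$items)
    unlink(path)
  }
})

test_that("read_catalog reports malformed files", {
  path <- tempfile(fileext = ".csv")
  df <- tiny_catalog()$items
  df$unit_cost[2] <- -1
  write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_catalog(path), "negative or missing unit_cost")
  expect_error(read_catalog(tempfile()), "not found")
  unlink(path)
})

test_that("lookup_cost prices unit cost times quantity", {
  cat <- tiny_catalog()
  expect_equal(lookup_cost(cat, "mri", "FFS"), 20000)
  expect_equal(lookup_cost(cat, "fee", "DPC"), 120000)
  expect_equal(lookup_cost(cat, "drug", "drug_tariff"), 10000)
  zero <- catalog(cost_item("z", "zero qty", "pre", "fee", 10000, 0, "FFS"))
  expect_equal(lookup_cost(zero, "z", "FFS"), 0)
  expect_error(lookup_cost(cat, "mri", "DPC"), "available systems: FFS")
  expect_error(lookup_cost(cat, "nope", "FFS"), "unknown item")
})

test_that("hospitalisation cost follows the day-indexed schedule", {
  s <- hosp_schedule(c(1, 4), c(3, Inf), c(10000, 8000))
  expect_equal(hospitalisation_cost(s, 0), 0)
  expect_equal(hospitalisation_cost(s, 3), 30000)
  expect_equal(hospitalisation_cost(s, 5), 46000)
  expect_error(hospitalisation_cost(s, -1), "non-negative integer")
  expect_error(hosp_schedule(c(2, 4), c(3, Inf), c(1, 1)), "start at day 1")
  expect_error(hosp_schedule(c(1, 5), c(3, Inf), c(1, 1)), "contiguous")
})

test_that("cumulative stay cost equals a brute-force day loop and is
           non-decreasing", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    bounds <- sort(sample(2:12, n - 1))
    fees <- round(runif(n, 0, 30000))
    s <- hosp_schedule(c(1, bounds + 1), c(bounds, Inf), fees)
    per_day <- vapply(1:15, function(d) {
      fees[findInterval(d, c(1, bounds + 1))]
    }, numeric(1))
    cum <- vapply(0:15, function(d) hospitalisation_cost(s, d), numeric(1))
    expect_equal(cum, c(0, cumsum(per_day)))
    expect_true(all(diff(cum) >= 0))
  }
})

test_that("calibrated DBS stay schedule matches the published stay deltas", {
  sched <- fx$catalog$schedules$dbs_post
  expect_equal(hospitalisation_cost(sched, 10) -
                 hospitalisation_cost(sched, 8), 40820)
  expect_equal(hospitalisation_cost(sched, 8) -
                 hospitalisation_cost(sched, 2), 102460)
})
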