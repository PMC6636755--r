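test_that("gamma moment matching recovers mean and sd in closed form", {
  gp <- gamma_params(100, 20)
  expect_equal(gp$shape, 25)
  expect_equal(gp$scale, 4)
  expect_equal(gp$shape * gp$scale, 100)                 # mean
  expect_equal(sqrt(gp$shape) * gp$scale, 20)            # sd
  # sd = 20% of mean always gives shape 25
  for (m in c(0.5, 3e3, 2145037)) {
    expect_equal(gamma_params(m, 0.2 * m)$shape, 25)
  }
  expect_error(gamma_params(-1, 2), "mean > 0")
  expect_error(gamma_params(1, 0), "sd > 0")
})

test_that("beta moment matching recovers mean and sd in closed form", {
  bp <- beta_params(0.5, 0.1)
  expect_equal(bp$alpha, 12)
  expect_equal(bp$beta, 12)
  bp2 <- beta_params(0.0356, 0.00712)
  expect_equal(bp2$alpha, 24.0744, tolerance = 1e-4)
  expect_equal(bp2$beta, 652.1728, tolerance = 1e-4)
  expect_equal(bp2$alpha / (bp2$alpha + bp2$beta), 0.0356)
  expect_error(beta_params(0.5, 0.6), "infeasible sd")
  expect_error(beta_params(1.2, 0.1), "0 < mean < 1")
})

test_that("moment-matched sampling recovers the requested moments at large
           n", {
  n <- 1e6
  gp <- gamma_params(100, 20)
  set.seed(11)
  g <- rgamma(n, shape = gp$shape, scale = gp$scale)
  expect_lt(abs(mean(g) - 100), 3 * 20 / sqrt(n))
  bp <- beta_params(0.0356, 0.00712)
  b <- rbeta(n, bp$alpha, bp$beta)
  expect_lt(abs(mean(b) - 0.0356), 3 * 0.00712 / sqrt(n))
  expect_equal(sd(b), 0.00712, tolerance = 0.01)
})

test_that("the PSA is bit-reproducible for a given seed and parameter
           streams are independent of each other", {
  sc <- scenario_ffs()
  r1 <- suppressWarnings(run_psa(sc, iterations = 50, seed = 7))
  r2 <- suppressWarnings(run_psa(sc, iterations = 50, seed = 7))
  expect_identical(r1$samples, r2$samples)
  r3 <- suppressWarnings(run_psa(sc, iterations = 50, seed = 8))
  expect_false(identical(r1$samples, r3$samples))
  # dropping one parameter leaves all other streams untouched
  specs <- psa_specs(sc)
  keep <- vapply(specs, function(s) s$parameter_id != "item:rft_procedure",
                 logical(1))
  r4 <- suppressWarnings(run_psa(sc, specs = specs[keep], iterations = 50, seed = 7))
  shared <- intersect(colnames(r1$draws), colnames(r4$draws))
  expect_identical(r1$draws[, shared], r4$draws[, shared])
})

test_that("all-fixed specs degenerate to the base case every iteration", {
  sc <- scenario_ffs()
  specs <- lapply(psa_specs(sc), function(s) {
    distribution_spec(s$parameter_id, "fixed", s$mean)
  })
  r <- run_psa(sc, specs = specs, iterations = 5, seed = 1)
  base <- run_scenario(sc)
  expect_equal(unname(r$samples[, "MRgFUS"]),
               rep(base$medical_total[1], 5))
  expect_equal(unname(r$samples[, "unilateral_DBS"]),
               rep(base$medical_total[2], 5))
})

test_that("linked parameters share one draw per iteration", {
  sc <- scenario_ffs()
  r <- suppressWarnings(run_psa(sc, iterations = 200, seed = 3))
  pre_m <- r$draws[, "item:mrgfus_pre"]
  pre_d <- r$draws[, "item:dbs_pre"]
  expect_equal(cor(pre_m, pre_d), 1)
  expect_identical(pre_m, pre_d)   # identical distributions -> same values
  unlinked <- cor(r$draws[, "item:mrgfus_procedure"],
                  r$draws[, "item:dbs_procedure"])
  expect_lt(abs(unlinked), 0.3)
})

test_that("the PSA mean is unbiased for the deterministic base case", {
  sc <- scenario_ffs()
  r <- suppressWarnings(run_psa(sc, iterations = 2000, seed = 21))
  base <- run_scenario(sc)$medical_total
  for (j in 1:2) {
    se <- sd(r$samples[, j]) / sqrt(r$iterations)
    expect_lt(abs(mean(r$samples[, j]) - base[j]), 3 * se)
  }
})

test_that("summary statistics match an independent recomputation from the
           raw samples", {
  sc <- scenario_ffs()
  r <- suppressWarnings(run_psa(sc, iterations = 300, seed = 5))
  for (i in 1:2) {
    x <- r$samples[, r$summary$procedure[i]]
    expect_equal(r$summary$mean[i], mean(x))
    expect_equal(r$summary$median[i], unname(quantile(x, 0.5)))
    q1 <- unname(quantile(x, 0.25)); q3 <- unname(quantile(x, 0.75))
    iqr <- q3 - q1
    expect_equal(r$summary$q1[i], q1)
    expect_equal(r$summary$whisker_low[i], min(x[x >= q1 - 1.5 * iqr]))
    expect_equal(r$summary$whisker_high[i], max(x[x <= q3 + 1.5 * iqr]))
  }
  expect_equal(r$mean_difference,
               mean(r$samples[, 2]) - mean(r$samples[, 1]))
  expect_gte(r$fraction_cheaper, 0)
  expect_lte(r$fraction_cheaper, 1)
})

test_that("the between-arm comparison runs the stated testing procedure", {
  sc <- scenario_ffs()
  r <- suppressWarnings(run_psa(sc, iterations = 1000, seed = 1))
  expect_true(r$test$t_p_value < 0.01)
  expect_true(r$test$significant)
  expect_true(r$test$t_statistic < 0)  # MRgFUS arm cheaper
  # identical samples: t = 0, not significant
  x <- rnorm(100, 100, 5)
  fake <- structure(list(samples = cbind(a = x, b = x)), class = "cma_psa")
  cmp <- compare_psa(fake, 0.01)
  expect_equal(cmp$t_statistic, 0)
  expect_false(cmp$significant)
  expect_true(cmp$pooled)
  degenerate <- structure(list(samples = cbind(a = rep(1, 10),
                                               b = rep(2, 10))),
                          class = "cma_psa")
  expect_error(compare_psa(degenerate), "degenerate")
})

test_that("psa input validation catches bad requests", {
  sc <- scenario_ffs()
  expect_error(run_psa(sc, iterations = 1), "iterations must be >= 2")
  specs <- psa_specs(sc)
  expect_error(run_psa(sc, specs = c(specs, specs[1]), iterations = 5),
               "duplicate parameter_id")
})
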