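#' Moment-matched gamma parameters
#'
#' Shape/scale of the gamma distribution with the given mean and standard
#' deviation: `shape = (mean/sd)^2`, `scale = sd^2/mean`. With the model's
#' default `sd = 0.2 * mean`, every cost and quantity parameter has
#' `shape = 25`.
#'
#' @param mean Positive mean.
#' @param sd Positive standard deviation.
#' @return `list(shape =, scale =)`.
#' @export
gamma_params <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || mean <= 0 || sd <= 0) {
    stop("gamma moment matching requires mean > 0 and sd > 0", call. = FALSE)
  }
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Moment-matched beta parameters
#'
#' Method-of-moments beta parameters for a percentage input:
#' `nu = mean (1 - mean) / sd^2 - 1`, `alpha = mean * nu`,
#' `beta = (1 - mean) * nu`. Requires `sd^2 < mean (1 - mean)`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation with `sd^2 < mean * (1 - mean)`.
#' @return `list(alpha =, beta =)`.
#' @export
beta_params <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1) {
    stop("beta moment matching requires 0 < mean < 1", call. = FALSE)
  }
  if (!is.numeric(sd) || sd <= 0 || sd^2 >= mean * (1 - mean)) {
    stop("infeasible sd for beta: need sd^2 < mean*(1-mean) = ",
         signif(mean * (1 - mean), 6), " (sd < ",
         signif(sqrt(mean * (1 - mean)), 6), ")", call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Declare a sampling distribution for one model parameter
#'
#' Each uncertain parameter is sampled from a moment-matched distribution:
#' gamma for costs and quantities, beta for percentages, with SD defaulting
#' to 20% of the mean. Parameters sharing a `linkage_group` draw one value
#' per iteration (used for tariff premiums whose quantity equals the parent
#' activity's frequency, and for resource use declared identical across
#' arms).
#'
#' @param parameter_id Identifier; the calibrated model uses `"item:<id>"`,
#'   `"hosp:<procedure>"` and `"event:<procedure>:<event>"`.
#' @param family `"gamma"`, `"beta"` or `"fixed"`.
#' @param mean Base-case value.
#' @param sd Standard deviation (ignored for `"fixed"`).
#' @param linkage_group Optional group identifier.
#' @return An object of class `distribution_spec`.
#' @export
distribution_spec <- function(parameter_id,
                              family = c("gamma", "beta", "fixed"),
                              mean, sd = 0.2 * mean,
                              linkage_group = NA_character_) {
  family <- match.arg(family)
  if (family == "gamma") gamma_params(mean, sd)       # validate
  if (family == "beta") beta_params(mean, sd)         # validate
  structure(list(parameter_id = parameter_id, family = family,
                 mean = mean, sd = sd, linkage_group = linkage_group),
            class = "distribution_spec")
}

#' Derive the default PSA specification from a scenario
#'
#' Enumerates every uncertain parameter of the scenario: each sampled catalog
#' item priced by an index or referenced procedure (gamma on its priced
#' cost), each hospitalisation stay (gamma on the stay cost at the base
#' duration; the number of primary procedures itself stays fixed at one), and
#' each downstream-event probability (beta). SDs are 20% of the mean.
#' Zero-mean parameters are declared fixed. Linkage groups come from the
#' scenario's item linkage map.
#'
#' @param scenario A `cma_scenario`.
#' @return List of [distribution_spec()] objects.
#' @export
psa_specs <- function(scenario) {
  stopifnot(inherits(scenario, "cma_scenario"))
  specs <- list()
  items <- scenario$catalog$items
  seen <- character()
  for (p in scenario$procedures) {
    for (id in p$items) {
      if (id %in% seen) next
      seen <- c(seen, id)
      row <- which(items$item_id == id)[1]
      if (!isTRUE(items$sampled[row])) next
      m <- price_item(scenario, id)
      grp <- NA_character_
      if (!is.null(scenario$linkage) && id %in% names(scenario$linkage)) {
        grp <- scenario$linkage[[id]]
      }
      specs[[length(specs) + 1]] <- if (m > 0) {
        distribution_spec(paste0("item:", id), "gamma", m,
                          linkage_group = grp)
      } else {
        distribution_spec(paste0("item:", id), "fixed", m,
                          linkage_group = grp)
      }
    }
    if (!is.null(p$hospitalisation)) {
      m <- procedure_hosp_cost(scenario, p)
      specs[[length(specs) + 1]] <- if (m > 0) {
        distribution_spec(paste0("hosp:", p$name), "gamma", m)
      } else {
        distribution_spec(paste0("hosp:", p$name), "fixed", m)
      }
    }
    for (ev in p$events) {
      pe <- event_probability(scenario, p, ev)
      id <- paste0("event:", p$name, ":", ev$name)
      specs[[length(specs) + 1]] <- if (pe > 0 && pe < 1) {
        distribution_spec(id, "beta", pe)
      } else {
        distribution_spec(id, "fixed", pe)
      }
    }
  }
  specs
}

# Deterministic per-stream seed from the root seed and a stream key, so that
# adding a parameter never perturbs the draws of the others. Arithmetic on
# doubles stays well below 2^53, result below 2^31.
stream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration draws
#' every sampled parameter once (parameters in a linkage group share the
#' iteration's quantile draw, giving perfectly correlated values) and
#' re-evaluates the scenario deterministically. One root seed derives an
#' independent stream per parameter, so results are bit-reproducible and
#' adding a parameter leaves the other streams untouched.
#'
#' @param scenario A `cma_scenario`.
#' @param specs List of [distribution_spec()]; default [psa_specs()].
#' @param iterations Number of iterations (>= 2); the reference analysis
#'   uses 1,000.
#' @param seed Integer root seed.
#' @param alpha_level Significance level for the between-arm test
#'   (default 0.01).
#' @return An object of class `cma_psa`: iterations, seed, a samples matrix
#'   (iterations x index procedures, grand totals), per-procedure summary
#'   (mean, median, quartiles, 1.5*IQR whisker bounds), `mean_difference`
#'   (second arm minus first, i.e. the saving of the first-listed procedure),
#'   `fraction_cheaper`, and the significance test report (see
#'   [compare_psa()]).
#' @export
run_psa <- function(scenario, specs = NULL, iterations = 1000, seed = 1,
                    alpha_level = 0.01) {
  stopifnot(inherits(scenario, "cma_scenario"))
  if (iterations < 2) stop("iterations must be >= 2", call. = FALSE)
  if (is.null(specs)) specs <- psa_specs(scenario)
  ids <- vapply(specs, function(s) s$parameter_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate parameter_id in specs: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  # one uniform stream per linkage group (or per parameter when unlinked)
  stream_of <- vapply(specs, function(s) {
    if (!is.na(s$linkage_group)) paste0("group:", s$linkage_group)
    else paste0("param:", s$parameter_id)
  }, character(1))
  u <- matrix(NA_real_, nrow = iterations,
              ncol = length(unique(stream_of)),
              dimnames = list(NULL, unique(stream_of)))
  for (key in unique(stream_of)) {
    set.seed(stream_seed(seed, key))
    u[, key] <- runif(iterations)
  }
  draws <- matrix(NA_real_, nrow = iterations, ncol = length(specs),
                  dimnames = list(NULL, ids))
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    uj <- u[, stream_of[j]]
    draws[, j] <- switch(s$family,
      fixed = rep(s$mean, iterations),
      gamma = {
        gp <- gamma_params(s$mean, s$sd)
        stats::qgamma(uj, shape = gp$shape, scale = gp$scale)
      },
      beta = {
        bp <- beta_params(s$mean, s$sd)
        stats::qbeta(uj, shape1 = bp$alpha, shape2 = bp$beta)
      })
  }
  procs <- scenario$index_procedures
  samples <- matrix(NA_real_, nrow = iterations, ncol = length(procs),
                    dimnames = list(NULL, procs))
  sc <- scenario
  for (i in seq_len(iterations)) {
    sc$value_overrides <- as.list(draws[i, ])
    for (p in procs) {
      samples[i, p] <- total_cost(sc, p)$total + scenario_labour_cost(sc, p)
    }
  }
  summary <- do.call(rbind, lapply(procs, function(p) {
    x <- samples[, p]
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(procedure = p, mean = mean(x), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
               whisker_high = max(x[x <= q[3] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  res <- structure(
    list(iterations = iterations, seed = seed, samples = samples,
         draws = draws, summary = summary,
         mean_difference = if (length(procs) >= 2) {
           mean(samples[, 2] - samples[, 1])
         } else {
           NA_real_
         },
         fraction_cheaper = if (length(procs) >= 2) {
           mean(samples[, 1] < samples[, 2])
         } else {
           NA_real_
         },
         test = NULL),
    class = "cma_psa")
  if (length(procs) >= 2 && var(samples[, 1]) > 0 &&
      var(samples[, 2]) > 0) {
    res$test <- compare_psa(res, alpha_level)
  }
  res
}

#' @export
print.cma_psa <- function(x, ...) {
  cat("<cma_psa> ", x$iterations, " iterations (seed ", x$seed, ")\n",
      sep = "")
  s <- x$summary
  s[-1] <- lapply(s[-1], function(v) format(round_jpy(v), big.mark = ","))
  print(s, row.names = FALSE)
  if (!is.na(x$mean_difference)) {
    cat("mean difference (", colnames(x$samples)[2], " - ",
        colnames(x$samples)[1], "): ",
        format(round_jpy(x$mean_difference), big.mark = ","), " JPY\n",
        sep = "")
    cat(sprintf("fraction of iterations with %s cheaper: %.3f\n",
                colnames(x$samples)[1], x$fraction_cheaper))
  }
  if (!is.null(x$test)) {
    cat(sprintf("t = %.2f, p = %.3g (%ssignificant at %g%%)\n",
                x$test$t_statistic, x$test$t_p_value,
                if (x$test$significant) "" else "not ",
                100 * x$test$alpha_level))
  }
  invisible(x)
}

#' Between-arm significance test on PSA samples
#'
#' Follows the reference analysis: a variance-homogeneity check on the two
#' arms' per-iteration totals, then a two-tailed pooled-variance t-test at
#' the stated level; if the variances are incompatible (F-test p < 0.05) the
#' Welch unequal-variance t-test is used instead and a warning is issued.
#'
#' @param result A `cma_psa` with at least two procedures.
#' @param alpha_level Significance level (default 0.01).
#' @return `list(variance_check_p, t_statistic, t_p_value, significant,
#'   alpha_level, pooled)`.
#' @export
compare_psa <- function(result, alpha_level = 0.01) {
  stopifnot(inherits(result, "cma_psa"))
  if (ncol(result$samples) < 2) {
    stop("need two procedures to compare", call. = FALSE)
  }
  x <- result$samples[, 1]
  y <- result$samples[, 2]
  if (length(x) < 2 || var(x) == 0 || var(y) == 0) {
    stop("degenerate (zero-variance) samples; cannot test", call. = FALSE)
  }
  vp <- stats::var.test(x, y)$p.value
  pooled <- vp >= 0.05
  if (!pooled) {
    warning("arm variances differ (F-test p = ", signif(vp, 3),
            "); falling back to the Welch unequal-variance t-test",
            call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(variance_check_p = vp,
       t_statistic = unname(tt$statistic),
       t_p_value = tt$p.value,
       significant = tt$p.value < alpha_level,
       alpha_level = alpha_level,
       pooled = pooled)
}
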