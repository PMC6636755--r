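#' Define a one-way sensitivity-analysis parameter
#'
#' The four parameters varied one at a time in the deterministic sensitivity
#' analyses: the proportion of MRgFUS procedures needing a subsequent RFT
#' (base 3.56%, varied 0–10%), the DBS electrode extraction rate (base 1%,
#' varied 0–2%), the post-procedure hospitalisation duration for unilateral
#' DBS (base 8 days, varied 2–10), and the MRgFUS procedure duration in the
#' labour scenarios (base 4 h, varied 2–6).
#'
#' @param name One of `"rft_proportion"`, `"extraction_rate"`,
#'   `"dbs_post_hospital_days"`, `"mrgfus_duration_hours"`.
#' @param base_value Base-case value.
#' @param test_values Values to evaluate in addition to the base.
#' @return An object of class `dsa_parameter`.
#' @export
dsa_parameter <- function(name, base_value, test_values) {
  name <- match.arg(name, c("rft_proportion", "extraction_rate",
                            "dbs_post_hospital_days",
                            "mrgfus_duration_hours"))
  if (name %in% c("rft_proportion", "extraction_rate") &&
      any(c(base_value, test_values) < 0 | c(base_value, test_values) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (name == "dbs_post_hospital_days" &&
      any(c(base_value, test_values) < 0 |
            c(base_value, test_values) != floor(c(base_value, test_values)))) {
    stop("hospital days must be non-negative integers", call. = FALSE)
  }
  if (name == "mrgfus_duration_hours" &&
      any(c(base_value, test_values) <= 0)) {
    stop("durations must be positive", call. = FALSE)
  }
  structure(list(name = name, base_value = base_value,
                 test_values = test_values),
            class = "dsa_parameter")
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the full scenario at the base value and at each test value of
#' a single parameter, rebuilding the scenario for every row (no shared
#' mutable state, so rows are independent and order-insensitive). The row at
#' the base value reproduces the unmodified scenario exactly.
#'
#' @param scenario A `cma_scenario`.
#' @param parameter A [dsa_parameter()].
#' @return A data.frame of class `cma_dsa`: one row per parameter value with
#'   the grand total of each index procedure and their difference.
#' @export
run_one_way <- function(scenario, parameter) {
  stopifnot(inherits(scenario, "cma_scenario"),
            inherits(parameter, "dsa_parameter"))
  if (parameter$name == "mrgfus_duration_hours" &&
      scenario$config$labour_year == "none") {
    stop("mrgfus_duration_hours requires a labour scenario ",
         "(labour_year 2016 or 2018)", call. = FALSE)
  }
  values <- c(parameter$base_value, parameter$test_values)
  rows <- lapply(values, function(v) {
    cfg <- scenario$config
    cfg$overrides[[parameter$name]] <- v
    sc <- build_scenario(cfg, scenario$inputs$catalog,
                         scenario$inputs$procedures_base,
                         labour = scenario$inputs$labour_set,
                         linkage = scenario$inputs$linkage)
    res <- run_scenario(sc)
    wide <- setNames(as.list(res$grand_total), res$row)
    cbind(data.frame(parameter = parameter$name, value = v,
                     stringsAsFactors = FALSE),
          as.data.frame(wide, check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cma_dsa", "data.frame")
  attr(out, "base_value") <- parameter$base_value
  out
}

#' @export
print.cma_dsa <- function(x, ...) {
  cat("One-way sensitivity analysis:", x$parameter[1],
      "(base", attr(x, "base_value"), "; JPY, rounded)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  num[names(y) == "value"] <- FALSE
  y[num] <- lapply(y[num], function(v) format(round_jpy(v), big.mark = ","))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Tornado-style span summary of one-way analyses
#'
#' For each parameter table, the minimum and maximum of the between-procedure
#' difference across its rows and the resulting span width, sorted widest
#' first — the ranking used to draw a tornado diagram.
#'
#' @param tables A list of `cma_dsa` tables (or a single table).
#' @return A data.frame with columns `parameter`, `min_difference`,
#'   `max_difference`, `span`.
#' @export
tornado_summary <- function(tables) {
  if (inherits(tables, "cma_dsa")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    stopifnot(inherits(tb, "cma_dsa"))
    d <- tb$difference
    data.frame(parameter = tb$parameter[1], min_difference = min(d),
               max_difference = max(d), span = max(d) - min(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), , drop = FALSE]
  rownames(out) <- NULL
  out
}
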