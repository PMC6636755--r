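#' Configure an analysis scenario
#'
#' A scenario fixes the tariff mode (FFS base case, or DPC substitution where
#' DPC tariffs replace FFS prices for pre-procedure, post-procedure and
#' day-of-procedure hospitalisation items), the labour add-on year (none,
#' 2016 or 2018 JHIFS tariffs) and any parameter overrides used by the
#' one-way sensitivity analyses.
#'
#' @param medical_tariff `"FFS"` or `"DPC"`.
#' @param labour_year `"none"`, `"2016"` or `"2018"`.
#' @param correction_factor Day-of-procedure labour correction factor
#'   (default 0.7; unused when `labour_year = "none"`).
#' @param overrides Named list of parameter overrides; recognised names are
#'   `rft_proportion`, `extraction_rate`, `dbs_post_hospital_days` and
#'   `mrgfus_duration_hours`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(medical_tariff = c("FFS", "DPC"),
                            labour_year = c("none", "2016", "2018"),
                            correction_factor = 0.7,
                            overrides = list()) {
  medical_tariff <- match.arg(medical_tariff)
  labour_year <- match.arg(as.character(labour_year),
                           c("none", "2016", "2018"))
  if (correction_factor <= 0 || correction_factor > 1) {
    stop("correction_factor must be in (0, 1]", call. = FALSE)
  }
  known <- c("rft_proportion", "extraction_rate", "dbs_post_hospital_days",
             "mrgfus_duration_hours")
  unknown <- setdiff(names(overrides), known)
  if (length(unknown)) {
    stop("unknown override parameter(s): ",
         paste(unknown, collapse = ", "), "; recognised: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(list(medical_tariff = medical_tariff, labour_year = labour_year,
                 correction_factor = correction_factor,
                 overrides = overrides),
            class = "scenario_config")
}

# Apply one named override to the procedure set; returns modified procedures.
apply_override <- function(procedures, name, value, labour_year) {
  set_event_prob <- function(proc_name, event_name, p) {
    if (p < 0 || p > 1) {
      stop("override '", name, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
    p_obj <- procedures[[proc_name]]
    for (i in seq_along(p_obj$events)) {
      if (p_obj$events[[i]]$name == event_name) {
        p_obj$events[[i]]$probability <- p
        procedures[[proc_name]] <<- p_obj
        return(invisible())
      }
    }
    stop("procedure '", proc_name, "' has no event '", event_name, "'",
         call. = FALSE)
  }
  switch(name,
    rft_proportion = set_event_prob("MRgFUS", "rft_retreatment", value),
    extraction_rate = set_event_prob("unilateral_DBS", "electrode_extraction",
                                     value),
    dbs_post_hospital_days = {
      if (value < 0 || value != floor(value)) {
        stop("dbs_post_hospital_days must be a non-negative integer",
             call. = FALSE)
      }
      procedures$unilateral_DBS$hospitalisation$days <- value
    },
    mrgfus_duration_hours = {
      if (labour_year == "none") {
        stop("mrgfus_duration_hours requires a labour scenario ",
             "(labour_year 2016 or 2018)", call. = FALSE)
      }
      if (value <= 0) stop("mrgfus_duration_hours must be positive",
                           call. = FALSE)
      procedures$MRgFUS$duration_hours <- value
    },
    stop("unknown override '", name, "'", call. = FALSE)
  )
  procedures
}

#' Assemble a runnable scenario
#'
#' Resolves the catalog, procedure definitions and (optionally) labour models
#' under a [scenario_config()]. In DPC mode an item is priced under its DPC
#' row where one exists and falls back to FFS (then the drug tariff)
#' otherwise, so the substitution touches exactly the items the catalog
#' declares under DPC; procedure fees, devices and drugs without DPC rows
#' keep their base prices.
#'
#' @param config A [scenario_config()].
#' @param cat A `cma_catalog`.
#' @param procedures Named list of [procedure_model()] objects.
#' @param labour Optional labour model set: a list keyed by year
#'   (`"2016"`, `"2018"`), each a named list of [labour_model()] objects per
#'   procedure.
#' @param linkage Optional named character vector mapping item ids to PSA
#'   linkage groups (linked parameters share one draw per iteration).
#' @return An object of class `cma_scenario`.
#' @export
build_scenario <- function(config, cat, procedures, labour = NULL,
                           linkage = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(cat, "cma_catalog"))
  validate_catalog(cat)
  for (ov in names(config$overrides)) {
    procedures <- apply_override(procedures, ov, config$overrides[[ov]],
                                 config$labour_year)
  }
  # event references must resolve and must be depth-1
  for (p in procedures) {
    for (ev in p$events) {
      ref <- procedures[[ev$procedure]]
      if (is.null(ref)) {
        stop("procedure '", p$name, "' event '", ev$name,
             "' references unresolved procedure '", ev$procedure, "'",
             call. = FALSE)
      }
      if (length(ref$events)) {
        stop("event tree must have depth 1: '", ev$procedure,
             "' is referenced by '", p$name, "' but has events of its own",
             call. = FALSE)
      }
    }
  }
  tariff_order <- if (config$medical_tariff == "DPC") {
    c("DPC", "FFS", "drug_tariff")
  } else {
    c("FFS", "drug_tariff")
  }
  active_labour <- NULL
  if (config$labour_year != "none") {
    if (is.null(labour) || is.null(labour[[config$labour_year]])) {
      stop("labour_year = ", config$labour_year,
           " but no labour models were supplied for that year",
           call. = FALSE)
    }
    active_labour <- labour[[config$labour_year]]
  }
  referenced <- unlist(lapply(procedures,
                              function(p) vapply(p$events,
                                                 function(e) e$procedure,
                                                 character(1))))
  sc <- structure(
    list(config = config, catalog = cat, procedures = procedures,
         labour = active_labour, linkage = linkage,
         tariff_order = tariff_order,
         index_procedures = setdiff(names(procedures), referenced),
         value_overrides = list(),
         inputs = list(catalog = cat, procedures_base = procedures,
                       labour_set = labour, linkage = linkage)),
    class = "cma_scenario")
  # fail fast on unpriceable items
  for (p in sc$index_procedures) total_cost(sc, p)
  sc
}

#' @export
print.cma_scenario <- function(x, ...) {
  cat("<cma_scenario> tariff:", x$config$medical_tariff,
      "| labour:", x$config$labour_year, "\n")
  cat("  procedures:", paste(names(x$procedures), collapse = ", "), "\n")
  if (length(x$config$overrides)) {
    cat("  overrides:",
        paste(names(x$config$overrides), unlist(x$config$overrides),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Labour cost attached to one index procedure in this scenario (0 if the
# scenario has no labour add-on or the procedure has no labour model).
scenario_labour_cost <- function(scenario, proc_name) {
  if (is.null(scenario$labour)) return(0)
  model <- scenario$labour[[proc_name]]
  if (is.null(model)) return(0)
  proc <- scenario$procedures[[proc_name]]
  procedure_labour_cost(model, scenario$config$labour_year,
                        proc$duration_hours)
}

#' Run a scenario and tabulate per-procedure costs
#'
#' Evaluates the staged totals of every index procedure (a procedure not
#' referenced as a downstream event), the labour add-on where configured, and
#' a difference row (first index procedure minus second — MRgFUS minus DBS in
#' the calibrated model, so negative differences are savings for MRgFUS).
#' All values are exact; use [render_table()] for integer-rounded output.
#'
#' @param scenario A `cma_scenario`.
#' @return A data.frame of class `cma_results` with columns `row`, `pre`,
#'   `procedure`, `post`, `medical_total`, `labour`, `grand_total`.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "cma_scenario"))
  procs <- scenario$index_procedures
  rows <- lapply(procs, function(p) {
    bd <- total_cost(scenario, p)
    lab <- scenario_labour_cost(scenario, p)
    data.frame(row = p, pre = bd$pre, procedure = bd$procedure,
               post = bd$post, medical_total = bd$total, labour = lab,
               grand_total = bd$total + lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(procs) >= 2) {
    d <- out[1, -1] - out[2, -1]
    out <- rbind(out, cbind(data.frame(row = "difference",
                                       stringsAsFactors = FALSE), d))
  }
  rownames(out) <- NULL
  class(out) <- c("cma_results", "data.frame")
  attr(out, "config") <- scenario$config
  out
}

#' @export
print.cma_results <- function(x, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    cat("Scenario results (JPY, rounded; tariff ", cfg$medical_tariff,
        ", labour ", cfg$labour_year, ")\n", sep = "")
  }
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) format(round_jpy(v), big.mark = ","))
  print(y, row.names = FALSE)
  invisible(x)
}
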