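#' Define a labour entry (one professional role on one phase)
#'
#' JHIFS (Gaihoren) hourly labour tariffs price healthcare-professional time
#' not fully reflected in FFS/DPC tariffs. An entry is one role with
#' year-specific hourly rates, a headcount, and a number of hours, tagged
#' with the phase it belongs to. Entries flagged
#' `scales_with_duration = TRUE` are evaluated at the procedure duration
#' instead of their nominal `hours`.
#'
#' @param role Role description.
#' @param rates Named numeric vector of hourly rates in JPY keyed by year,
#'   e.g. `c("2016" = 9000, "2018" = 11000)`.
#' @param headcount Number of staff (>= 1).
#' @param hours Nominal hours of labour (>= 0).
#' @param phase `"pre_procedure"` or `"day_of_procedure"`.
#' @param scales_with_duration Logical; evaluate at the procedure duration?
#' @return An object of class `labour_entry`.
#' @export
labour_entry <- function(role, rates, headcount = 1, hours = 1,
                         phase = c("pre_procedure", "day_of_procedure"),
                         scales_with_duration = FALSE) {
  phase <- match.arg(phase)
  if (any(rates < 0) || headcount < 0 || hours < 0) {
    stop("rates, headcount and hours must be non-negative", call. = FALSE)
  }
  if (is.null(names(rates)) || any(names(rates) == "")) {
    stop("rates must be named by year", call. = FALSE)
  }
  structure(list(role = role, rates = rates, headcount = headcount,
                 hours = hours, phase = phase,
                 scales_with_duration = isTRUE(scales_with_duration)),
            class = "labour_entry")
}

#' Assemble a labour model for one procedure
#'
#' The day-of-procedure phase is multiplied by a correction factor
#' (default 0.7) to offset the known overestimation of the JHIFS tariff
#' relative to FFS; pre-procedure entries are never corrected. Labour for a
#' probability-weighted downstream procedure (re-treatment RFT after MRgFUS)
#' can be attached via `event_labour` and enters weighted by its probability.
#'
#' @param entries List of [labour_entry()] objects.
#' @param correction_factor Fraction in `(0, 1]` applied to the
#'   day-of-procedure phase only.
#' @param event_labour Optional `list(probability =, model =, duration =)`
#'   adding `probability * procedure_labour_cost(model, year, duration)`.
#' @return An object of class `labour_model`.
#' @export
labour_model <- function(entries, correction_factor = 0.7,
                         event_labour = NULL) {
  if (!is.numeric(correction_factor) || correction_factor <= 0 ||
      correction_factor > 1) {
    stop("correction_factor must be in (0, 1]", call. = FALSE)
  }
  for (e in entries) stopifnot(inherits(e, "labour_entry"))
  if (!is.null(event_labour)) {
    stopifnot(is.list(event_labour),
              all(c("probability", "model", "duration") %in%
                    names(event_labour)),
              inherits(event_labour$model, "labour_model"))
  }
  structure(list(entries = entries, correction_factor = correction_factor,
                 event_labour = event_labour),
            class = "labour_model")
}

#' Cost of a single labour entry
#'
#' `hourly_rate(year) * headcount * hours`; duration-scaling entries are
#' evaluated at `duration` instead of their nominal hours.
#'
#' @param entry A [labour_entry()].
#' @param year Tariff year (must have a rate defined).
#' @param duration Procedure duration in hours (used only by scaling
#'   entries).
#' @return Cost in JPY (uncorrected).
#' @export
labour_entry_cost <- function(entry, year, duration = NULL) {
  stopifnot(inherits(entry, "labour_entry"))
  rate <- unname(entry$rates[as.character(year)])
  if (is.na(rate)) {
    stop("no hourly rate defined for year ", year, " (role '", entry$role,
         "'); available years: ", paste(names(entry$rates), collapse = ", "),
         call. = FALSE)
  }
  hrs <- if (entry$scales_with_duration) {
    if (is.null(duration)) {
      stop("entry '", entry$role, "' scales with duration but no duration ",
           "was supplied", call. = FALSE)
    }
    duration
  } else {
    entry$hours
  }
  rate * entry$headcount * hrs
}

#' Labour cost of a procedure
#'
#' Pre-procedure entries are summed uncorrected; day-of-procedure entries are
#' summed (with duration-scaling entries evaluated at `duration`) and
#' multiplied by the correction factor; probability-weighted event labour is
#' added last. Exact, unrounded.
#'
#' @param model A [labour_model()].
#' @param year Tariff year (2016 or 2018 for the JHIFS tariffs).
#' @param duration Procedure duration in hours (> 0).
#' @return Labour cost in JPY.
#' @export
procedure_labour_cost <- function(model, year, duration) {
  stopifnot(inherits(model, "labour_model"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  pre <- 0
  day <- 0
  for (e in model$entries) {
    cost <- labour_entry_cost(e, year, duration)
    if (e$phase == "pre_procedure") pre <- pre + cost else day <- day + cost
  }
  total <- pre + model$correction_factor * day
  ev <- model$event_labour
  if (!is.null(ev) && ev$probability > 0) {
    total <- total + ev$probability *
      procedure_labour_cost(ev$model, year, ev$duration)
  }
  total
}

#' Labour cost across procedure durations
#'
#' Evaluates [procedure_labour_cost()] at each duration. Because only the
#' day-of-procedure scaling entries depend on duration, the result is affine
#' in duration with slope
#' `correction_factor * sum(rate * headcount)` over scaling entries.
#'
#' @param model A [labour_model()].
#' @param year Tariff year.
#' @param durations Numeric vector of positive durations in hours.
#' @return Named numeric vector, one labour cost per duration.
#' @export
duration_sensitivity <- function(model, year, durations) {
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  setNames(vapply(durations,
                  function(d) procedure_labour_cost(model, year, d),
                  numeric(1)),
           as.character(durations))
}
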