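#' Define a probability-weighted downstream event
#'
#' Downstream events attach the expected cost of a follow-on procedure to an
#' index procedure over the 12-month horizon: re-treatment by radiofrequency
#' thalamotomy after tremor recurrence following MRgFUS, and extraction
#' surgery after unilateral DBS. The event contributes
#' `probability * total cost of the referenced procedure`, allocated to the
#' post-procedure stage. Referenced procedures may not themselves carry
#' events (the event tree has depth 1).
#'
#' @param name Event name.
#' @param probability Probability over the 12-month horizon, in `[0, 1]`.
#' @param procedure Name of the referenced procedure.
#' @return An object of class `downstream_event`.
#' @export
downstream_event <- function(name, probability, procedure) {
  if (!is.numeric(probability) || length(probability) != 1 ||
      is.na(probability) || probability < 0 || probability > 1) {
    stop("event probability must be a single value in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, probability = as.numeric(probability),
                 procedure = procedure),
            class = "downstream_event")
}

#' Define a procedure as a bundle of catalog items and downstream events
#'
#' A procedure is costed as the sum of its stage-tagged catalog items, an
#' optional day-indexed hospitalisation stay, and the expected cost of its
#' downstream events.
#'
#' @param name Procedure name (e.g. `"MRgFUS"`, `"unilateral_DBS"`, `"RFT"`,
#'   `"extraction"`).
#' @param items Character vector of catalog item ids.
#' @param events List of [downstream_event()] objects.
#' @param duration_hours Procedure duration in hours (used by the labour
#'   model; base 4 for MRgFUS and DBS, 2 for extraction surgery).
#' @param hospitalisation Optional `list(schedule =, days =, stage =)` costing
#'   a hospital stay from a named catalog [hosp_schedule()].
#' @return An object of class `procedure_model`.
#' @export
procedure_model <- function(name, items = character(), events = list(),
                            duration_hours = 4, hospitalisation = NULL) {
  if (!is.numeric(duration_hours) || duration_hours <= 0) {
    stop("duration_hours must be positive", call. = FALSE)
  }
  for (ev in events) {
    if (!inherits(ev, "downstream_event")) {
      stop("events must be downstream_event objects", call. = FALSE)
    }
    if (identical(ev$procedure, name)) {
      stop("procedure '", name, "' may not reference itself as a downstream ",
           "event", call. = FALSE)
    }
  }
  if (!is.null(hospitalisation)) {
    stopifnot(is.list(hospitalisation),
              all(c("schedule", "days", "stage") %in% names(hospitalisation)))
    hospitalisation$stage <- match.arg(hospitalisation$stage, cma_stages)
  }
  structure(list(name = name, items = as.character(items), events = events,
                 duration_hours = as.numeric(duration_hours),
                 hospitalisation = hospitalisation),
            class = "procedure_model")
}

# Resolve a procedure argument (name or object) against a scenario.
resolve_procedure <- function(scenario, procedure) {
  if (inherits(procedure, "procedure_model")) return(procedure)
  p <- scenario$procedures[[procedure]]
  if (is.null(p)) {
    stop("unknown procedure '", procedure, "'; scenario defines: ",
         paste(names(scenario$procedures), collapse = ", "), call. = FALSE)
  }
  p
}

# Price one item id under the scenario's tariff preference order, honouring
# PSA value overrides ("item:<id>").
price_item <- function(scenario, item_id) {
  ov <- scenario$value_overrides[[paste0("item:", item_id)]]
  if (!is.null(ov)) return(ov)
  items <- scenario$catalog$items
  for (sys in scenario$tariff_order) {
    hit <- which(items$item_id == item_id & items$tariff_system == sys)
    if (length(hit)) {
      return(items$unit_cost[hit[1]] * items$quantity[hit[1]])
    }
  }
  avail <- unique(items$tariff_system[items$item_id == item_id])
  if (length(avail)) {
    stop("item '", item_id, "' not priced under any of: ",
         paste(scenario$tariff_order, collapse = ", "),
         " (available: ", paste(avail, collapse = ", "), ")", call. = FALSE)
  }
  stop("unknown item '", item_id, "'", call. = FALSE)
}

# Resolve the hospitalisation schedule for a procedure under the scenario's
# tariff mode (a "<name>_dpc" variant takes precedence in DPC mode) and cost
# the stay, honouring PSA overrides ("hosp:<procedure>").
procedure_hosp_cost <- function(scenario, proc) {
  h <- proc$hospitalisation
  if (is.null(h)) return(0)
  ov <- scenario$value_overrides[[paste0("hosp:", proc$name)]]
  if (!is.null(ov)) return(ov)
  name <- h$schedule
  if (scenario$config$medical_tariff == "DPC") {
    dpc_name <- paste0(name, "_dpc")
    if (dpc_name %in% names(scenario$catalog$schedules)) name <- dpc_name
  }
  sched <- scenario$catalog$schedules[[name]]
  if (is.null(sched)) {
    stop("hospitalisation schedule '", name, "' not found in catalog",
         call. = FALSE)
  }
  hospitalisation_cost(sched, h$days)
}

event_probability <- function(scenario, proc, event) {
  ov <- scenario$value_overrides[[paste0("event:", proc$name, ":",
                                         event$name)]]
  if (!is.null(ov)) ov else event$probability
}

#' Cost of one stage of a procedure
#'
#' Sums `unit_cost * quantity` over the procedure's catalog items tagged with
#' the stage, plus the hospitalisation stay if allocated to that stage.
#' Downstream events are *not* included here (see [total_cost()]).
#'
#' @param scenario A `cma_scenario` from [build_scenario()].
#' @param procedure Procedure name or `procedure_model`.
#' @param stage One of `"pre"`, `"procedure"`, `"post"`.
#' @return Cost in JPY (exact, unrounded).
#' @export
stage_cost <- function(scenario, procedure, stage) {
  stage <- match.arg(stage, cma_stages)
  proc <- resolve_procedure(scenario, procedure)
  items <- scenario$catalog$items
  total <- 0
  for (id in proc$items) {
    # stage tag comes from the first priced row for the id
    rows <- which(items$item_id == id)
    if (!length(rows)) stop("unknown item '", id, "'", call. = FALSE)
    if (items$stage[rows[1]] != stage) next
    total <- total + price_item(scenario, id)
  }
  if (!is.null(proc$hospitalisation) &&
      proc$hospitalisation$stage == stage) {
    total <- total + procedure_hosp_cost(scenario, proc)
  }
  total
}

#' Expected cost of a downstream event
#'
#' `probability * total cost of the referenced procedure`, exact and
#' unrounded. The referenced procedure must itself have no downstream events.
#'
#' @param scenario A `cma_scenario`.
#' @param event A [downstream_event()].
#' @param owner Optional owning `procedure_model` (needed to honour
#'   probability overrides set by sensitivity analyses).
#' @return Expected cost in JPY.
#' @export
expected_event_cost <- function(scenario, event, owner = NULL) {
  ref <- scenario$procedures[[event$procedure]]
  if (is.null(ref)) {
    stop("event '", event$name, "' references unknown procedure '",
         event$procedure, "'", call. = FALSE)
  }
  if (length(ref$events)) {
    stop("referenced procedure '", ref$name, "' has downstream events of ",
         "its own; the event tree must have depth 1", call. = FALSE)
  }
  p <- if (is.null(owner)) event$probability else {
    event_probability(scenario, owner, event)
  }
  if (p == 0) return(0)
  p * total_cost(scenario, ref)$total
}

#' Staged total cost of a procedure
#'
#' Sums the pre-procedure, procedure and post-procedure costs over the
#' 12-month horizon; the expected cost of each downstream event is added to
#' the post-procedure stage. No discounting is applied (12-month horizon).
#' All arithmetic is exact; rounding happens only at report rendering.
#'
#' @param scenario A `cma_scenario`.
#' @param procedure Procedure name or `procedure_model`.
#' @return An object of class `stage_breakdown`: list with components `pre`,
#'   `procedure`, `post` and `total` (`total = pre + procedure + post`
#'   exactly).
#' @export
total_cost <- function(scenario, procedure) {
  proc <- resolve_procedure(scenario, procedure)
  pre <- stage_cost(scenario, proc, "pre")
  during <- stage_cost(scenario, proc, "procedure")
  post <- stage_cost(scenario, proc, "post")
  for (ev in proc$events) {
    post <- post + expected_event_cost(scenario, ev, owner = proc)
  }
  structure(list(pre = pre, procedure = during, post = post,
                 total = pre + during + post),
            class = "stage_breakdown")
}

#' @export
print.stage_breakdown <- function(x, ...) {
  cat("<stage_breakdown> (JPY)\n")
  cat(sprintf("  pre:       %15.2f\n", x$pre))
  cat(sprintf("  procedure: %15.2f\n", x$procedure))
  cat(sprintf("  post:      %15.2f\n", x$post))
  cat(sprintf("  total:     %15.2f\n", x$total))
  invisible(x)
}

#' Signed difference between two staged totals
#'
#' `a$total - b$total`, exact before rounding. By convention the model
#' reports MRgFUS minus DBS, so a negative value is a saving for MRgFUS.
#'
#' @param a,b [total_cost()] breakdowns from the same scenario.
#' @return Signed difference in JPY.
#' @export
cost_difference <- function(a, b) {
  stopifnot(inherits(a, "stage_breakdown"), inherits(b, "stage_breakdown"))
  a$total - b$total
}
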