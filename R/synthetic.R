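#' Generate a random synthetic catalog with brute-force truth totals
#'
#' Property-testing generator: builds a reproducible random catalog with the
#' structure the cost model assumes — stage-tagged items for two index
#' procedures, premium items linked to parents, depth-1 downstream events
#' (one referenced procedure per event probability), and a day-indexed
#' hospitalisation schedule on the second procedure — together with
#' *independently* computed expected totals. The truth totals are accumulated
#' by a flat loop over catalog rows, deliberately separate from the model's
#' own costing path, so they can serve as an oracle for equivalence tests.
#'
#' @param seed Integer seed; the same seed reproduces the catalog exactly.
#' @param n_items Number of non-premium items per index procedure (>= 1).
#' @param cost_range Length-2 numeric range of unit costs in JPY.
#' @param event_probabilities Numeric vector of event probabilities in
#'   `[0, 1]`; element `i` creates downstream event `i` on index procedure
#'   `(i %% 2) + 1` referencing its own event-free procedure.
#' @param n_premiums Number of premium items per index procedure.
#' @return `list(catalog, procedures, truth)` where `truth` holds per-
#'   procedure stage sums and totals computed by the independent loop.
#' @export
generate_synthetic_catalog <- function(seed, n_items = 10,
                                       cost_range = c(1000, 500000),
                                       event_probabilities = c(0.05, 0.01),
                                       n_premiums = 2) {
  if (n_items < 1) stop("n_items must be >= 1", call. = FALSE)
  if (length(cost_range) != 2 || any(cost_range < 0) ||
      cost_range[2] < cost_range[1]) {
    stop("cost_range must be a non-negative increasing interval",
         call. = FALSE)
  }
  if (any(event_probabilities < 0 | event_probabilities > 1)) {
    stop("event probabilities must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  categories <- setdiff(cma_categories, c("premium", "hospitalisation"))
  rows <- list()
  add_items <- function(prefix, n, with_premiums) {
    ids <- character(n)
    for (i in seq_len(n)) {
      id <- paste0(prefix, "_item", i)
      ids[i] <- id
      rows[[length(rows) + 1]] <<- cost_item(
        id, paste(prefix, "item", i),
        stage = sample(cma_stages, 1),
        category = sample(categories, 1),
        unit_cost = round(runif(1, cost_range[1], cost_range[2]), 2),
        quantity = sample(c(1, 1, 2, 0.5), 1),
        tariff_system = "FFS")
    }
    if (with_premiums > 0) {
      for (j in seq_len(with_premiums)) {
        parent <- sample(ids, 1)
        rows[[length(rows) + 1]] <<- cost_item(
          paste0(prefix, "_premium", j), paste(prefix, "premium", j),
          stage = sample(cma_stages, 1), category = "premium",
          unit_cost = round(runif(1, cost_range[1] / 10,
                                  cost_range[2] / 10), 2),
          quantity = 1, tariff_system = "FFS", parent_item = parent)
      }
    }
    c(ids, if (with_premiums > 0) paste0(prefix, "_premium",
                                         seq_len(with_premiums)))
  }

  ids_a <- add_items("proc_a", n_items, n_premiums)
  ids_b <- add_items("proc_b", n_items, n_premiums)
  ref_ids <- list()
  for (e in seq_along(event_probabilities)) {
    ref_ids[[e]] <- add_items(paste0("ref", e), max(1, n_items %/% 3), 0)
  }

  n_tiers <- sample(2:3, 1)
  tier_bounds <- sort(sample(2:9, n_tiers - 1))
  sched <- hosp_schedule(c(1, tier_bounds + 1),
                         c(tier_bounds, Inf),
                         round(runif(n_tiers, 5000, 30000), 0))
  days_b <- sample(3:10, 1)

  items <- do.call(rbind, rows)
  cat <- catalog(items, schedules = list(stay_b = sched),
                 currency_year = 2018)

  events_a <- list(); events_b <- list()
  ref_procs <- list()
  for (e in seq_along(event_probabilities)) {
    ref_name <- paste0("referenced_", e)
    ref_procs[[ref_name]] <- procedure_model(ref_name,
                                             items = ref_ids[[e]],
                                             duration_hours = 2)
    ev <- downstream_event(paste0("event_", e), event_probabilities[e],
                           ref_name)
    if (e %% 2 == 1) events_a[[length(events_a) + 1]] <- ev
    else events_b[[length(events_b) + 1]] <- ev
  }
  procedures <- c(list(
    proc_A = procedure_model("proc_A", items = ids_a, events = events_a,
                             duration_hours = 4),
    proc_B = procedure_model("proc_B", items = ids_b, events = events_b,
                             duration_hours = 4,
                             hospitalisation = list(schedule = "stay_b",
                                                    days = days_b,
                                                    stage = "post"))),
    ref_procs)

  truth <- brute_force_truth(items, sched, days_b, procedures,
                             event_probabilities)
  list(catalog = cat, procedures = procedures, truth = truth)
}

# Independent oracle: flat loops over the item table, no calls into the
# model's costing functions.
brute_force_truth <- function(items, sched, days_b, procedures,
                              event_probabilities) {
  sum_proc <- function(ids) {
    stage_sum <- c(pre = 0, procedure = 0, post = 0)
    for (i in seq_len(nrow(items))) {
      if (items$item_id[i] %in% ids) {
        stage_sum[items$stage[i]] <- stage_sum[items$stage[i]] +
          items$unit_cost[i] * items$quantity[i]
      }
    }
    stage_sum
  }
  hosp <- 0
  d <- 1
  while (d <= days_b) {
    for (r in seq_along(sched$day_from)) {
      if (d >= sched$day_from[r] && d <= sched$day_to[r]) {
        hosp <- hosp + sched$fee_per_day[r]
      }
    }
    d <- d + 1
  }
  ref_totals <- numeric(0)
  for (nm in names(procedures)) {
    if (startsWith(nm, "referenced_")) {
      ref_totals[nm] <- sum(sum_proc(procedures[[nm]]$items))
    }
  }
  totals <- list()
  for (nm in c("proc_A", "proc_B")) {
    p <- procedures[[nm]]
    s <- sum_proc(p$items)
    if (nm == "proc_B") s["post"] <- s["post"] + hosp
    ev_cost <- 0
    for (ev in p$events) {
      ev_cost <- ev_cost + ev$probability * ref_totals[[ev$procedure]]
    }
    totals[[nm]] <- list(stages = s, event_cost = ev_cost,
                         total = sum(s) + ev_cost)
  }
  totals$referenced <- ref_totals
  totals$hospitalisation <- hosp
  totals
}
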