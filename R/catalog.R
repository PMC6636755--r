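#' @importFrom stats median quantile rnorm runif setNames var
#' @importFrom utils read.csv write.csv
NULL

# Enumerations shared across the package. Tariff systems follow the Japanese
# reimbursement landscape: itemised fee-for-service (FFS), the DRG-style
# Diagnosis Procedure Combination per-diems (DPC), the National Drug Tariff,
# and the JHIFS (Gaihoren) hourly labour tariffs for 2016 and 2018.
cma_stages <- c("pre", "procedure", "post")
cma_categories <- c("imaging", "hospitalisation", "drug", "device", "fee",
                    "anaesthesia", "session", "labour", "premium")
cma_tariff_systems <- c("FFS", "DPC", "drug_tariff", "JHIFS2016", "JHIFS2018")

#' Create a tariff cost line item
#'
#' A `cost_item` is the atom of the costing model: a resource-use line priced
#' under one tariff system. Premium items (category `"premium"`) are tariff
#' add-ons billed alongside a parent activity and must name that parent via
#' `parent_item`.
#'
#' @param item_id Identifier, unique within a tariff system.
#' @param label Human-readable description.
#' @param stage One of `"pre"`, `"procedure"`, `"post"`.
#' @param category Item category (see Details).
#' @param unit_cost Unit cost in JPY, non-negative.
#' @param quantity Quantity (continuous values allowed), non-negative.
#' @param tariff_system One of `"FFS"`, `"DPC"`, `"drug_tariff"`,
#'   `"JHIFS2016"`, `"JHIFS2018"`.
#' @param parent_item Parent item id for premium items, otherwise `NA`.
#' @param sampled Logical; does the item participate in probabilistic
#'   sensitivity analysis (`TRUE`) or is it structurally fixed?
#'
#' @details Categories: imaging, hospitalisation, drug, device, fee,
#'   anaesthesia, session, labour, premium.
#'
#' @return A one-row data.frame with the item fields.
#' @examples
#' cost_item("mri_pre", "Pre-procedure MRI", "pre", "imaging", 19000, 1)
#' @export
cost_item <- function(item_id, label, stage, category, unit_cost,
                      quantity = 1, tariff_system = "FFS",
                      parent_item = NA_character_, sampled = TRUE) {
  stage <- match.arg(stage, cma_stages)
  category <- match.arg(category, cma_categories)
  tariff_system <- match.arg(tariff_system, cma_tariff_systems)
  if (!is.numeric(unit_cost) || length(unit_cost) != 1 || is.na(unit_cost) ||
      unit_cost < 0) {
    stop("unit_cost must be a single non-negative number (item '",
         item_id, "')", call. = FALSE)
  }
  if (!is.numeric(quantity) || length(quantity) != 1 || is.na(quantity) ||
      quantity < 0) {
    stop("quantity must be a single non-negative number (item '",
         item_id, "')", call. = FALSE)
  }
  data.frame(item_id = as.character(item_id), label = as.character(label),
             stage = stage, category = category,
             unit_cost = as.numeric(unit_cost),
             quantity = as.numeric(quantity),
             tariff_system = tariff_system,
             parent_item = as.character(parent_item),
             sampled = isTRUE(sampled),
             stringsAsFactors = FALSE)
}

#' Create a day-indexed hospitalisation fee schedule
#'
#' Japanese per-diem hospitalisation fees are tiered by day of stay, so the
#' marginal cost of a day depends on how long the patient has already been in
#' hospital. A schedule is a piecewise-constant per-day fee over contiguous
#' day ranges starting at day 1; the last range may be open-ended
#' (`day_to = Inf`).
#'
#' @param day_from,day_to Integer vectors of range bounds (inclusive).
#' @param fee_per_day Per-day fee in JPY for each range, non-negative.
#' @return An object of class `hosp_schedule`.
#' @examples
#' sched <- hosp_schedule(c(1, 9), c(8, Inf), c(17000, 20410))
#' hospitalisation_cost(sched, 10)
#' @export
hosp_schedule <- function(day_from, day_to, fee_per_day) {
  if (length(day_from) != length(day_to) ||
      length(day_from) != length(fee_per_day)) {
    stop("day_from, day_to and fee_per_day must have equal length",
         call. = FALSE)
  }
  if (length(day_from) == 0) stop("schedule must have at least one range",
                                  call. = FALSE)
  ord <- order(day_from)
  day_from <- day_from[ord]; day_to <- day_to[ord]
  fee_per_day <- fee_per_day[ord]
  if (day_from[1] != 1) stop("schedule ranges must start at day 1",
                             call. = FALSE)
  if (any(day_to < day_from)) stop("each range needs day_to >= day_from",
                                   call. = FALSE)
  if (length(day_from) > 1 &&
      any(day_from[-1] != day_to[-length(day_to)] + 1)) {
    stop("schedule ranges must be contiguous and non-overlapping",
         call. = FALSE)
  }
  if (any(fee_per_day < 0)) stop("per-day fees must be non-negative",
                                 call. = FALSE)
  structure(list(day_from = day_from, day_to = day_to,
                 fee_per_day = as.numeric(fee_per_day)),
            class = "hosp_schedule")
}

#' Cumulative hospitalisation cost for a stay
#'
#' Sums the per-day fees of a [hosp_schedule()] over days `1..days`.
#'
#' @param schedule A [hosp_schedule()].
#' @param days Non-negative integer number of days.
#' @return Total cost in JPY.
#' @export
hospitalisation_cost <- function(schedule, days) {
  stopifnot(inherits(schedule, "hosp_schedule"))
  if (!is.numeric(days) || length(days) != 1 || is.na(days) || days < 0 ||
      days != floor(days)) {
    stop("days must be a single non-negative integer", call. = FALSE)
  }
  if (days == 0) return(0)
  if (is.finite(max(schedule$day_to)) && days > max(schedule$day_to)) {
    stop("schedule does not cover ", days, " days", call. = FALSE)
  }
  lo <- schedule$day_from
  hi <- pmin(schedule$day_to, days)
  n_days <- pmax(hi - lo + 1, 0)
  sum(n_days * schedule$fee_per_day)
}

#' Assemble a tariff catalog
#'
#' A catalog bundles priced line items with named hospitalisation fee
#' schedules for a given tariff year. Item ids must be unique within a tariff
#' system (the same id may appear under several systems, e.g. an FFS and a
#' DPC price for the same activity); every premium must reference an existing
#' non-premium parent item.
#'
#' @param items A data.frame of items, typically `rbind`-ed [cost_item()]
#'   rows.
#' @param schedules Named list of [hosp_schedule()] objects.
#' @param currency_year Tariff year the prices refer to.
#' @return An object of class `cma_catalog`.
#' @seealso [read_catalog()], [lookup_cost()]
#' @export
catalog <- function(items, schedules = list(), currency_year = 2018) {
  cat <- structure(list(items = items, schedules = schedules,
                        currency_year = currency_year),
                   class = "cma_catalog")
  validate_catalog(cat)
  cat
}

#' Validate a catalog
#'
#' Checks the catalog invariants: required columns present, costs and
#' quantities non-negative, ids unique within a tariff system, premium parents
#' resolvable to non-premium items, and schedules well-formed. Errors name
#' the offending row.
#'
#' @param cat A `cma_catalog`.
#' @return `cat`, invisibly, if valid.
#' @export
validate_catalog <- function(cat) {
  stopifnot(inherits(cat, "cma_catalog"))
  items <- cat$items
  required <- c("item_id", "label", "stage", "category", "unit_cost",
                "quantity", "tariff_system", "parent_item", "sampled")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    stop("catalog items are missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!items$stage %in% cma_stages)
  if (length(bad)) stop("invalid stage in item row ", bad[1], " ('",
                        items$item_id[bad[1]], "')", call. = FALSE)
  bad <- which(!items$category %in% cma_categories)
  if (length(bad)) stop("invalid category in item row ", bad[1], " ('",
                        items$item_id[bad[1]], "')", call. = FALSE)
  bad <- which(!items$tariff_system %in% cma_tariff_systems)
  if (length(bad)) stop("invalid tariff_system in item row ", bad[1], " ('",
                        items$item_id[bad[1]], "')", call. = FALSE)
  bad <- which(is.na(items$unit_cost) | items$unit_cost < 0)
  if (length(bad)) {
    stop("negative or missing unit_cost in item row ", bad[1], " ('",
         items$item_id[bad[1]], "')", call. = FALSE)
  }
  bad <- which(is.na(items$quantity) | items$quantity < 0)
  if (length(bad)) {
    stop("negative or missing quantity in item row ", bad[1], " ('",
         items$item_id[bad[1]], "')", call. = FALSE)
  }
  key <- paste(items$tariff_system, items$item_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate item id within a tariff system: ", dup, call. = FALSE)
  }
  prem <- which(items$category == "premium")
  if (length(prem)) {
    parents_ok <- items$item_id[items$category != "premium"]
    bad <- prem[is.na(items$parent_item[prem]) |
                  !(items$parent_item[prem] %in% parents_ok)]
    if (length(bad)) {
      stop("premium item '", items$item_id[bad[1]],
           "' (row ", bad[1], ") has no resolvable non-premium parent_item",
           call. = FALSE)
    }
  }
  for (nm in names(cat$schedules)) {
    if (!inherits(cat$schedules[[nm]], "hosp_schedule")) {
      stop("schedule '", nm, "' is not a hosp_schedule", call. = FALSE)
    }
  }
  invisible(cat)
}

#' @export
print.cma_catalog <- function(x, ...) {
  cat("<cma_catalog> ", nrow(x$items), " items, ",
      length(x$schedules), " hospitalisation schedule(s), tariff year ",
      x$currency_year, "\n", sep = "")
  tab <- table(x$items$tariff_system)
  cat("  items by system:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a catalog from CSV or JSON
#'
#' CSV files carry the item table only (UTF-8, comma-separated, header row
#' required); JSON files additionally carry hospitalisation schedules and the
#' currency year. Field names match the [cost_item()] arguments.
#'
#' @param path File path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return A validated `cma_catalog`.
#' @export
read_catalog <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  if (format == "csv") {
    items <- read.csv(path, stringsAsFactors = FALSE)
    if ("parent_item" %in% names(items)) {
      items$parent_item <- as.character(items$parent_item)
      items$parent_item[items$parent_item %in% c("", "NA")] <- NA_character_
    }
    if ("sampled" %in% names(items)) {
      items$sampled <- as.logical(items$sampled)
    }
    return(catalog(items, schedules = list(), currency_year = 2018))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as.data.frame(obj$items, stringsAsFactors = FALSE)
  items$parent_item <- as.character(items$parent_item)
  items$parent_item[items$parent_item %in% c("", "NA")] <- NA_character_
  schedules <- lapply(obj$schedules, function(s) {
    day_to <- s$day_to
    day_to[is.na(day_to)] <- Inf
    hosp_schedule(s$day_from, day_to, s$fee_per_day)
  })
  catalog(items, schedules = schedules,
          currency_year = obj$currency_year %||% 2018)
}

#' Write a catalog to CSV or JSON
#'
#' Inverse of [read_catalog()]; `read_catalog(write_catalog(cat, p))` is the
#' identity on all fields (JSON) or on the item table (CSV).
#'
#' @param cat A `cma_catalog`.
#' @param path Output file path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(cat, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(cat, "cma_catalog"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    write.csv(cat$items, path, row.names = FALSE, na = "")
  } else {
    schedules <- lapply(cat$schedules, function(s) {
      list(day_from = s$day_from,
           day_to = ifelse(is.finite(s$day_to), s$day_to, NA),
           fee_per_day = s$fee_per_day)
    })
    jsonlite::write_json(list(items = cat$items, schedules = schedules,
                              currency_year = cat$currency_year),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Price a single catalog line item
#'
#' Returns `unit_cost * quantity` for the item under the requested tariff
#' system.
#'
#' @param cat A `cma_catalog`.
#' @param item_id Item identifier.
#' @param system Tariff system to price under.
#' @return Cost in JPY.
#' @export
lookup_cost <- function(cat, item_id, system = "FFS") {
  stopifnot(inherits(cat, "cma_catalog"))
  hit <- cat$items$item_id == item_id & cat$items$tariff_system == system
  if (!any(hit)) {
    avail <- cat$items$tariff_system[cat$items$item_id == item_id]
    if (length(avail)) {
      stop("item '", item_id, "' not priced under ", system,
           "; available systems: ", paste(avail, collapse = ", "),
           call. = FALSE)
    }
    stop("unknown item '", item_id, "'", call. = FALSE)
  }
  row <- which(hit)[1]
  cat$items$unit_cost[row] * cat$items$quantity[row]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
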