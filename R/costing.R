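# Valuation of estimated HCW time with cadre salary schedules, and the
# interval arithmetic used for uncertainty propagation.
#
# A cost's uncertainty interval (UI) combines statistical uncertainty in the
# time estimate with uncertainty about a clinic's salary structure: the upper
# CI bound of the time need is valued at the cadre's highest salary level and
# the lower CI bound at its lowest level, with negative lower bounds floored
# at zero.  UIs of sums and differences take the extreme values attainable
# within the component bounds.

#' Convert an annual salary to a per-minute wage
#'
#' `annual / (workdays_per_year * hours_per_day * 60)`, optionally converting
#' Eswatini Lilangeni to United States dollars at the 2018 annual exchange
#' rate (SZL 13.234 per $1).
#'
#' @param annual annual salary (currency units per year), `>= 0`.
#' @param workdays_per_year working days per year (default 220).
#' @param hours_per_day working hours per day (default 8).
#' @param exchange_rate `NULL` for no conversion, or SZL per USD (use
#'   `szl_per_usd()` for the 2018 rate).
#' @return wage in currency units per minute.
#' @export
#' @examples
#' per_minute_wage(105600)            # 1.00 per minute
#' per_minute_wage(200000, exchange_rate = szl_per_usd())
per_minute_wage <- function(annual, workdays_per_year = 220,
                            hours_per_day = 8, exchange_rate = NULL) {
  if (any(annual < 0)) abort("Annual salary must be non-negative.")
  w <- annual / (workdays_per_year * hours_per_day * 60)
  if (!is.null(exchange_rate)) w <- w / exchange_rate
  w
}

#' @rdname per_minute_wage
#' @export
szl_per_usd <- function() 13.234

#' Cadre salary schedule
#'
#' Per-minute wage triples (low, mid, high salary level) per HCW cadre.  The
#' mid wage is the cadre's average salary level and prices point estimates;
#' the low/high levels drive uncertainty-interval bounds only.  Cadres with a
#' single salary level have `low = mid = high`.
#'
#' @param wages data.frame with columns `cadre`, `wage_low`, `wage_mid`,
#'   `wage_high` (currency per minute).
#' @param currency currency tag, informational.
#' @return object of class `salary_schedule`.
#' @export
salary_schedule <- function(wages, currency = "USD") {
  stopifnot(all(c("cadre", "wage_low", "wage_mid", "wage_high") %in%
                  names(wages)))
  bad <- setdiff(wages$cadre, hcw_cadres())
  if (length(bad) > 0) {
    abort(paste0("Unknown cadre(s) in salary schedule: ",
                 paste(bad, collapse = ", ")))
  }
  with(wages, stopifnot(all(wage_low >= 0), all(wage_low <= wage_mid),
                        all(wage_mid <= wage_high)))
  structure(list(wages = as_tibble(wages), currency = currency),
            class = "salary_schedule")
}

#' @rdname salary_schedule
#' @param schedule a `salary_schedule`.
#' @param cadre a cadre code.
#' @return `cadre_wages()`: named numeric `c(low, mid, high)`.
#' @export
cadre_wages <- function(schedule, cadre) {
  stopifnot(inherits(schedule, "salary_schedule"))
  row <- schedule$wages[schedule$wages$cadre == cadre, ]
  if (nrow(row) != 1) abort(paste0("Cadre not in salary schedule: ", cadre))
  c(low = row$wage_low, mid = row$wage_mid, high = row$wage_high)
}

#' @export
print.salary_schedule <- function(x, ...) {
  cat("Salary schedule (", x$currency, " per minute)\n", sep = "")
  print(as.data.frame(x$wages), digits = 3)
  invisible(x)
}

#' Cost intervals
#'
#' A point cost with asymmetric uncertainty bounds.  Constructed costs carry
#' `ui_low >= 0`; differences may have negative bounds (savings can be
#' negative).
#'
#' @param point,ui_low,ui_high numeric scalars, `ui_low <= ui_high`.
#' @return object of class `cost_interval`.
#' @export
cost_interval <- function(point, ui_low, ui_high) {
  stopifnot(length(point) == 1, ui_low <= ui_high + 1e-12)
  structure(list(point = point, ui_low = ui_low, ui_high = ui_high),
            class = "cost_interval")
}

#' @export
print.cost_interval <- function(x, ...) {
  cat(format_cost(x$point), " [UI ", format_cost(x$ui_low), "-",
      format_cost(x$ui_high), "]\n", sep = "")
  invisible(x)
}

#' Format a currency value the way the cost tables print it
#'
#' Values of at least 0.10 are printed to 2 decimals, smaller values to 2
#' significant figures (so 0.042 and 0.086 keep their precision).  Internal
#' computation is always at full precision; rounding happens only here.
#'
#' @param x numeric vector.
#' @return character vector.
#' @export
format_cost <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (abs(v) >= 0.10) sprintf("%.2f", v) else format(signif(v, 2))
  }, character(1))
}

#' @rdname format_cost
#' @details `round_cost()` returns the numeric value at the same precision
#'   (2 decimals at or above 0.10, 2 significant figures below).
#' @export
round_cost <- function(x) {
  ifelse(abs(x) >= 0.10, round(x, 2), signif(x, 2))
}

#' Value a time estimate with a cadre's wages
#'
#' The point time estimate is priced at the cadre's mid (average) wage; the
#' UI prices the upper CI bound at the high wage and the lower CI bound at
#' the low wage, floored at zero.
#'
#' @param minutes point estimate of the time need (minutes).
#' @param ci_low,ci_high 95% CI bounds of the time need (minutes; `ci_low`
#'   may be negative).
#' @param cadre cadre code.
#' @param schedule a [salary_schedule()].
#' @return a [cost_interval()].
#' @export
time_cost <- function(minutes, ci_low, ci_high, cadre, schedule) {
  stopifnot(ci_low <= ci_high)
  w <- cadre_wages(schedule, cadre)
  cost_interval(
    point = minutes * w[["mid"]],
    ui_low = max(0, ci_low * w[["low"]]),
    ui_high = ci_high * w[["high"]]
  )
}

#' Interval arithmetic on cost intervals
#'
#' `interval_sum()` adds points and bounds componentwise (the extreme values
#' attainable within the component UIs).  `interval_diff()` subtracts points
#' and takes `a.ui_low - b.ui_high` / `a.ui_high - b.ui_low` as bounds; no
#' zero flooring, since differences (savings) may legitimately be negative.
#'
#' @param intervals a list of `cost_interval` objects (or several passed via
#'   `...`).
#' @return a `cost_interval`.
#' @export
interval_sum <- function(intervals, ...) {
  if (inherits(intervals, "cost_interval")) {
    intervals <- c(list(intervals), list(...))
  }
  stopifnot(length(intervals) >= 1,
            all(vapply(intervals, inherits, logical(1), "cost_interval")))
  cost_interval(
    point = sum(vapply(intervals, `[[`, numeric(1), "point")),
    ui_low = sum(vapply(intervals, `[[`, numeric(1), "ui_low")),
    ui_high = sum(vapply(intervals, `[[`, numeric(1), "ui_high"))
  )
}

#' @rdname interval_sum
#' @param a,b `cost_interval` objects.
#' @export
interval_diff <- function(a, b) {
  stopifnot(inherits(a, "cost_interval"), inherits(b, "cost_interval"))
  cost_interval(
    point = a$point - b$point,
    ui_low = a$ui_low - b$ui_high,
    ui_high = a$ui_high - b$ui_low
  )
}

#' Cost of a predicted clinic visit for one cadre
#'
#' Predicts the visit duration (point and CI) under the fit and values it
#' with the cadre's wage triple via [time_cost()].
#'
#' @param fit a `decomposition_fit`.
#' @param cadre cadre code.
#' @param schedule a [salary_schedule()].
#' @param activities activity set of the visit; defaults to the full set of
#'   the visit class.
#' @param visit_class `"INITIATION_VISIT"` or `"FOLLOWUP_VISIT"`; used when
#'   `activities` is not given.
#' @param interrupted passed to [predict_visit()].
#' @return a [cost_interval()].
#' @export
visit_cost <- function(fit, cadre, schedule,
                       activities = NULL,
                       visit_class = c("INITIATION_VISIT", "FOLLOWUP_VISIT"),
                       interrupted = FALSE) {
  if (is.null(activities)) {
    visit_class <- match.arg(visit_class)
    activities <- if (visit_class == "INITIATION_VISIT") {
      initiation_activities()
    } else {
      followup_activities()
    }
  }
  pred <- predict_visit(fit, activities, interrupted = interrupted)
  time_cost(pred$expected_minutes, pred$ci_low, pred$ci_high, cadre, schedule)
}

#' Cost matrix across activities and cadres
#'
#' Values the fixed time cost and every activity's estimated time need at
#' each cadre's wages, one row per (component, cadre).  Cadres unlikely to
#' provide an activity can be excluded via `assignable`.
#'
#' @param fit a `decomposition_fit` whose terms include the activities.
#' @param schedule a [salary_schedule()].
#' @param assignable optional named list activity -> character vector of
#'   cadres that may provide it (others are skipped).
#' @return tibble with columns `component`, `cadre`, `minutes`, `ci_low`,
#'   `ci_high`, `cost`, `ui_low`, `ui_high`.
#' @export
cost_matrix <- function(fit, schedule, assignable = NULL) {
  comps <- fit$ci[fit$ci$term %in% c("constant", prep_activities()), ]
  rows <- list()
  for (i in seq_len(nrow(comps))) {
    term <- comps$term[i]
    cads <- schedule$wages$cadre
    if (!is.null(assignable) && term %in% names(assignable)) {
      cads <- intersect(cads, assignable[[term]])
    }
    for (cd in cads) {
      ci <- time_cost(comps$estimate[i], comps$ci_low[i], comps$ci_high[i],
                      cd, schedule)
      rows[[length(rows) + 1]] <- tibble(
        component = term, cadre = cd,
        minutes = comps$estimate[i],
        ci_low = comps$ci_low[i], ci_high = comps$ci_high[i],
        cost = ci$point, ui_low = ci$ui_low, ui_high = ci$ui_high
      )
    }
  }
  bind_rows(rows)
}
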