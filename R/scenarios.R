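# Task-shifting scenario engine.
#
# A scenario assigns each PrEP activity to an HCW cadre.  Activity time is
# valued at the assigned cadre's average wage.  Non-activity time (the fixed
# time cost, the activity-count adjustment and any interruption penalty) is
# not assigned to anyone: it is valued at both the lowest and the highest
# average wage among the involved cadres, giving a per-visit cost *range*
# rather than a point when several cadres share a visit.  Task sharing
# between cadres interrupts the workflow, which adds the interruption
# coefficient to the visit's time need.

#' Define a task-shifting scenario
#'
#' @param name scenario label.
#' @param assignment named character vector mapping every activity code in
#'   [prep_activities()] to a cadre code.
#' @param interrupted `NULL` to derive the interruption status per visit
#'   class (interrupted iff at least two distinct cadres are involved in that
#'   class's activities), or a logical override.
#' @return object of class `scenario`.
#' @export
scenario <- function(name, assignment, interrupted = NULL) {
  missing <- setdiff(prep_activities(), names(assignment))
  if (length(missing) > 0) {
    abort(paste0("Scenario '", name, "' leaves activity/ies unassigned: ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unname(assignment), hcw_cadres())
  if (length(bad) > 0) {
    abort(paste0("Scenario '", name, "' assigns unknown cadre(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(name = name,
                 assignment = assignment[prep_activities()],
                 interrupted = interrupted),
            class = "scenario")
}

#' @rdname scenario
#' @details `base_case_scenario()` assigns every activity to a nurse with an
#'   uninterrupted workflow — the costing base case.
#' @export
base_case_scenario <- function() {
  scenario("Base case",
           setNames(rep("NURSE", 6), prep_activities()),
           interrupted = FALSE)
}

#' Built-in task-shifting scenario catalogue
#'
#' The base case plus five scenarios: (1) all activities shifted up to a
#' nursing sister; (2) counselling and risk assessment shared with an HTS
#' counselor and blood testing with a phlebotomist; (3) as 2 but blood
#' testing by the HTS counselor; (4) as 3 with follow-up counselling by a
#' nurse assistant; (5) as 4 with pre-PrEP counselling and risk assessment
#' by a peer supporter.  Scenarios 2-5 share tasks between cadres and hence
#' run interrupted; 1 is a full shift and stays uninterrupted.
#'
#' @return named list of [scenario()] objects.
#' @export
scenario_catalog <- function() {
  asg <- function(pre, risk, screen, init, fu, blood) {
    setNames(c(pre, risk, screen, init, fu, blood), prep_activities())
  }
  list(
    base = base_case_scenario(),
    scenario_1 = scenario(
      "Scenario 1", asg("NURSING_SISTER", "NURSING_SISTER", "NURSING_SISTER",
                        "NURSING_SISTER", "NURSING_SISTER", "NURSING_SISTER"),
      interrupted = FALSE),
    scenario_2 = scenario(
      "Scenario 2", asg("HTS_COUNSELOR", "HTS_COUNSELOR", "NURSE", "NURSE",
                        "NURSE", "PHLEBOTOMIST")),
    scenario_3 = scenario(
      "Scenario 3", asg("HTS_COUNSELOR", "HTS_COUNSELOR", "NURSE", "NURSE",
                        "NURSE", "HTS_COUNSELOR")),
    scenario_4 = scenario(
      "Scenario 4", asg("HTS_COUNSELOR", "HTS_COUNSELOR", "NURSE", "NURSE",
                        "NURSE_ASSISTANT", "HTS_COUNSELOR")),
    scenario_5 = scenario(
      "Scenario 5", asg("PEER_SUPPORTER", "PEER_SUPPORTER", "NURSE", "NURSE",
                        "NURSE_ASSISTANT", "HTS_COUNSELOR"))
  )
}

class_activities <- function(visit_class) {
  if (visit_class == "INITIATION_VISIT") initiation_activities()
  else followup_activities()
}

scenario_interrupted <- function(scn, cadres_involved) {
  if (!is.null(scn$interrupted)) scn$interrupted
  else length(unique(cadres_involved)) >= 2
}

# CI of the non-activity time: constant + n_activities * count term +
# interruption term, from the fit's covariance.
overhead_time <- function(fit, n_acts, interrupted) {
  terms <- names(fit$coefficients)
  cvec <- setNames(numeric(length(terms)), terms)
  cvec["constant"] <- 1
  if ("n_activities" %in% terms) cvec["n_activities"] <- n_acts
  if (interrupted) {
    if (!"interrupted" %in% terms) {
      abort("Fit has no interruption term; use a Model-2-shaped fit.")
    }
    cvec["interrupted"] <- 1
  }
  point <- sum(cvec * fit$coefficients)
  v <- drop(t(cvec) %*% fit$vcov %*% cvec)
  tq <- qt(1 - (1 - fit$level) / 2, fit$df_residual)
  c(point = point, ci_low = point - tq * sqrt(v),
    ci_high = point + tq * sqrt(v))
}

#' Evaluate a task-shifting scenario
#'
#' For one visit class, values each activity's estimated time at its assigned
#' cadre's average wage, and the non-activity time (fixed time cost +
#' activity-count adjustment + interruption penalty, when the workflow is
#' interrupted) at the lowest and highest average wage among the involved
#' cadres — yielding a cost point range (degenerate for single-cadre
#' scenarios).  The uncertainty interval sums, per component, the CI bounds
#' valued at the relevant cadres' extreme salary levels, with lower bounds
#' floored at zero.
#'
#' @param scn a [scenario()].
#' @param fit a `decomposition_fit` with `n_activities` and `interrupted`
#'   terms.
#' @param schedule a [salary_schedule()].
#' @param visit_class `"INITIATION_VISIT"` or `"FOLLOWUP_VISIT"`.
#' @return object of class `scenario_result`: list with `scenario`,
#'   `visit_class`, `interrupted`, `cadres`, `point_low`, `point_high`,
#'   `ui_low`, `ui_high`, `minutes` (point time need of the visit).
#' @export
evaluate_scenario <- function(scn, fit, schedule,
                              visit_class = c("INITIATION_VISIT",
                                              "FOLLOWUP_VISIT")) {
  stopifnot(inherits(scn, "scenario"), inherits(fit, "decomposition_fit"))
  visit_class <- match.arg(visit_class)
  acts <- class_activities(visit_class)
  bad <- setdiff(acts, names(fit$coefficients))
  if (length(bad) > 0) {
    abort(paste0("Fit lacks activity term(s): ", paste(bad, collapse = ", ")))
  }
  assignment <- scn$assignment[acts]
  cadres_involved <- unique(unname(assignment))
  interrupted <- scenario_interrupted(scn, cadres_involved)

  est <- fit$ci[match(acts, fit$ci$term), ]
  wages <- lapply(assignment, cadre_wages, schedule = schedule)
  act_cost <- sum(est$estimate * vapply(wages, `[[`, numeric(1), "mid"))
  act_ui_low <- sum(pmax(0, est$ci_low *
                           vapply(wages, `[[`, numeric(1), "low")))
  act_ui_high <- sum(est$ci_high * vapply(wages, `[[`, numeric(1), "high"))

  oh <- overhead_time(fit, length(acts), interrupted)
  mids <- vapply(cadres_involved, function(cd)
    cadre_wages(schedule, cd)[["mid"]], numeric(1))
  lows <- vapply(cadres_involved, function(cd)
    cadre_wages(schedule, cd)[["low"]], numeric(1))
  highs <- vapply(cadres_involved, function(cd)
    cadre_wages(schedule, cd)[["high"]], numeric(1))

  structure(list(
    scenario = scn$name,
    visit_class = visit_class,
    interrupted = interrupted,
    cadres = cadres_involved,
    minutes = sum(est$estimate) + oh[["point"]],
    point_low = act_cost + oh[["point"]] * min(mids),
    point_high = act_cost + oh[["point"]] * max(mids),
    ui_low = act_ui_low + max(0, oh[["ci_low"]] * min(lows)),
    ui_high = act_ui_high + oh[["ci_high"]] * max(highs)
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  rng <- if (abs(x$point_high - x$point_low) < 1e-9) {
    format_cost(x$point_low)
  } else {
    paste0(format_cost(x$point_low), "-", format_cost(x$point_high))
  }
  cat(x$scenario, " (", x$visit_class, if (x$interrupted) ", interrupted",
      "): ", rng, " [UI ", format_cost(x$ui_low), "-",
      format_cost(x$ui_high), "]\n", sep = "")
  invisible(x)
}

#' Cost of a workflow interruption
#'
#' Values the interruption coefficient across all cadres of the schedule:
#' the point range spans the lowest to the highest average per-minute wage;
#' the UI values the CI bounds at the extreme salary levels, floored at
#' zero.
#'
#' @inheritParams evaluate_scenario
#' @return tibble with `minutes`, `ci_low`, `ci_high` (time scale) and
#'   `cost_low`, `cost_high`, `ui_low`, `ui_high` (currency scale).
#' @export
interruption_cost <- function(fit, schedule) {
  if (!"interrupted" %in% names(fit$coefficients)) {
    abort("Fit has no interruption term.")
  }
  est <- fit$ci[fit$ci$term == "interrupted", ]
  w <- schedule$wages
  tibble(
    minutes = est$estimate, ci_low = est$ci_low, ci_high = est$ci_high,
    cost_low = est$estimate * min(w$wage_mid),
    cost_high = est$estimate * max(w$wage_mid),
    ui_low = max(0, est$ci_low * min(w$wage_low)),
    ui_high = est$ci_high * max(w$wage_high)
  )
}

#' Savings of a scenario against the base case
#'
#' Point savings are the range induced by the two cost ranges (base minus
#' scenario, crosswise); UI bounds follow [interval_diff()] and may be
#' negative — task sharing can cost more than the base case.
#'
#' @param base,result `scenario_result` objects for the same visit class and
#'   fit.
#' @return tibble with `savings_low`, `savings_high`, `ui_low`, `ui_high`.
#' @export
savings_vs_base <- function(result, base) {
  stopifnot(inherits(result, "scenario_result"),
            inherits(base, "scenario_result"))
  if (result$visit_class != base$visit_class) {
    abort("Scenario and base case evaluate different visit classes.")
  }
  d <- interval_diff(
    cost_interval((base$point_low + base$point_high) / 2,
                  base$ui_low, base$ui_high),
    cost_interval((result$point_low + result$point_high) / 2,
                  result$ui_low, result$ui_high)
  )
  tibble(
    savings_low = base$point_low - result$point_high,
    savings_high = base$point_high - result$point_low,
    ui_low = d$ui_low, ui_high = d$ui_high
  )
}

#' Nurse worktime freed by a scenario
#'
#' Minutes per visit moved off the nurse, as a range over how the
#' non-activity time is apportioned.  Shifted activity time is the sum of the
#' shifted activities' coefficients plus their share of the activity-count
#' adjustment.  At the lower end the nurse keeps all non-activity time and
#' absorbs the interruption penalty that task sharing induces; at the upper
#' end the fixed time cost moves off the nurse as well and no penalty is
#' charged.  CIs come from the corresponding linear combinations of
#' coefficients.
#'
#' @inheritParams evaluate_scenario
#' @return tibble with `lower`, `lower_ci_low`, `lower_ci_high`, `upper`,
#'   `upper_ci_low`, `upper_ci_high`, `n_shifted`.
#' @export
freed_nurse_time <- function(scn, fit,
                             visit_class = c("INITIATION_VISIT",
                                             "FOLLOWUP_VISIT")) {
  stopifnot(inherits(scn, "scenario"))
  visit_class <- match.arg(visit_class)
  acts <- class_activities(visit_class)
  assignment <- scn$assignment[acts]
  shifted <- acts[assignment != "NURSE"]
  interrupted <- scenario_interrupted(scn, unique(unname(assignment)))
  terms <- names(fit$coefficients)
  tq <- qt(1 - (1 - fit$level) / 2, fit$df_residual)
  lincomb <- function(cvec) {
    point <- sum(cvec * fit$coefficients)
    v <- drop(t(cvec) %*% fit$vcov %*% cvec)
    c(point, point - tq * sqrt(v), point + tq * sqrt(v))
  }
  base_c <- setNames(numeric(length(terms)), terms)
  base_c[shifted] <- 1
  if ("n_activities" %in% terms) base_c["n_activities"] <- length(shifted)
  lower_c <- base_c
  if (interrupted && length(shifted) > 0) {
    if (!"interrupted" %in% terms) {
      abort("Fit has no interruption term; use a Model-2-shaped fit.")
    }
    lower_c["interrupted"] <- -1
  }
  upper_c <- base_c
  if (length(shifted) > 0) upper_c["constant"] <- 1
  lo <- lincomb(lower_c)
  hi <- lincomb(upper_c)
  tibble(
    lower = lo[1], lower_ci_low = lo[2], lower_ci_high = lo[3],
    upper = hi[1], upper_ci_low = hi[2], upper_ci_high = hi[3],
    n_shifted = length(shifted)
  )
}

#' Scenario summary table
#'
#' Evaluates every scenario of a catalogue for both visit classes, with
#' savings against the base case and freed nurse time.
#'
#' @param fit a Model-2-shaped `decomposition_fit`.
#' @param schedule a [salary_schedule()].
#' @param scenarios named list of scenarios; the element named `base` is the
#'   comparator.
#' @param classes visit classes to evaluate.
#' @return tibble, one row per (scenario, visit class).
#' @export
scenario_table <- function(fit, schedule, scenarios = scenario_catalog(),
                           classes = c("INITIATION_VISIT",
                                       "FOLLOWUP_VISIT")) {
  stopifnot("base" %in% names(scenarios))
  rows <- list()
  for (vc in classes) {
    base <- evaluate_scenario(scenarios$base, fit, schedule, vc)
    for (nm in names(scenarios)) {
      res <- evaluate_scenario(scenarios[[nm]], fit, schedule, vc)
      sav <- savings_vs_base(res, base)
      freed <- freed_nurse_time(scenarios[[nm]], fit, vc)
      rows[[length(rows) + 1]] <- tibble(
        scenario = scenarios[[nm]]$name,
        visit_class = vc,
        interrupted = res$interrupted,
        minutes = res$minutes,
        cost_low = res$point_low, cost_high = res$point_high,
        ui_low = res$ui_low, ui_high = res$ui_high,
        savings_low = sav$savings_low, savings_high = sav$savings_high,
        savings_ui_low = sav$ui_low, savings_ui_high = sav$ui_high,
        freed_minutes_low = freed$lower, freed_minutes_high = freed$upper
      )
    }
  }
  bind_rows(rows)
}
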