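# Published reference inputs from the Eswatini nurse-led PrEP demonstration
# project (six primary care clinics, 2017-2019): regression point estimates
# with 95% CIs for the two selected model specifications, and the 2018
# per-minute government salary schedule in USD.  These printed estimates are
# inputs for prediction, costing and scenario analysis when the underlying
# records are not available.

#' Published Eswatini reference estimates and salaries
#'
#' `eswatini_estimates()` returns the published activity-time decomposition
#' estimates (minutes, with 95% CI bounds) for the activities-plus-constant
#' specification (`"model1"`) or the specification that adds the activity
#' count and workflow-interruption terms (`"model2"`).
#' `eswatini_reference_fit()` wraps them in a [fit_from_estimates()] object
#' (n = 284 activity sequences); `eswatini_salaries()` returns the 2018
#' per-minute USD salary schedule of the six HCW cadres as a
#' [salary_schedule()].
#'
#' @param model `"model1"` or `"model2"`.
#' @return A tibble, `decomposition_fit`, or `salary_schedule`.
#' @export
#' @examples
#' fit <- eswatini_reference_fit("model1")
#' predict_visit(fit, initiation_activities())
eswatini_estimates <- function(model = c("model1", "model2")) {
  model <- match.arg(model)
  path <- system.file("extdata", paste0("eswatini_", model, ".csv"),
                      package = "prepshift", mustWork = TRUE)
  readr::read_csv(path, col_types = "cddd", progress = FALSE)
}

#' @rdname eswatini_estimates
#' @param n number of activity sequences behind the estimates.
#' @export
eswatini_reference_fit <- function(model = c("model1", "model2"), n = 284) {
  est <- eswatini_estimates(model)
  fit_from_estimates(est, n = n)
}

#' @rdname eswatini_estimates
#' @export
eswatini_salaries <- function() {
  path <- system.file("extdata", "eswatini_salaries.csv",
                      package = "prepshift", mustWork = TRUE)
  salary_schedule(readr::read_csv(path, col_types = "cddd", progress = FALSE))
}
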