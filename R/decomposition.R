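# Regression decomposition of visit durations into activity-level time needs.
#
# Model 1: total PrEP minutes ~ activity indicators + constant.  The constant
# is the fixed time cost of a visit (time not attributable to any specific
# activity); each activity coefficient is the average extra time that activity
# adds.  Model 2 adds the number of provided activities and a workflow-
# interruption indicator.  Extended specifications add months of PrEP
# experience, a promotion-package flag, nurse involvement and clinic fixed
# effects.

#' Model specification for the time decomposition
#'
#' @param model `"1"` (activities + constant), `"2"` (adds activity count and
#'   interruption), or `"ext"` (builds on Model 2; enable extras via the
#'   flags).
#' @param n_activities,interruption,experience,promotion,nurse_involved,clinic_fe
#'   logical switches for the individual covariates; defaults follow `model`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = c("1", "2", "ext"),
                       n_activities = NULL, interruption = NULL,
                       experience = NULL, promotion = NULL,
                       nurse_involved = NULL, clinic_fe = NULL) {
  model <- match.arg(model)
  base2 <- model %in% c("2", "ext")
  spec <- list(
    model = model,
    n_activities = if (is.null(n_activities)) base2 else n_activities,
    interruption = if (is.null(interruption)) base2 else interruption,
    experience = if (is.null(experience)) model == "ext" else experience,
    promotion = if (is.null(promotion)) FALSE else promotion,
    nurse_involved = if (is.null(nurse_involved)) FALSE else nurse_involved,
    clinic_fe = if (is.null(clinic_fe)) FALSE else clinic_fe
  )
  structure(spec, class = "model_spec")
}

#' Build the response and design matrix for a decomposition fit
#'
#' One row per visit.  The response is the visit's total PrEP minutes.  The
#' design holds a constant column, an indicator per PrEP activity present,
#' and the covariates the specification enables: the recorded-activity count
#' (`n_activity_entries`; see [build_visits()]), the
#' interruption indicator, months since the clinic's PrEP introduction, the
#' promotion-package flag, nurse involvement, and clinic indicators with the
#' lexicographically first clinic as reference.
#'
#' @param visits visit tibble from [build_visits()] (or the synthetic
#'   generator's truth ledger).
#' @param spec a [model_spec()].
#' @param promotion_dates named Date vector (clinic id -> introduction date of
#'   the promotion package), required when `spec$promotion` is on.
#' @return list with `y` (response vector), `X` (design matrix with named
#'   columns, constant first).
#' @export
build_design <- function(visits, spec = model_spec("1"),
                         promotion_dates = NULL) {
  stopifnot(inherits(spec, "model_spec"), nrow(visits) >= 1)
  y <- visits$total_prep_minutes
  acts <- prep_activities()
  X <- matrix(0, nrow(visits), length(acts),
              dimnames = list(NULL, acts))
  for (i in seq_len(nrow(visits))) {
    X[i, visits$activities[[i]]] <- 1
  }
  X <- cbind(constant = 1, X)
  if (spec$n_activities) {
    # the count of *recorded* activity entries (duplicates across forms
    # counted), not the set cardinality: the cardinality equals the sum of
    # the activity indicators row-wise and would make the design singular
    cnt <- if ("n_activity_entries" %in% names(visits)) {
      visits$n_activity_entries
    } else {
      lengths(visits$activities)
    }
    X <- cbind(X, n_activities = cnt)
  }
  if (spec$interruption) {
    X <- cbind(X, interrupted = as.numeric(visits$interrupted))
  }
  if (spec$experience) {
    X <- cbind(X, months_experience = visits$months_since_prep_start)
  }
  if (spec$promotion) {
    if (is.null(promotion_dates)) {
      abort("spec includes the promotion flag but no promotion_dates given.")
    }
    X <- cbind(X, promotion = as.numeric(
      visits$visit_date >= promotion_dates[visits$clinic_id]))
  }
  if (spec$nurse_involved) {
    X <- cbind(X, nurse_involved = vapply(
      visits$cadres,
      function(cd) as.numeric(any(cd %in% c("NURSE", "NURSING_SISTER"))),
      numeric(1)))
  }
  if (spec$clinic_fe) {
    clinics <- sort(unique(visits$clinic_id))
    for (cl in clinics[-1]) {
      col <- matrix(as.numeric(visits$clinic_id == cl), ncol = 1,
                    dimnames = list(NULL, paste0("clinic_", cl)))
      X <- cbind(X, col)
    }
  }
  # all-zero activity columns (activity never observed) are dropped rather
  # than reported as collinear with nothing
  keep <- colnames(X) == "constant" | colSums(abs(X)) > 0
  X <- X[, keep, drop = FALSE]
  list(y = y, X = X, spec = spec)
}

check_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(qx)
}

#' Ordinary least squares fit of a time decomposition
#'
#' Fits the linear decomposition by OLS and returns coefficient estimates
#' with classical (homoskedastic) covariance \eqn{\hat\sigma^2 (X'X)^{-1}},
#' 95% confidence intervals from the t distribution with `n - k` degrees of
#' freedom, adjusted R-squared, and Gaussian-likelihood AIC/BIC (including
#' the `2*pi` constant, so absolute values are comparable across software).
#' Heteroskedasticity-robust (HC1) intervals are available via `robust`.
#'
#' @param X design matrix from [build_design()] (constant column first) or
#'   any full-rank numeric matrix with named columns.
#' @param y numeric response vector.
#' @param robust use HC1 sandwich covariance instead of the classical one.
#' @param level confidence level for the intervals.
#' @return An object of class `decomposition_fit`: a list with `coefficients`
#'   (named vector, minutes), `vcov`, `ci` (tibble: term, estimate, se,
#'   ci_low, ci_high, p_value), `n`, `k`, `df_residual`, `rss`, `sigma2`,
#'   `adj_r2`, `aic`, `bic`, `spec`, `level`.
#' @export
fit_ols <- function(X, y, robust = FALSE, level = 0.95) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  n <- nrow(X); k <- ncol(X)
  if (n <= k) abort(paste0("Need n > k to fit: n = ", n, ", k = ", k, "."))
  check_rank(X)
  has_const <- "constant" %in% colnames(X)
  d <- as.data.frame(X[, setdiff(colnames(X), "constant"), drop = FALSE])
  d$.y <- y
  fml <- if (has_const) .y ~ . else .y ~ 0 + .
  fit <- lm(fml, data = d)
  cf <- coef(fit)
  names(cf)[names(cf) == "(Intercept)"] <- "constant"
  cf <- cf[match(colnames(X), names(cf))]
  V <- if (robust) sandwich::vcovHC(fit, type = "HC1") else vcov(fit)
  dimnames(V) <- list(names(coef(fit)), names(coef(fit)))
  rownames(V)[rownames(V) == "(Intercept)"] <- "constant"
  colnames(V)[colnames(V) == "(Intercept)"] <- "constant"
  V <- V[names(cf), names(cf)]
  se <- sqrt(diag(V))
  df <- n - k
  tq <- qt(1 - (1 - level) / 2, df)
  rss <- sum(fit$residuals^2)
  structure(list(
    coefficients = cf,
    vcov = V,
    ci = tibble(
      term = names(cf),
      estimate = unname(cf),
      se = unname(se),
      ci_low = unname(cf - tq * se),
      ci_high = unname(cf + tq * se),
      p_value = unname(2 * pt(abs(cf / se), df, lower.tail = FALSE))
    ),
    n = n, k = k, df_residual = df,
    rss = rss, sigma2 = rss / df,
    adj_r2 = summary(fit)$adj.r.squared,
    aic = AIC(fit), bic = BIC(fit),
    spec = NULL, level = level, robust = robust,
    approx_cov = FALSE
  ), class = "decomposition_fit")
}

#' @rdname fit_ols
#' @param visits visit tibble.
#' @param spec a [model_spec()].
#' @param ... passed on to [build_design()] and [fit_ols()].
#' @export
fit_decomposition <- function(visits, spec = model_spec("1"), ...) {
  dots <- list(...)
  design <- build_design(visits, spec,
                         promotion_dates = dots$promotion_dates)
  fit <- fit_ols(design$X, design$y,
                 robust = isTRUE(dots$robust),
                 level = if (is.null(dots$level)) 0.95 else dots$level)
  fit$spec <- spec
  fit
}

#' @export
print.decomposition_fit <- function(x, ...) {
  cat("Time decomposition fit (", x$k, " terms, n = ", x$n, ")\n", sep = "")
  print(as.data.frame(x$ci), digits = 3)
  cat(sprintf("adj R2 %.3f  AIC %.1f  BIC %.1f\n", x$adj_r2, x$aic, x$bic))
  invisible(x)
}

#' Build a fit object from published coefficient estimates
#'
#' Constructs a `decomposition_fit` from a table of point estimates and 95%
#' confidence bounds (e.g. published regression results), for use with
#' [predict_visit()] and the costing functions when the underlying records
#' are not at hand.  The covariance is diagonal, implied by the printed CI
#' widths (`se = width / (2 t)`), so point predictions are exact while
#' propagated interval widths are approximate (correlations between
#' coefficients are not published).
#'
#' @param estimates tibble/data.frame with columns `term`, `estimate`,
#'   `ci_low`, `ci_high`.
#' @param n number of observations behind the estimates.
#' @param level confidence level of the supplied bounds.
#' @return A `decomposition_fit` with `approx_cov = TRUE`.
#' @export
fit_from_estimates <- function(estimates, n, level = 0.95) {
  stopifnot(all(c("term", "estimate", "ci_low", "ci_high") %in%
                  names(estimates)))
  k <- nrow(estimates)
  df <- n - k
  tq <- qt(1 - (1 - level) / 2, df)
  cf <- setNames(estimates$estimate, estimates$term)
  se <- (estimates$ci_high - estimates$ci_low) / (2 * tq)
  V <- diag(se^2, nrow = k)
  dimnames(V) <- list(estimates$term, estimates$term)
  structure(list(
    coefficients = cf, vcov = V,
    ci = tibble(term = estimates$term, estimate = estimates$estimate,
                se = se, ci_low = estimates$ci_low,
                ci_high = estimates$ci_high, p_value = NA_real_),
    n = n, k = k, df_residual = df,
    rss = NA_real_, sigma2 = NA_real_, adj_r2 = NA_real_,
    aic = NA_real_, bic = NA_real_,
    spec = NULL, level = level, robust = FALSE,
    approx_cov = TRUE
  ), class = "decomposition_fit")
}

#' Rank candidate model fits by BIC
#'
#' Orders fits of the same response by ascending Bayesian information
#' criterion (the selection rule used throughout the package); AIC is
#' reported alongside.
#'
#' @param ... `decomposition_fit` objects, or a single list of them.
#' @param names optional model labels.
#' @return tibble with one row per fit, ordered by `bic`.
#' @export
compare_models <- function(..., names = NULL) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "decomposition_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "decomposition_fit")))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1) {
    abort("Fits were estimated on different numbers of observations.")
  }
  if (is.null(names)) names <- paste0("model_", seq_along(fits))
  tibble(
    model = names,
    n = ns,
    k = vapply(fits, function(f) f$k, numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    adj_r2 = vapply(fits, function(f) f$adj_r2, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1))
  ) %>% arrange(.data$bic)
}

#' Predict the HCW time need of a clinic visit
#'
#' Expected visit duration for a given activity set under a fitted
#' decomposition: the constant plus the selected activity coefficients, plus
#' (when present in the fit) the activity-count term, the interruption term,
#' and any further covariates supplied.  The confidence interval comes from
#' the variance of the linear combination, `c' V c`, with the fit's
#' t quantile.
#'
#' @param fit a `decomposition_fit`.
#' @param activities character vector of activity codes.
#' @param interrupted logical; adds the interruption coefficient (error if the
#'   fit has none and `TRUE` is requested).
#' @param covariates named numeric vector of further term values (e.g.
#'   `c(months_experience = 6)`).
#' @param level confidence level; defaults to the fit's.
#' @return tibble with `expected_minutes`, `ci_low`, `ci_high`,
#'   `interrupted`.
#' @export
predict_visit <- function(fit, activities, interrupted = FALSE,
                          covariates = NULL, level = NULL) {
  stopifnot(inherits(fit, "decomposition_fit"))
  if (is.null(level)) level <- fit$level
  terms <- names(fit$coefficients)
  activities <- unique(activities)
  bad <- setdiff(activities, terms)
  if (length(bad) > 0) {
    abort(paste0("Fit has no term for activity/ies: ",
                 paste(bad, collapse = ", ")))
  }
  cvec <- setNames(numeric(length(terms)), terms)
  if ("constant" %in% terms) cvec["constant"] <- 1
  cvec[activities] <- 1
  if ("n_activities" %in% terms) cvec["n_activities"] <- length(activities)
  if (interrupted) {
    if (!"interrupted" %in% terms) {
      abort("Fit has no interruption term; cannot predict interrupted = TRUE.")
    }
    cvec["interrupted"] <- 1
  }
  if (!is.null(covariates)) {
    bad <- setdiff(names(covariates), terms)
    if (length(bad) > 0) {
      abort(paste0("Fit has no term(s): ", paste(bad, collapse = ", ")))
    }
    cvec[names(covariates)] <- covariates
  }
  point <- sum(cvec * fit$coefficients)
  v <- drop(t(cvec) %*% fit$vcov %*% cvec)
  tq <- qt(1 - (1 - level) / 2, fit$df_residual)
  tibble(
    expected_minutes = point,
    ci_low = point - tq * sqrt(v),
    ci_high = point + tq * sqrt(v),
    interrupted = interrupted
  )
}
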