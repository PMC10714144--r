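#' Ordinary least squares with standard diagnostics
#'
#' Least-squares fit with intercept; reports the coefficient table,
#' `R^2 = 1 - SSE/SST`, the overall F statistic with (k, n-k-1) degrees of
#' freedom and its p-value.
#'
#' @param y Response vector.
#' @param X data.frame (or matrix) of predictors.
#' @return List of class `regression_fit`: `coefficients` (matrix: estimate,
#'   se), `r_squared`, `F`, `df`, `p`, `n`, `predictors`, `fit` (the `lm`).
#' @export
ols <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n != nrow(X)) stop("y and X dimensions disagree")
  if (n <= ncol(X) + 1) stop("need n > predictors + 1")
  if (stats::var(y) == 0) stop("constant response: R^2 undefined")
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  k <- ncol(X)
  Fst <- sm$fstatistic
  structure(list(
    coefficients = stats::coef(sm)[, 1:2, drop = FALSE],
    r_squared = sm$r.squared,
    F = unname(Fst[1]), df = unname(Fst[2:3]),
    p = stats::pf(Fst[1], Fst[2], Fst[3], lower.tail = FALSE),
    n = n, predictors = colnames(X), fit = fit
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): %s\n", x$n, paste(x$predictors, collapse = " + ")))
  print(round(x$coefficients, 4))
  cat(sprintf("R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r_squared, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Whole-deployment calibration regressions
#'
#' Fits the three total-period calibrations: daily DLW energy expenditure on
#' mean VeDBA; total DLW energy on activity-predicted total energy; and
#' daily DLW energy on activity-predicted daily energy (the daily form
#' avoids the temporal bias of having sampling duration on both sides).
#'
#' @param energy Per-bird energy table with columns `DLW_DEE`,
#'   `VeDBA_mean_T`, `DLW_EE`, `Pred_EE`, `Pred_DEE`.
#' @return Named list of `regression_fit`: `dee_vedba`, `ee_pred`,
#'   `dee_pred`.
#' @export
calibrate_total <- function(energy) {
  energy <- as.data.frame(energy)
  if (nrow(energy) < 4) stop("need at least 4 birds")
  list(
    dee_vedba = ols(energy$DLW_DEE, data.frame(VeDBA_mean = energy$VeDBA_mean_T)),
    ee_pred = ols(energy$DLW_EE, data.frame(Pred_EE = energy$Pred_EE)),
    dee_pred = ols(energy$DLW_DEE, data.frame(Pred_DEE = energy$Pred_DEE))
  )
}

#' At-sea calibration regressions
#'
#' Fits daily at-sea energy expenditure from each subtraction method (S1:
#' activity-specific land costs; S2: published on-land constants) on mean
#' at-sea VeDBA. Birds flagged by S2 (estimated land energy at or above the
#' DLW total) are excluded listwise from the S2 regression only.
#'
#' @param energy Per-bird energy table with `DLW_DEE_S1`, `DLW_DEE_S2`,
#'   `VeDBA_mean_S` and optionally `S2_excluded`.
#' @return Named list of `regression_fit`: `s1_vedba` and (when S2 values
#'   are present) `s2_vedba`.
#' @export
calibrate_at_sea <- function(energy) {
  energy <- as.data.frame(energy)
  ok1 <- !is.na(energy$DLW_DEE_S1) & !is.na(energy$VeDBA_mean_S)
  out <- list(
    s1_vedba = ols(energy$DLW_DEE_S1[ok1],
                   data.frame(VeDBA_mean_S = energy$VeDBA_mean_S[ok1]))
  )
  if ("DLW_DEE_S2" %in% names(energy) && any(!is.na(energy$DLW_DEE_S2))) {
    keep <- !is.na(energy$DLW_DEE_S2) & !is.na(energy$VeDBA_mean_S)
    if ("S2_excluded" %in% names(energy)) keep <- keep & !energy$S2_excluded
    out$s2_vedba <- ols(energy$DLW_DEE_S2[keep],
                        data.frame(VeDBA_mean_S = energy$VeDBA_mean_S[keep]))
  }
  out
}

#' Stepwise (forward and backward) covariate selection
#'
#' Bidirectional AIC-based search starting from the VeDBA-only base model,
#' over candidate covariates likely to influence energy expenditure (total
#' distance travelled, dive rate, body mass, proportion of time at sea or --
#' for at-sea models -- proportion of at-sea time at night, tarsus length).
#' The VeDBA term is protected and never dropped (release it with
#' `protect_base = FALSE`).
#'
#' @param data data.frame holding response, base predictor and candidates.
#' @param response Name of the response column.
#' @param base Name of the always-present base predictor (the VeDBA term).
#' @param candidates Character vector of candidate covariate names.
#' @param protect_base Keep the base term in every model (default `TRUE`).
#' @return List of class `model_search`: `selected` (character), `fit`
#'   (`regression_fit` of the final model), `trace` (stepwise anova),
#'   `candidates`.
#' @export
stepwise_select <- function(data, response, base, candidates,
                            protect_base = TRUE) {
  data <- as.data.frame(data)
  miss <- setdiff(c(response, base, candidates), names(data))
  if (length(miss)) stop("columns missing from data: ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[, c(response, base, candidates)]),
               c(response, base, candidates)]
  f_base <- stats::as.formula(paste(response, "~", base))
  f_lower <- if (protect_base) f_base else stats::as.formula(paste(response, "~ 1"))
  f_upper <- stats::as.formula(paste(response, "~", paste(c(base, candidates),
                                                          collapse = " + ")))
  start <- stats::lm(f_base, data = data)
  sel <- MASS::stepAIC(start, scope = list(lower = f_lower, upper = f_upper),
                       direction = "both", trace = 0)
  selected <- attr(stats::terms(sel), "term.labels")
  fit <- ols(data[[response]], data[, selected, drop = FALSE])
  structure(list(selected = selected, fit = fit, trace = sel$anova,
                 candidates = candidates),
            class = "model_search")
}
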