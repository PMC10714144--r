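#' Assemble a per-bird predictor matrix from activity budgets
#'
#' @param budgets List of `activity_budget` objects (one per bird).
#' @param basis `"time"` (hours per behaviour, T_i) or `"vedba_sum"`
#'   (summed VeDBA per behaviour, g s).
#' @return Numeric matrix, birds x behaviours (columns in
#'   [behaviour_levels()] order).
#' @export
budget_matrix <- function(budgets, basis = c("time", "vedba_sum")) {
  basis <- match.arg(basis)
  col <- if (basis == "time") "T_h" else "vedba_sum"
  m <- t(vapply(budgets, function(b) {
    v <- b$table[[col]]
    names(v) <- as.character(b$table$behaviour)
    v[BEHAVIOURS]
  }, numeric(length(BEHAVIOURS))))
  colnames(m) <- BEHAVIOURS
  m
}

#' Fit activity-specific energy coefficients
#'
#' Multiple least-squares regression of total DLW energy expenditure on the
#' six activity-specific predictors with no intercept: a bird spending zero
#' time in every behaviour must expend zero energy, which is the additive
#' form of the time-activity energy model `EE = sum_i C_i T_i`. Under the
#' `time` basis, coefficients are energy rates in kJ h^-1; under the
#' `vedba_sum` basis they are kJ per unit summed VeDBA. Behaviours absent in
#' every bird give a rank-deficient design; the term is dropped with a
#' warning and its coefficient reported as `NA`.
#'
#' @param DLW_EE Per-bird total energy expenditure (kJ).
#' @param budgets Predictor matrix from [budget_matrix()], or a list of
#'   `activity_budget` objects.
#' @param basis Predictor basis, `"time"` or `"vedba_sum"`.
#' @param intercept Fit an intercept (sensitivity-analysis variant; default
#'   `FALSE`).
#' @return List of class `activity_coefficients`: `coefficients` (named, one
#'   per behaviour, `NA` if dropped), `se`, `r_squared`, `basis`, `fit` (the
#'   underlying `lm`).
#' @export
fit_activity_coefficients <- function(DLW_EE, budgets,
                                      basis = c("time", "vedba_sum"),
                                      intercept = FALSE) {
  basis <- match.arg(basis)
  X <- if (is.list(budgets) && !is.data.frame(budgets))
    budget_matrix(budgets, basis) else as.matrix(budgets)
  if (nrow(X) != length(DLW_EE)) stop("one budget row per bird required")
  if (length(DLW_EE) <= ncol(X))
    stop("need more birds than coefficients to fit the activity model")

  absent <- colSums(abs(X)) == 0
  if (any(absent)) {
    warning("behaviour(s) absent in all birds, dropped from the fit: ",
            paste(colnames(X)[absent], collapse = ", "))
  }
  Xf <- X[, !absent, drop = FALSE]
  dat <- data.frame(DLW_EE = DLW_EE, Xf, check.names = FALSE)
  fml <- if (intercept) DLW_EE ~ . else DLW_EE ~ 0 + .
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  cf <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  se <- cf
  est <- stats::coef(sm)
  keep <- rownames(est)[rownames(est) %in% colnames(X) |
                          paste0("`", colnames(X), "`") %in% rownames(est)]
  rn <- gsub("`", "", rownames(est))
  for (b in colnames(X)[!absent]) {
    i <- match(b, rn)
    if (!is.na(i)) { cf[b] <- est[i, 1]; se[b] <- est[i, 2] }
  }
  structure(list(coefficients = cf, se = se, r_squared = sm$r.squared,
                 basis = basis, fit = fit),
            class = "activity_coefficients")
}

#' Predict energy expenditure from an activity budget
#'
#' `Pred_EE = sum_i C_i T_i` (or `C_i * VeDBA_sum_i` under the vedba_sum
#' basis); `Pred_DEE` divides by the sampling duration in days. Dropped
#' (`NA`) coefficients contribute nothing.
#'
#' @param coeffs An `activity_coefficients` object.
#' @param budget An `activity_budget`, or a named numeric vector of
#'   predictor values per behaviour.
#' @param sampling_days Sampling duration (days) for the daily rate; taken
#'   from the budget when omitted.
#' @return List: `Pred_EE` (kJ), `Pred_DEE` (kJ day^-1).
#' @export
predict_ee <- function(coeffs, budget, sampling_days = NULL) {
  if (inherits(budget, "activity_budget")) {
    if (is.null(sampling_days)) sampling_days <- budget$deployment_h / 24
    v <- if (coeffs$basis == "time") budget$table$T_h else budget$table$vedba_sum
    names(v) <- as.character(budget$table$behaviour)
  } else {
    v <- budget
    if (is.null(sampling_days)) stop("sampling_days required with a bare vector")
  }
  cf <- coeffs$coefficients
  common <- intersect(names(cf)[!is.na(cf)], names(v))
  EE <- sum(cf[common] * v[common])
  list(Pred_EE = EE, Pred_DEE = EE / sampling_days)
}

#' At-sea energy by the activity-specific subtraction (method S1)
#'
#' The on-land energy estimated from the activity model (`C_land * T_land`)
#' is subtracted from the DLW total; the daily at-sea rate divides by the
#' time spent at sea. By construction, at-sea energy plus the estimated land
#' energy reconstructs the DLW total exactly.
#'
#' @param DLW_EE Total energy expenditure (kJ).
#' @param coeffs An `activity_coefficients` (time basis) providing `C_land`.
#' @param T_land_h Hours resting on land.
#' @param time_at_sea_h Hours at sea (> 0).
#' @return List: `DLW_EE_S1` (kJ), `DLW_DEE_S1` (kJ day^-1),
#'   `EE_land` (kJ).
#' @export
at_sea_s1 <- function(DLW_EE, coeffs, T_land_h, time_at_sea_h) {
  if (time_at_sea_h <= 0) stop("no time at sea: at-sea rate undefined")
  c_land <- coeffs$coefficients["rest_land"]
  if (is.na(c_land)) stop("land coefficient unavailable")
  EE_land <- unname(c_land) * T_land_h
  EE_S1 <- DLW_EE - EE_land
  list(DLW_EE_S1 = EE_S1, DLW_DEE_S1 = EE_S1 / (time_at_sea_h / 24),
       EE_land = EE_land)
}

#' At-sea energy using published on-land constants (method S2)
#'
#' On-land energy is `c_day * T_land_day + c_night * T_land_night` with
#' day/night metabolic constants taken from external literature (none are
#' bundled: both must be supplied explicitly). Birds whose estimated land
#' energy reaches the DLW total are flagged for listwise exclusion from S2
#' regressions.
#'
#' @param DLW_EE Total energy expenditure (kJ).
#' @param T_land_day_h,T_land_night_h Hours on land during day and night.
#' @param c_day,c_night On-land metabolic rates (kJ h^-1); required.
#' @param time_at_sea_h Hours at sea (> 0).
#' @return List: `DLW_EE_S2`, `DLW_DEE_S2`, `EE_land`, `excluded` (logical).
#' @export
at_sea_s2 <- function(DLW_EE, T_land_day_h, T_land_night_h,
                      c_day, c_night, time_at_sea_h) {
  if (missing(c_day) || missing(c_night) || is.null(c_day) || is.null(c_night))
    stop("c_day and c_night must be supplied: no published on-land constants are bundled")
  if (time_at_sea_h <= 0) stop("no time at sea: at-sea rate undefined")
  EE_land <- c_day * T_land_day_h + c_night * T_land_night_h
  EE_S2 <- DLW_EE - EE_land
  excluded <- EE_land >= DLW_EE
  list(DLW_EE_S2 = EE_S2, DLW_DEE_S2 = EE_S2 / (time_at_sea_h / 24),
       EE_land = EE_land, excluded = excluded)
}

#' Per-behaviour fits of estimated activity energy on summed VeDBA
#'
#' For each behaviour, regresses the per-bird estimated activity energy
#' (`C_i * T_i` from the fitted time-basis coefficients) on the per-bird
#' summed VeDBA within that behaviour, reporting slope, R^2, F and p.
#' Behaviours with zero predictor variance (or dropped coefficients) are
#' omitted.
#'
#' @param coeffs An `activity_coefficients` (time basis).
#' @param T_mat Birds x behaviours matrix of hours ([budget_matrix()], time).
#' @param V_mat Birds x behaviours matrix of summed VeDBA.
#' @return data.table: behaviour, slope, r_squared, F, df1, df2, p.
#' @export
activity_fit_table <- function(coeffs, T_mat, V_mat) {
  rows <- lapply(BEHAVIOURS, function(b) {
    cf <- coeffs$coefficients[b]
    if (is.na(cf)) return(NULL)
    y <- unname(cf) * T_mat[, b]
    x <- V_mat[, b]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NULL)
    f <- ols(y, data.frame(vedba_sum = x))
    data.table::data.table(behaviour = b, slope = f$coefficients["vedba_sum", 1],
                           r_squared = f$r_squared, F = f$F,
                           df1 = f$df[1], df2 = f$df[2], p = f$p)
  })
  data.table::rbindlist(rows)
}
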