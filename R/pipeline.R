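#' Simulate and process one complete deployment
#'
#' Runs a single bird through the whole chain: ethogram simulation, 25 Hz
#' accelerometry, static/dynamic separation and per-second VeDBA, GPS track,
#' speed-filtered trip segmentation, day/night apportionment, isotope
#' washout and the full DLW computation. With `classify = TRUE` the
#' behaviour labels come from the unsupervised wavelet/k-means classifier;
#' otherwise the generator's true labels are used (isolating the energetics
#' chain from classification error).
#'
#' @param config A [sim_config()].
#' @param bird_id Bird identifier / RNG stream.
#' @param classify Recover the ethogram from the accelerometry instead of
#'   using the true labels.
#' @return List: `row` (one-row data.table of the per-bird energy-table
#'   entries), `budget` (`activity_budget`), `truth`, `trips`
#'   (`trip_summary`), `ethogram` (data.table: second, behaviour, vedba),
#'   `accuracy` (per-second agreement with truth when `classify = TRUE`).
#' @export
simulate_bird <- function(config, bird_id = 1L, classify = FALSE) {
  sim <- simulate_ethogram(config, bird_id)
  trace <- simulate_accel(sim)
  parts <- split_static_dynamic(trace, window_s = 2)
  v1 <- vedba_per_second(compute_vedba(parts$dynamic))
  gps <- simulate_gps(sim)

  n_sec <- nrow(sim$ethogram)
  vedba <- v1$vedba[match(sim$ethogram$second, v1$second)]
  accuracy <- NA_real_
  if (classify) {
    eth <- classify_ethogram(trace, gps$fixes, config$colony_latlon,
                             start_time = config$start_time)
    accuracy <- mean(as.character(eth$behaviour) ==
                       as.character(sim$ethogram$behaviour[seq_len(nrow(eth))]),
                     na.rm = TRUE)
    labels <- eth$behaviour
    vedba <- eth$vedba
  } else {
    labels <- sim$ethogram$behaviour
  }
  rm(trace, parts)

  bud <- budget(labels, vedba)
  filtered <- speed_filter(gps$fixes, vmax = 85)
  trips <- segment_trips(filtered, config$colony_latlon, radius_km = 0.5)

  # day/night apportionment of on-land time, and night share of at-sea time
  times <- config$start_time + as.numeric(sim$ethogram$second[seq_along(labels)])
  day <- is_daytime(times, config$colony_latlon[1], config$colony_latlon[2])
  land <- !is.na(labels) & as.character(labels) == "rest_land"
  sea <- !is.na(labels) & !land
  T_land_day <- sum(land & day) / 3600
  T_land_night <- sum(land & !day) / 3600
  NT <- if (any(sea)) sum(sea & !day) / sum(sea) else NA_real_

  # morphometrics and body masses
  set.seed(sim_seed(config, bird_id, 5L))
  mass_initial <- stats::rnorm(1, config$mass_kg, config$mass_sd_kg)
  mass_final <- mass_initial * (1 + stats::rnorm(1, 0.02, 0.02))
  tarsus <- stats::rnorm(1, config$tarsus_mm, config$tarsus_sd_mm)

  iso <- simulate_isotopes(sim$truth, mass_initial, mass_final, config)
  dlw <- dlw_energetics(iso$record, config$energy_equiv_kj_per_l)

  sea_mask <- sea
  row <- data.table::data.table(
    bird_id = bird_id,
    DLW_EE = dlw$DLW_EE, DLW_DEE = dlw$DLW_DEE,
    VeDBA_mean_T = mean(vedba, na.rm = TRUE),
    VeDBA_mean_S = if (any(sea_mask)) mean(vedba[sea_mask], na.rm = TRUE) else NA_real_,
    TD = trips$total_distance_km,
    NT = NT,
    T_land_h = bud$table$T_h[bud$table$behaviour == "rest_land"],
    T_land_day_h = T_land_day, T_land_night_h = T_land_night,
    time_at_sea_h = bud$time_at_sea_h,
    prop_at_sea = bud$time_at_sea_h / bud$deployment_h,
    dive_rate = bud$dive_rate,
    mass = mass_initial, tarsus = tarsus,
    sampling_days = bud$deployment_h / 24
  )
  list(row = row, budget = bud, truth = iso$truth, trips = trips,
       ethogram = data.table::data.table(second = sim$ethogram$second[seq_along(labels)],
                                         behaviour = labels, vedba = vedba),
       accuracy = accuracy)
}

#' Simulate and analyse a whole cohort
#'
#' Processes `config$n_birds` deployments, fits the activity-specific energy
#' coefficients, predicts per-bird energy expenditure, computes at-sea
#' energy by both subtraction methods, and returns the per-bird energy
#' table alongside the coefficient fit and ground truth.
#'
#' @param config A [sim_config()].
#' @param classify Use the unsupervised classifier for each bird's ethogram.
#' @param basis Predictor basis for the coefficient fit, see
#'   [fit_activity_coefficients()].
#' @param land_constants Optional `c(day =, night =)` on-land metabolic
#'   rates (kJ h^-1) enabling the S2 subtraction method.
#' @param progress Print one line per bird.
#' @return List of class `cohort`: `energy` (per-bird table), `coefficients`
#'   (`activity_coefficients`), `T_mat`, `V_mat` (budget matrices), `truth`
#'   (per-bird ground-truth table), `config`.
#' @export
simulate_cohort <- function(config, classify = FALSE,
                            basis = c("time", "vedba_sum"),
                            land_constants = NULL, progress = FALSE) {
  basis <- match.arg(basis)
  rows <- vector("list", config$n_birds)
  budgets <- vector("list", config$n_birds)
  truths <- vector("list", config$n_birds)
  for (i in seq_len(config$n_birds)) {
    b <- simulate_bird(config, bird_id = i, classify = classify)
    rows[[i]] <- b$row
    budgets[[i]] <- b$budget
    tt <- b$truth
    truths[[i]] <- data.table::data.table(
      bird_id = tt$bird_id, true_EE = tt$true_EE,
      true_rCO2 = tt$true_rCO2, true_k_d = tt$true_k_d, true_k_o = tt$true_k_o,
      t(tt$true_T_i))
    if (progress) message(sprintf("bird %d/%d done", i, config$n_birds))
  }
  energy <- data.table::rbindlist(rows)
  truth <- data.table::rbindlist(truths)

  coeffs <- fit_activity_coefficients(energy$DLW_EE, budgets, basis = basis)
  T_mat <- budget_matrix(budgets, "time")
  V_mat <- budget_matrix(budgets, "vedba_sum")

  pred <- lapply(seq_len(config$n_birds), function(i)
    predict_ee(coeffs, budgets[[i]]))
  energy$Pred_EE <- vapply(pred, `[[`, numeric(1), "Pred_EE")
  energy$Pred_DEE <- vapply(pred, `[[`, numeric(1), "Pred_DEE")

  # birds that never left the colony have no defined at-sea rate
  s1 <- lapply(seq_len(config$n_birds), function(i) {
    if (energy$time_at_sea_h[i] <= 0)
      return(list(DLW_EE_S1 = NA_real_, DLW_DEE_S1 = NA_real_))
    at_sea_s1(energy$DLW_EE[i], coeffs, energy$T_land_h[i],
              energy$time_at_sea_h[i])
  })
  energy$DLW_EE_S1 <- vapply(s1, `[[`, numeric(1), "DLW_EE_S1")
  energy$DLW_DEE_S1 <- vapply(s1, `[[`, numeric(1), "DLW_DEE_S1")

  if (!is.null(land_constants)) {
    s2 <- lapply(seq_len(config$n_birds), function(i) {
      if (energy$time_at_sea_h[i] <= 0)
        return(list(DLW_EE_S2 = NA_real_, DLW_DEE_S2 = NA_real_, excluded = TRUE))
      at_sea_s2(energy$DLW_EE[i], energy$T_land_day_h[i],
                energy$T_land_night_h[i], land_constants["day"],
                land_constants["night"], energy$time_at_sea_h[i])
    })
    energy$DLW_EE_S2 <- vapply(s2, `[[`, numeric(1), "DLW_EE_S2")
    energy$DLW_DEE_S2 <- vapply(s2, `[[`, numeric(1), "DLW_DEE_S2")
    energy$S2_excluded <- vapply(s2, `[[`, logical(1), "excluded")
  }

  structure(list(energy = energy, coefficients = coeffs, T_mat = T_mat,
                 V_mat = V_mat, truth = truth, config = config),
            class = "cohort")
}

#' Calibration analysis of a cohort energy table
#'
#' Fits the total-period and at-sea calibration regressions, the
#' per-behaviour activity fits, and runs stepwise covariate selection for
#' the total model (candidates: total distance, dive rate, body mass,
#' proportion of time at sea, tarsus length) and the at-sea model (the
#' night-at-sea proportion NT replaces the at-sea proportion).
#'
#' @param cohort A `cohort` from [simulate_cohort()], or a compatible list
#'   with `energy`, `coefficients`, `T_mat`, `V_mat`.
#' @return List: `total`, `at_sea` (regression-fit lists), `activity`
#'   (per-behaviour fit table), `step_total`, `step_at_sea`
#'   (`model_search`).
#' @export
analyse_cohort <- function(cohort) {
  energy <- as.data.frame(cohort$energy)
  total <- calibrate_total(energy)
  at_sea <- calibrate_at_sea(energy)
  activity <- activity_fit_table(cohort$coefficients, cohort$T_mat, cohort$V_mat)
  step_total <- stepwise_select(
    energy, response = "DLW_DEE", base = "VeDBA_mean_T",
    candidates = c("TD", "dive_rate", "mass", "prop_at_sea", "tarsus"))
  step_at_sea <- stepwise_select(
    energy, response = "DLW_DEE_S1", base = "VeDBA_mean_S",
    candidates = c("TD", "dive_rate", "mass", "NT", "tarsus"))
  list(total = total, at_sea = at_sea, activity = activity,
       step_total = step_total, step_at_sea = step_at_sea)
}
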