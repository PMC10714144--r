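#' Configuration for synthetic gannet deployments
#'
#' Builds the parameter set that drives the synthetic-deployment generator:
#' a semi-Markov behaviour sequence alternating colony attendance with
#' central-place foraging trips, behaviour-specific acceleration signatures,
#' an out-and-back GPS track, and a two-isotope washout record consistent
#' with a known true energy budget.
#'
#' Defaults emulate a breeding Australasian gannet cohort: 15 birds sampled
#' for ~3 days at 25 Hz from a colony at 38.28 S, 144.70 E, spending roughly
#' half their time at the colony, with at-sea time dominated by surface
#' resting, and a mean daily energy expenditure near 3200 kJ day^-1. The
#' per-behaviour energy rates (`true_coefficients`, kJ h^-1) are the ground
#' truth that the activity-specific regression must recover.
#'
#' @param n_birds Number of birds in the cohort.
#' @param sampling_rate Accelerometer sampling rate (Hz).
#' @param deployment_h Deployment duration in hours, measured from the
#'   isotope-equilibration blood sample to the final blood sample.
#' @param start_time POSIXct (UTC) of the equilibration sample; the default
#'   corresponds to local midnight at the colony in early December.
#' @param colony_latlon Colony location, `c(lat, lon)` in decimal degrees.
#' @param colony_block_h Mean duration (h) of a colony-attendance block.
#' @param sea_block_h Mean duration (h) of an at-sea (foraging trip) block.
#'   Zero produces an all-land deployment.
#' @param behaviour_dwell Named vector of mean dwell times (s) for the
#'   semi-Markov sequence, one per behaviour (exponential dwell).
#' @param behaviour_accel Named list of per-behaviour waveform parameters:
#'   `freq_hz` (dominant frequency), `amp_g` (dynamic amplitude on the heave
#'   axis) and `orient` (unit gravity vector giving the static component).
#' @param true_coefficients Named vector of true energy rates C_i (kJ h^-1)
#'   per behaviour.
#' @param sea_state_prob Probabilities of choosing flapping/gliding/rest_sea
#'   as the next at-sea state (self-transitions excluded, renormalised).
#' @param p_plunge Probability that a flight segment ends in a plunge dive.
#' @param p_duck Probability that a surface-rest segment ends in a duck dive.
#' @param bird_heterogeneity Lognormal sd of per-bird multipliers applied to
#'   the at-sea dwell means; creates realistic between-bird variation in
#'   activity budgets (and hence in energy expenditure).
#' @param trip_speed Flight ground speed (km h^-1).
#' @param drift_speed Surface-drift speed while resting at sea (km h^-1).
#' @param gps_interval_s GPS fix interval (s).
#' @param gps_noise_m Positional noise sd (m), per fix.
#' @param mass_kg Mean adult body mass (kg); per-bird masses are drawn around
#'   this value.
#' @param mass_sd_kg Between-bird sd of body mass (kg).
#' @param tarsus_mm,tarsus_sd_mm Mean and sd of tarsus length (mm).
#' @param tbw_fraction Total body water as a fraction of body mass.
#' @param k_d_per_day True deuterium (water) fractional turnover (day^-1);
#'   fixed by the generator so the isotope inverse problem has one unknown.
#' @param energy_equiv_kj_per_l Energy equivalent of CO2 (kJ L^-1).
#' @param dose_g Mass of injected dose water (g).
#' @param inj_ppm Named vector `c(O=, H=)`: injectate isotope abundances
#'   (ppm).
#' @param bg_ppm Named vector `c(O=, H=)`: background body-water abundances
#'   (ppm), near natural abundance.
#' @param isotope_noise_sd Gaussian measurement noise sd added to each
#'   enrichment (ppm); a scalar, or a named vector `c(O =, H =)` for
#'   per-isotope precision.
#' @param vedba_noise_sd Gaussian accelerometer noise sd per axis (g).
#' @param seed Integer base seed; every simulator derives its stream from
#'   this, the bird id and a stage offset, so whole cohorts are reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_birds = 2, deployment_h = 6)
#' cfg$true_coefficients
sim_config <- function(n_birds = 15,
                       sampling_rate = 25,
                       deployment_h = 72,
                       start_time = as.POSIXct("2014-12-04 13:00:00", tz = "UTC"),
                       colony_latlon = c(-38.2783, 144.6967),
                       colony_block_h = 12,
                       sea_block_h = 13,
                       behaviour_dwell = c(rest_land = 43200, rest_sea = 200,
                                           flapping = 100, gliding = 45,
                                           plunge_dive = 12, duck_dive = 7),
                       behaviour_accel = NULL,
                       true_coefficients = c(rest_land = 15, rest_sea = 127,
                                             flapping = 500, gliding = 200,
                                             plunge_dive = 700, duck_dive = 400),
                       sea_state_prob = c(flapping = 0.30, gliding = 0.27,
                                          rest_sea = 0.43),
                       p_plunge = 0.66,
                       p_duck = 0.83,
                       bird_heterogeneity = 0.30,
                       trip_speed = 30,
                       drift_speed = 1.5,
                       gps_interval_s = 120,
                       gps_noise_m = 10,
                       mass_kg = 2.61,
                       mass_sd_kg = 0.15,
                       tarsus_mm = 55,
                       tarsus_sd_mm = 2,
                       tbw_fraction = 0.60,
                       k_d_per_day = 0.2,
                       energy_equiv_kj_per_l = 27.97,
                       dose_g = 1.85,
                       inj_ppm = c(O = 643000, H = 341000),
                       bg_ppm = c(O = 2005, H = 156),
                       isotope_noise_sd = 2,
                       vedba_noise_sd = 0.05,
                       seed = 1L) {
  if (is.null(behaviour_accel)) {
    flight_orient <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
    upright <- c(0, 0, 1)
    behaviour_accel <- list(
      rest_land   = list(freq_hz = 0.3, amp_g = 0.08, orient = upright),
      rest_sea    = list(freq_hz = 0.4, amp_g = 0.55, orient = upright),
      flapping    = list(freq_hz = 3.5, amp_g = 1.80, orient = flight_orient),
      gliding     = list(freq_hz = 0.8, amp_g = 0.40, orient = flight_orient),
      plunge_dive = list(freq_hz = 1.2, amp_g = 3.00, orient = upright),
      duck_dive   = list(freq_hz = 1.2, amp_g = 3.00, orient = upright)
    )
  }
  cfg <- list(
    n_birds = as.integer(n_birds), sampling_rate = sampling_rate,
    deployment_h = deployment_h, start_time = start_time,
    colony_latlon = colony_latlon, colony_block_h = colony_block_h,
    sea_block_h = sea_block_h, behaviour_dwell = behaviour_dwell,
    behaviour_accel = behaviour_accel, true_coefficients = true_coefficients,
    sea_state_prob = sea_state_prob, p_plunge = p_plunge, p_duck = p_duck,
    bird_heterogeneity = bird_heterogeneity, trip_speed = trip_speed,
    drift_speed = drift_speed, gps_interval_s = gps_interval_s,
    gps_noise_m = gps_noise_m, mass_kg = mass_kg, mass_sd_kg = mass_sd_kg,
    tarsus_mm = tarsus_mm, tarsus_sd_mm = tarsus_sd_mm,
    tbw_fraction = tbw_fraction, k_d_per_day = k_d_per_day,
    energy_equiv_kj_per_l = energy_equiv_kj_per_l, dose_g = dose_g,
    inj_ppm = inj_ppm, bg_ppm = bg_ppm,
    isotope_noise_sd = isotope_noise_sd, vedba_noise_sd = vedba_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!setequal(names(cfg$behaviour_dwell), BEHAVIOURS))
    stop("behaviour_dwell must name exactly the six behaviours: ",
         paste(BEHAVIOURS, collapse = ", "))
  if (!setequal(names(cfg$true_coefficients), BEHAVIOURS))
    stop("true_coefficients must name exactly the six behaviours")
  if (!setequal(names(cfg$behaviour_accel), BEHAVIOURS))
    stop("behaviour_accel must name exactly the six behaviours")
  if (any(cfg$behaviour_dwell <= 0)) stop("dwell times must be strictly positive")
  if (any(cfg$true_coefficients <= 0)) stop("energy rates must be strictly positive")
  amps <- vapply(cfg$behaviour_accel, function(b) b$amp_g, numeric(1))
  if (any(amps < 0)) stop("dynamic amplitudes must be non-negative")
  if (cfg$n_birds < 1L) stop("n_birds must be >= 1")
  if (cfg$sampling_rate <= 0 || cfg$deployment_h <= 0)
    stop("sampling_rate and deployment_h must be positive")
  if (cfg$sea_block_h < 0) stop("sea_block_h must be >= 0")
  invisible(cfg)
}

# deterministic per-bird, per-stage RNG streams derived from the base seed;
# kept below 2^31 so they remain valid R integer seeds
sim_seed <- function(cfg, bird_id, stage) {
  as.integer((abs(cfg$seed) * 10007 + bird_id * 101 + stage) %% 2147483647)
}
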