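test_that("ethogram generator conserves time and respects structure", {
  cfg <- short_config(seed = 2)
  b <- simulate_ethogram(cfg, 1)
  # conservation: per-behaviour times sum to the deployment
  expect_equal(sum(b$truth$true_T_i), cfg$deployment_h)
  expect_equal(nrow(b$ethogram), cfg$deployment_h * 3600)
  expect_false(anyNA(b$ethogram$behaviour))
  # true_EE is exactly sum C_i T_i
  expect_equal(b$truth$true_EE,
               sum(cfg$true_coefficients * b$truth$true_T_i[names(cfg$true_coefficients)]))

  lab <- as.character(b$ethogram$behaviour)
  r <- rle(lab)
  # dives only at sea, with the defining preceding behaviour
  pre <- r$values[which(r$values == "plunge_dive") - 1L]
  expect_true(all(pre %in% c("flapping", "gliding")))
  pre_d <- r$values[which(r$values == "duck_dive") - 1L]
  expect_true(all(pre_d == "rest_sea"))
  # every at-sea block starts and ends with flight (commute)
  sea <- lab != "rest_land"
  rs <- rle(sea)
  ends <- cumsum(rs$lengths); starts <- ends - rs$lengths + 1L
  for (i in which(rs$values)) {
    expect_equal(lab[starts[i]], "flapping")
    if (ends[i] < length(lab)) expect_equal(lab[ends[i]], "flapping")
  }
})

test_that("degenerate and invalid configurations are handled", {
  cfg <- sim_config(n_birds = 1, deployment_h = 3, sea_block_h = 0, seed = 1)
  b <- simulate_ethogram(cfg, 1)
  expect_true(all(b$ethogram$behaviour == "rest_land"))
  expect_error(simulate_ethogram(sim_config(deployment_h = 0.001)),
               "shorter than")
  expect_error(sim_config(behaviour_dwell = c(rest_land = 1)), "six behaviours")
  expect_error(sim_config(true_coefficients = c(rest_land = -1, rest_sea = 1,
                                                flapping = 1, gliding = 1,
                                                plunge_dive = 1, duck_dive = 1)),
               "positive")
})

test_that("simulators are reproducible under a fixed seed", {
  cfg <- short_config(seed = 9)
  b1 <- simulate_ethogram(cfg, 1)
  b2 <- simulate_ethogram(cfg, 1)
  expect_identical(b1$ethogram$behaviour, b2$ethogram$behaviour)
  a1 <- simulate_accel(b1)
  a2 <- simulate_accel(b2)
  expect_identical(a1$z, a2$z)
  g1 <- simulate_gps(b1)
  g2 <- simulate_gps(b2)
  expect_identical(g1$fixes$lat, g2$fixes$lat)
  # different bird id gives a different realisation
  b3 <- simulate_ethogram(cfg, 2)
  expect_false(identical(b1$ethogram$behaviour, b3$ethogram$behaviour))
})

test_that("ethogram dwell times follow the configured means", {
  cfg <- sim_config(n_birds = 1, deployment_h = 400, colony_block_h = 0.5,
                    sea_block_h = 4, bird_heterogeneity = 0, seed = 4)
  b <- simulate_ethogram(cfg, 1)
  r <- rle(as.character(b$ethogram$behaviour))
  for (beh in c("flapping", "gliding", "rest_sea")) {
    m <- mean(r$lengths[r$values == beh])
    # exponential dwell, truncated at block ends: mean within 10%
    expect_lt(abs(m / cfg$behaviour_dwell[beh] - 1), 0.10)
  }
})

test_that("acceleration signatures reflect the configuration", {
  cfg <- short_config(seed = 3, vedba_noise_sd = 0)
  # zero amplitude + zero noise + constant orientation -> VeDBA ~ 0
  cfg0 <- cfg
  for (b in names(cfg0$behaviour_accel)) {
    cfg0$behaviour_accel[[b]]$amp_g <- 0
    cfg0$behaviour_accel[[b]]$orient <- c(0, 0, 1)
  }
  sim <- simulate_ethogram(cfg0, 1)
  tr <- simulate_accel(sim)
  p <- split_static_dynamic(tr)
  expect_lt(max(compute_vedba(p$dynamic)$vedba), 1e-8)

  # monotone: flapping VeDBA exceeds resting VeDBA at configured amplitudes
  sim2 <- simulate_ethogram(short_config(seed = 3), 1)
  tr2 <- simulate_accel(sim2)
  p2 <- split_static_dynamic(tr2)
  v <- compute_vedba(p2$dynamic)$vedba
  lab <- as.character(sim2$ethogram$behaviour)[floor(tr2$t) + 1]
  expect_gt(mean(v[lab == "flapping"]), mean(v[lab == "rest_land"]))
  expect_gt(mean(v[lab == "rest_sea"]), mean(v[lab == "rest_land"]))
})

test_that("flapping block spectral peak matches the configured frequency", {
  cfg <- short_config(seed = 3, vedba_noise_sd = 0.01)
  sim <- simulate_ethogram(cfg, 1)
  tr <- simulate_accel(sim)
  lab <- as.character(sim$ethogram$behaviour)[floor(tr$t) + 1]
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  i <- which(r$values == "flapping" & r$lengths >= 100 * 25)[1]
  expect_false(is.na(i))
  z <- tr$z[starts[i]:ends[i]]
  z <- z - mean(z)
  # FFT oracle: dominant frequency of the block
  sp <- Mod(fft(z))[1:(length(z) %/% 2)]
  fgrid <- (seq_along(sp) - 1) * 25 / length(z)
  expect_lt(abs(fgrid[which.max(sp)] - cfg$behaviour_accel$flapping$freq_hz), 0.1)
})

test_that("GPS track is colony-bound and recovers trip distance", {
  # all-land deployment: every fix within the colony radius
  cfg <- sim_config(n_birds = 1, deployment_h = 3, sea_block_h = 0, seed = 5)
  sim <- simulate_ethogram(cfg, 1)
  g <- simulate_gps(sim)
  d <- haversine_km(g$fixes$lat, g$fixes$lon,
                    cfg$colony_latlon[1], cfg$colony_latlon[2])
  expect_lt(max(d), 0.1)
  expect_equal(g$true_trip_distance, 0)

  # out-and-back foraging trips: measured track length close to the
  # generator's truth (study-scale blocks so every trip leaves the colony
  # radius)
  cfg2 <- sim_config(n_birds = 1, seed = 6)
  sim2 <- simulate_ethogram(cfg2, 1)
  g2 <- simulate_gps(sim2)
  ts <- segment_trips(speed_filter(g2$fixes), cfg2$colony_latlon)
  expect_gt(g2$true_trip_distance, 20)
  expect_lt(abs(ts$total_distance_km / g2$true_trip_distance - 1), 0.02)
})

test_that("isotope simulation inverts the DLW chain", {
  cfg <- short_config(seed = 7, isotope_noise_sd = 0)
  sim <- simulate_ethogram(cfg, 1)
  iso <- simulate_isotopes(sim$truth, 2.6, 2.66, cfg)
  expect_gt(iso$truth$true_k_o, iso$truth$true_k_d)
  # noise-free round trip recovers the true energy budget
  d <- dlw_energetics(iso$record, cfg$energy_equiv_kj_per_l)
  expect_lt(abs(d$DLW_EE / sim$truth$true_EE - 1), 1e-3)

  # doubling true_EE at fixed pool and k_d washes 18O out faster
  t2 <- sim$truth
  t2$true_EE <- 2 * t2$true_EE
  iso2 <- simulate_isotopes(t2, 2.6, 2.66, cfg)
  expect_lt(iso2$record$E_fin_O, iso$record$E_fin_O)
  # deuterium washout unchanged (k_d fixed)
  expect_equal(iso2$record$E_fin_H, iso$record$E_fin_H)

  expect_error(simulate_isotopes(list(true_EE = -5, bird_id = 1), 2.6, 2.6, cfg),
               "positive")
})

test_that("zero elapsed time leaves final enrichment at the plateau", {
  # vanishing elapsed time and energy: no washout has occurred
  cfg <- short_config(seed = 7, isotope_noise_sd = 0)
  cfg$deployment_h <- 1e-9
  truth <- list(bird_id = 1, true_EE = 1e-9)
  iso <- simulate_isotopes(truth, 2.6, 2.6, cfg)
  expect_equal(iso$record$E_fin_O, iso$record$E_eq_O, tolerance = 1e-9)
  expect_equal(iso$record$E_fin_H, iso$record$E_eq_H, tolerance = 1e-9)
})
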