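test_that("wavelet frames localise a pure tone and count seconds", {
  rate <- 25
  t <- seq(0, 30 - 1 / rate, by = 1 / rate)
  z <- sin(2 * pi * 3.5 * t)
  fr <- wavelet_frames(z, rate)
  expect_equal(length(fr$second), 30)
  # peak band contains 3.5 Hz within the log-spaced band resolution
  peak <- fr$freqs[apply(fr$spectrum, 1, which.max)]
  step <- log(fr$freqs[2] / fr$freqs[1])
  expect_true(all(abs(log(peak / 3.5)) <= step))

  expect_equal(max(wavelet_frames(numeric(100), rate)$spectrum), 0)
  expect_equal(length(wavelet_frames(z[1:80], rate)$second), 3)  # floor(3.2 s)
  expect_error(wavelet_frames(z[1:10], rate), "shorter than one second")
})

test_that("chunked CWT equals the whole-trace transform away from edges", {
  set.seed(8)
  x <- rnorm(6000)
  freqs <- exp(seq(log(0.5), log(12), length.out = 8))
  whole <- morlet_cwt(x, 25, freqs)
  chunked <- morlet_cwt(x, 25, freqs, chunk_len = 2048)
  core <- 500:5500
  # bands comfortably below Nyquist are exact; bands approaching Nyquist
  # (12.5 Hz here) carry spectral-truncation tails in both variants whose
  # placement differs, so agreement loosens as the band nears the limit
  expect_lt(max(abs(whole[core, freqs <= 5] - chunked[core, freqs <= 5])), 1e-8)
  expect_lt(max(abs(whole[core, freqs <= 10] - chunked[core, freqs <= 10])), 1e-3)
  expect_lt(max(abs(whole[core, ] - chunked[core, ])), 0.05)
})

test_that("k-means separates distinct regimes and is reproducible", {
  rate <- 25
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  z <- c(0.1 * sin(2 * pi * 0.5 * t), 1.5 * sin(2 * pi * 3.5 * t))
  fr <- wavelet_frames(z, rate)
  cl <- cluster_frames(fr, k = 2, seed = 1)
  truth <- rep(1:2, each = 60)
  # perfect separation up to label permutation, scored away from the trace
  # edges and the regime switch where frames mix both signals
  interior <- c(2:59, 62:119)
  agree <- max(mean(cl[interior] == truth[interior]),
               mean(cl[interior] == 3 - truth[interior]))
  expect_equal(agree, 1)
  expect_identical(cl, cluster_frames(fr, k = 2, seed = 1))
  expect_error(cluster_frames(fr, k = 1000), "exceeds")
})

test_that("cluster-to-behaviour mapping follows the amplitude heuristics", {
  # three synthetic clusters: quiet low-frequency, wingbeat-band, burst
  fr <- structure(list(
    second = 0:29,
    spectrum = rbind(
      matrix(rep(c(1, 0.2, 0.1), 10), 10, 3, byrow = TRUE),
      matrix(rep(c(0.2, 2.0, 0.2), 10), 10, 3, byrow = TRUE),
      matrix(rep(c(0.5, 0.5, 3.0), 10), 10, 3, byrow = TRUE)),
    rms_dynamic = rep(c(0.1, 0.9, 2.5), each = 10),
    freqs = c(0.5, 3.5, 8)), class = "spectral_frames")
  cl <- rep(1:3, each = 10)
  lab <- assign_behaviours(cl, fr)
  expect_equal(unique(lab[cl == 1]), "low")
  expect_equal(unique(lab[cl == 2]), "flapping")
  expect_equal(unique(lab[cl == 3]), "dive")   # max-RMS cluster is the dive
  m <- attr(lab, "mapping")
  expect_equal(m$behaviour[m$cluster == 3], "dive")
  # permuting cluster ids leaves the behaviour sequence unchanged
  lab2 <- assign_behaviours(4 - cl, fr)
  expect_equal(as.character(lab2), as.character(lab))
})

test_that("speed and location rules resolve low-dynamic seconds", {
  lab <- rep("low", 6)
  speed <- c(40, 1, 1, 40, 1, NA)
  dist <- c(5, 5, 0.1, 0.1, NA, 2)
  out <- apply_rules(lab, speed, dist)
  expect_equal(as.character(out[1:4]),
               c("gliding", "rest_sea", "rest_land", "gliding"))
  expect_true(all(is.na(out[5:6])))
  expect_equal(attr(out, "n_flagged"), 2L)
  # idempotent
  out2 <- apply_rules(out, speed, dist)
  expect_equal(as.character(out2), as.character(out))
  # non-low labels untouched
  expect_equal(as.character(apply_rules("flapping", 1, 0.1)), "flapping")
})

test_that("dive bouts are merged and typed by the preceding behaviour", {
  lab <- c(rep("flapping", 6), "dive", "dive", rep("rest_sea", 6), "dive",
           rep("rest_sea", 3))
  out <- classify_dives(lab)
  expect_equal(as.character(out[7:8]), rep("plunge_dive", 2))
  expect_equal(as.character(out[15]), "duck_dive")
  expect_equal(attr(out, "n_plunge"), 1L)
  expect_equal(attr(out, "n_duck"), 1L)

  # two dive runs separated by less than the merge gap form one bout
  lab2 <- c(rep("flapping", 6), "dive", "rest_sea", "dive", rep("rest_sea", 5))
  out2 <- classify_dives(lab2, merge_gap_s = 2)
  expect_equal(attr(out2, "n_plunge") + attr(out2, "n_duck"), 1L)
  expect_equal(as.character(out2[7:9]), rep("plunge_dive", 3))

  # dive at trace start cannot be typed from context
  expect_warning(out3 <- classify_dives(c("dive", rep("rest_sea", 5))),
                 "no preceding")
  expect_equal(as.character(out3[1]), "plunge_dive")
})

test_that("activity budgets are complete, conserved and counted", {
  lab <- c(rep("rest_land", 3600), rep("flapping", 1800), rep("plunge_dive", 10),
           rep("rest_sea", 1790))
  v <- rep(0.3, length(lab))
  b <- budget(lab, v)
  expect_equal(sum(b$table$proportion), 1)
  expect_equal(sum(b$table$T_h), length(lab) / 3600)
  expect_equal(b$n_plunge, 1L)
  expect_equal(b$dive_rate, 1 / b$time_at_sea_h)
  expect_equal(b$table$vedba_sum[b$table$behaviour == "flapping"], 1800 * 0.3)

  # all-land ethogram
  b2 <- budget(rep("rest_land", 7200), rep(0.05, 7200))
  expect_equal(b2$table$T_h[b2$table$behaviour == "rest_land"], 2)
  expect_equal(sum(b2$table$T_h[b2$table$behaviour != "rest_land"]), 0)

  # budgets invariant under relabelling preserving per-class counts
  b3 <- budget(sample(lab), sample(v))
  expect_equal(b3$table$T_h, b$table$T_h)
})

test_that("unsupervised ethogram recovers the true labels on a synthetic bird", {
  cfg <- short_config(seed = 12)
  sim <- simulate_ethogram(cfg, 1)
  tr <- simulate_accel(sim)
  g <- simulate_gps(sim)
  eth <- suppressWarnings(
    classify_ethogram(tr, g$fixes, cfg$colony_latlon, start_time = cfg$start_time))
  n <- nrow(eth)
  truth <- as.character(sim$ethogram$behaviour[seq_len(n)])
  acc <- mean(as.character(eth$behaviour) == truth, na.rm = TRUE)
  expect_gte(acc, 0.90)

  # recovered per-behaviour times within 2% of the deployment duration
  b <- budget(eth$behaviour, eth$vedba)
  T_true <- sim$truth$true_T_i
  for (beh in behaviour_levels()) {
    T_hat <- b$table$T_h[b$table$behaviour == beh]
    expect_lt(abs(T_hat - T_true[beh]), 0.02 * cfg$deployment_h)
  }
})
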