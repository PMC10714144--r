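test_that("activity coefficients are recovered exactly from exact data", {
  set.seed(10)
  C <- c(rest_land = 15, rest_sea = 127, flapping = 500, gliding = 200,
         plunge_dive = 700, duck_dive = 400)
  T_mat <- matrix(runif(10 * 6, 0.5, 30), 10, 6,
                  dimnames = list(NULL, behaviour_levels()))
  EE <- drop(T_mat %*% C[colnames(T_mat)])
  fit <- fit_activity_coefficients(EE, T_mat, basis = "time")
  expect_equal(fit$coefficients[names(C)], C, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # invariant to bird ordering
  ord <- sample(10)
  fit2 <- fit_activity_coefficients(EE[ord], T_mat[ord, ], basis = "time")
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-9)
})

test_that("behaviours absent from all birds are dropped with a warning", {
  set.seed(11)
  T_mat <- matrix(runif(10 * 6, 1, 30), 10, 6,
                  dimnames = list(NULL, behaviour_levels()))
  T_mat[, "duck_dive"] <- 0
  C <- c(rest_land = 15, rest_sea = 127, flapping = 500, gliding = 200,
         plunge_dive = 700, duck_dive = 400)
  EE <- drop(T_mat %*% C[colnames(T_mat)])
  expect_warning(fit <- fit_activity_coefficients(EE, T_mat), "duck_dive")
  expect_true(is.na(fit$coefficients["duck_dive"]))
  expect_equal(fit$coefficients["flapping"], C["flapping"], tolerance = 1e-9)
  expect_error(fit_activity_coefficients(EE[1:5], T_mat[1:5, ]), "more birds")
})

test_that("energy prediction is additive and homogeneous", {
  C <- c(rest_land = 15, rest_sea = 127, flapping = 500, gliding = 200,
         plunge_dive = 700, duck_dive = 400)
  coeffs <- structure(list(coefficients = C, basis = "time"),
                      class = "activity_coefficients")
  bud <- setNames(c(10, 5, 2, 1, 0.1, 0.1), behaviour_levels())
  p <- predict_ee(coeffs, bud, sampling_days = 2)
  expect_equal(p$Pred_EE, sum(C[names(bud)] * bud))
  expect_equal(p$Pred_DEE, p$Pred_EE / 2)
  expect_equal(predict_ee(coeffs, 0 * bud, sampling_days = 2)$Pred_EE, 0)
  expect_equal(predict_ee(coeffs, 2 * bud, sampling_days = 2)$Pred_EE,
               2 * p$Pred_EE)
})

test_that("S1 subtraction conserves energy and handles edge cases", {
  C <- setNames(rep(100, 6), behaviour_levels()); C["rest_land"] <- 20
  coeffs <- structure(list(coefficients = C, basis = "time"),
                      class = "activity_coefficients")
  out <- at_sea_s1(5000, coeffs, T_land_h = 30, time_at_sea_h = 40)
  expect_equal(out$DLW_EE_S1 + out$EE_land, 5000)       # conservation
  expect_equal(out$DLW_DEE_S1, out$DLW_EE_S1 / (40 / 24))
  # no land time: at-sea energy equals the total
  expect_equal(at_sea_s1(5000, coeffs, 0, 40)$DLW_EE_S1, 5000)
  expect_error(at_sea_s1(5000, coeffs, 30, 0), "no time at sea")
})

test_that("S2 subtraction requires explicit constants and flags overshoot", {
  out <- at_sea_s2(5000, 20, 10, c_day = 30, c_night = 20, time_at_sea_h = 40)
  expect_equal(out$EE_land, 30 * 20 + 20 * 10)
  expect_equal(out$DLW_EE_S2, 5000 - 800)
  expect_false(out$excluded)
  # equal constants collapse to rate times total land time
  out2 <- at_sea_s2(5000, 20, 10, 25, 25, 40)
  expect_equal(out2$EE_land, 25 * 30)
  # zero land time: S2 equals the total
  expect_equal(at_sea_s2(5000, 0, 0, 30, 20, 40)$DLW_EE_S2, 5000)
  # land estimate at or above the total flags the bird
  expect_true(at_sea_s2(500, 20, 10, 30, 20, 40)$excluded)
  expect_error(at_sea_s2(5000, 20, 10, time_at_sea_h = 40), "c_day")
})

test_that("per-behaviour fits are perfect for proportional data", {
  set.seed(12)
  C <- c(rest_land = 15, rest_sea = 127, flapping = 500, gliding = 200,
         plunge_dive = 700, duck_dive = 400)
  T_mat <- matrix(runif(12 * 6, 1, 30), 12, 6,
                  dimnames = list(NULL, behaviour_levels()))
  V_mat <- sweep(T_mat, 2, c(0.05, 0.35, 1.2, 0.25, 1.9, 1.9) * 3600, `*`)
  coeffs <- structure(list(coefficients = C, basis = "time"),
                      class = "activity_coefficients")
  tab <- activity_fit_table(coeffs, T_mat, V_mat)
  expect_equal(nrow(tab), 6)
  expect_true(all(abs(tab$r_squared - 1) < 1e-9))
  expect_true(all(tab$df1 == 1 & tab$df2 == 10))

  # zero-variance behaviour is omitted
  V0 <- V_mat; V0[, "duck_dive"] <- 1
  tab2 <- activity_fit_table(coeffs, T_mat, V0)
  expect_false("duck_dive" %in% tab2$behaviour)
})

test_that("coefficients are recovered within sampling error under EE noise", {
  # one moderate replicate set; the full 500-cohort check runs in the
  # acceptance suite
  set.seed(13)
  C <- c(rest_land = 15, rest_sea = 127, flapping = 500, gliding = 200,
         plunge_dive = 700, duck_dive = 400)
  hits <- matrix(NA, 50, 6, dimnames = list(NULL, names(C)))
  for (r in 1:50) {
    T_mat <- cbind(rest_land = runif(15, 25, 45), rest_sea = runif(15, 15, 35),
                   flapping = runif(15, 4, 12), gliding = runif(15, 1, 6),
                   plunge_dive = runif(15, 0.2, 1), duck_dive = runif(15, 0.2, 1))
    EE <- drop(T_mat %*% C[colnames(T_mat)])
    EE <- EE + rnorm(15, 0, 0.05 * mean(EE))   # 5% of cohort-mean energy
    fit <- fit_activity_coefficients(EE, T_mat)
    hits[r, ] <- abs(fit$coefficients[names(C)] - C) <= 2 * fit$se[names(C)]
  }
  # smoke check at 50 replicates (binomial sd ~4%); the sharp >=90% bound
  # runs over 500 cohorts in the acceptance suite
  expect_gte(mean(hits), 0.88)
  expect_true(all(colMeans(hits) >= 0.78))
})
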