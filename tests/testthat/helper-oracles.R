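# Independent oracles and small fixture factories used across the suite.

# OLS by explicit normal equations (independent of lm)
ols_oracle <- function(y, X) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  list(beta = drop(beta), r_squared = 1 - sse / sst)
}

# Sunrise/sunset from the Spencer (1971) Fourier-series declination and
# equation of time -- an independent low-precision solar formulation.
spencer_sun <- function(date, lat, lon) {
  doy <- as.integer(format(as.Date(date), "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqt <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                   0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  phi <- lat * pi / 180
  cosH <- (cos(90.833 * pi / 180) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  H <- acos(cosH) * 180 / pi
  mid <- as.POSIXct(paste(format(as.Date(date)), "00:00:00"), tz = "UTC")
  list(sunrise = mid + (720 - 4 * (lon + H) - eqt) * 60,
       sunset = mid + (720 - 4 * (lon - H) - eqt) * 60)
}

# a deployment short enough for fast unit tests, with compressed blocks so
# all six behaviours occur
short_config <- function(seed = 11, ...) {
  sim_config(n_birds = 1, deployment_h = 6, colony_block_h = 1.5,
             sea_block_h = 3, seed = seed, ...)
}

# synthetic accel trace builder: per-axis functions of time
make_trace <- function(f_x, f_y, f_z, dur_s = 10, rate = 25) {
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  out <- data.table::data.table(t = t, x = f_x(t), y = f_y(t), z = f_z(t))
  data.table::setattr(out, "rate", rate)
  data.table::setattr(out, "start_time",
                      as.POSIXct("2014-12-05 00:00:00", tz = "UTC"))
  data.table::setattr(out, "class", c("accel_trace", class(out)))
  out
}
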