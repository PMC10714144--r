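#' Sunrise and sunset times (NOAA solar position algorithm)
#'
#' Computes apparent sunrise and sunset (solar zenith 90.833 deg, i.e.
#' including standard refraction and the solar disc radius) for a calendar
#' date and location, using the NOAA solar-calculator equations (solar
#' geometry from the Julian century: mean longitude and anomaly, equation of
#' centre, apparent longitude, obliquity, declination and the equation of
#' time). Returned times are POSIXct UTC and may fall on the adjacent UTC
#' calendar day at longitudes far from Greenwich.
#'
#' @param date A `Date` (or coercible) -- the UTC date whose solar noon
#'   anchors the day interval.
#' @param lat,lon Location in decimal degrees.
#' @return List with POSIXct `sunrise`, `sunset` (UTC) and `daylength_h`.
#' @export
#' @examples
#' sun_times(as.Date("2014-12-06"), -38.2783, 144.6967)
sun_times <- function(date, lat, lon) {
  date <- as.Date(date)
  d2r <- pi / 180
  jd <- as.numeric(date) + 2440587.5 + 0.5   # 12:00 UTC
  jc <- (jd - 2451545) / 36525

  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(M * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * M * d2r) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  lambda <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(eps * d2r) * sin(lambda * d2r)) / d2r

  y <- tan(eps * d2r / 2)^2
  eqtime <- 4 / d2r * (y * sin(2 * L0 * d2r) - 2 * e * sin(M * d2r) +
                       4 * e * y * sin(M * d2r) * cos(2 * L0 * d2r) -
                       0.5 * y^2 * sin(4 * L0 * d2r) -
                       1.25 * e^2 * sin(2 * M * d2r))   # minutes

  cos_ha <- cos(90.833 * d2r) / (cos(lat * d2r) * cos(decl * d2r)) -
    tan(lat * d2r) * tan(decl * d2r)
  if (any(abs(cos_ha) > 1))
    stop("polar day/night: sunrise/sunset undefined at this latitude and date")
  ha <- acos(cos_ha) / d2r

  noon_min <- 720 - 4 * lon - eqtime
  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  sunrise <- midnight + (noon_min - 4 * ha) * 60
  sunset <- midnight + (noon_min + 4 * ha) * 60
  list(sunrise = sunrise, sunset = sunset, daylength_h = 8 * ha / 60)
}

#' Split a time interval into day and night hours
#'
#' Splits `[start, end]` at computed sunrise and sunset for the location and
#' sums the daylight and night portions. Conservation holds exactly:
#' `T_day + T_night` equals the interval length.
#'
#' @param start,end POSIXct (UTC) interval bounds.
#' @param lat,lon Location in decimal degrees.
#' @return Named list: `T_day_h`, `T_night_h`.
#' @export
day_night_split <- function(start, end, lat, lon) {
  if (end < start) stop("end before start")
  total_h <- as.numeric(difftime(end, start, units = "hours"))
  dates <- seq(as.Date(start) - 1, as.Date(end) + 1, by = "day")
  day_h <- 0
  for (d in seq_along(dates)) {
    st <- sun_times(dates[d], lat, lon)
    lo <- max(as.numeric(start), as.numeric(st$sunrise))
    hi <- min(as.numeric(end), as.numeric(st$sunset))
    if (hi > lo) day_h <- day_h + (hi - lo) / 3600
  }
  list(T_day_h = day_h, T_night_h = total_h - day_h)
}

#' Daylight flag for a vector of times
#'
#' Classifies each time as day (between apparent sunrise and sunset) or
#' night at the given location.
#'
#' @param times POSIXct (UTC) vector.
#' @param lat,lon Location in decimal degrees.
#' @return Logical vector, `TRUE` for daylight.
#' @export
is_daytime <- function(times, lat, lon) {
  out <- rep(FALSE, length(times))
  dates <- seq(min(as.Date(times)) - 1, max(as.Date(times)) + 1, by = "day")
  tn <- as.numeric(times)
  for (d in seq_along(dates)) {
    st <- sun_times(dates[d], lat, lon)
    out <- out | (tn >= as.numeric(st$sunrise) & tn <= as.numeric(st$sunset))
  }
  out
}
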