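#' Simulate a GPS track consistent with an ethogram
#'
#' Produces fixes at the configured interval. While resting on land the bird
#' sits at the colony (plus fix noise). Each at-sea block is an out-and-back
#' trip along a random bearing: ground speed is `trip_speed` during flight,
#' `drift_speed` while resting at the surface and zero while diving; the bird
#' heads outbound until half the block's total path length is covered, then
#' returns, so every trip closes at the colony. The true total path length
#' over all trips is returned alongside the fixes.
#'
#' @inheritParams simulate_accel
#' @return List with `fixes` (data.table: `time` POSIXct UTC, `lat`, `lon`)
#'   and `true_trip_distance` (km, total over all at-sea blocks).
#' @export
simulate_gps <- function(bird, config = NULL, bird_id = NULL) {
  if (inherits(bird, "sim_bird")) {
    if (is.null(config)) config <- bird$config
    if (is.null(bird_id)) bird_id <- bird$truth$bird_id
    eth <- bird$ethogram
  } else {
    eth <- bird
    if (is.null(config)) stop("config required when passing a bare ethogram")
    if (is.null(bird_id)) bird_id <- 1L
  }
  validate_sim_config(config)
  set.seed(sim_seed(config, bird_id, 3L))

  beh <- as.character(eth$behaviour)
  n_sec <- length(beh)
  speed_ms <- numeric(n_sec)
  speed_ms[beh %in% c("flapping", "gliding")] <- config$trip_speed / 3.6
  speed_ms[beh == "rest_sea"] <- config$drift_speed / 3.6

  at_sea <- beh != "rest_land"
  block <- data.table::rleid(at_sea)
  radial_m <- numeric(n_sec)     # distance from colony along the trip bearing
  bearing <- numeric(n_sec)
  true_dist_m <- 0
  for (s in split(seq_len(n_sec), block)) {
    if (!at_sea[s[1L]]) next
    d <- cumsum(speed_ms[s])      # path length within the block
    D <- d[length(d)]
    true_dist_m <- true_dist_m + D
    radial_m[s] <- ifelse(d <= D / 2, d, D - d)
    bearing[s] <- stats::runif(1, 0, 360)
  }

  idx <- seq(1L, n_sec, by = config$gps_interval_s)
  colony <- c(config$colony_latlon[2], config$colony_latlon[1]) # lon, lat
  pts <- geosphere::destPoint(colony, b = bearing[idx], d = pmax(radial_m[idx], 0),
                              r = 6371000)
  # isotropic fix noise
  noise_b <- stats::runif(length(idx), 0, 360)
  noise_d <- abs(stats::rnorm(length(idx), 0, config$gps_noise_m))
  pts <- geosphere::destPoint(pts, b = noise_b, d = noise_d, r = 6371000)

  fixes <- data.table::data.table(
    time = config$start_time + (idx - 1L),
    lat = pts[, 2], lon = pts[, 1]
  )
  list(fixes = fixes, true_trip_distance = true_dist_m / 1000)
}
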