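#' Great-circle distance (haversine, Earth radius 6371 km)
#'
#' Vectorised wrapper around [geosphere::distHaversine()] with the spherical
#' Earth radius fixed at 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1)  # ~111.19 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Iterative speed filter for GPS fixes
#'
#' Removes fixes implying unrealistic point-to-point travelling speeds.
#' Repeatedly drops the fix terminating the fastest remaining leg until all
#' legs are at or below `vmax`; the first and last fixes are never dropped.
#' The result is a fixed point of the filter (a second pass changes nothing),
#' and removing fixes can only shorten the total track length.
#'
#' @param fixes data.table/data.frame with `time` (POSIXct, strictly
#'   increasing), `lat`, `lon`.
#' @param vmax Maximum plausible speed (km h^-1); default 85, above sustained
#'   gannet flight speed.
#' @return The filtered fix table (rows preserved in time order).
#' @export
speed_filter <- function(fixes, vmax = 85) {
  if (vmax <= 0) stop("vmax must be positive")
  stopifnot(all(diff(as.numeric(fixes$time)) > 0))
  keep <- rep(TRUE, nrow(fixes))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) stop("speed filter removed all interior fixes")
    d <- haversine_km(fixes$lat[idx[-length(idx)]], fixes$lon[idx[-length(idx)]],
                      fixes$lat[idx[-1]], fixes$lon[idx[-1]])
    dt_h <- diff(as.numeric(fixes$time[idx])) / 3600
    v <- d / dt_h
    bad <- which(v > vmax)
    if (!length(bad)) break
    worst <- bad[which.max(v[bad])]
    # the offending fix is the endpoint of the worst leg whose *other*
    # adjacent leg is also fast (a spike violates both its legs)
    a <- worst; b <- worst + 1L
    v_into_a <- if (a > 1L) v[a - 1L] else -Inf
    v_out_b <- if (b < length(idx)) v[b] else -Inf
    drop <- if (v_into_a > v_out_b) idx[a] else idx[b]
    if (drop == idx[length(idx)]) drop <- idx[a]        # protect the last fix
    if (drop == idx[1L]) break                          # protect the first fix
    keep[drop] <- FALSE
  }
  fixes[keep, , drop = FALSE]
}

#' Segment foraging trips and accumulate distance covariates
#'
#' A trip is a maximal run of fixes farther than `radius_km` from the colony.
#' Trip distance sums the haversine legs between consecutive trip fixes and
#' includes the commute legs that cross the colony-radius boundary. Fixes are
#' optionally clipped to a sampling window (equilibration sample to final
#' sample) before segmentation, truncating partial trips at the boundary.
#'
#' @param fixes Filtered fix table (`time`, `lat`, `lon`).
#' @param colony_latlon `c(lat, lon)` of the colony.
#' @param radius_km Colony radius (km).
#' @param window Optional POSIXct length-2 vector clipping the accounting
#'   window.
#' @return List of class `trip_summary`: `trips` (data.table: start, end,
#'   duration_h, distance_km), `total_distance_km` (TD), `n_trips`,
#'   `time_at_sea_h`, `prop_at_sea`.
#' @export
segment_trips <- function(fixes, colony_latlon, radius_km = 0.5, window = NULL) {
  f <- as.data.frame(fixes)
  if (!is.null(window)) {
    f <- f[f$time >= window[1] & f$time <= window[2], , drop = FALSE]
  }
  n <- nrow(f)
  empty <- list(trips = data.table::data.table(start = as.POSIXct(character()),
                                               end = as.POSIXct(character()),
                                               duration_h = numeric(),
                                               distance_km = numeric()),
                total_distance_km = 0, n_trips = 0L,
                time_at_sea_h = 0, prop_at_sea = 0)
  class(empty) <- "trip_summary"
  if (n < 2L) return(empty)

  at_sea <- haversine_km(f$lat, f$lon, colony_latlon[1], colony_latlon[2]) > radius_km
  if (!any(at_sea)) return(empty)

  r <- rle(at_sea)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trips <- lapply(which(r$values), function(b) {
    i0 <- max(1L, starts[b] - 1L)      # include commute legs across the boundary
    i1 <- min(n, ends[b] + 1L)
    idx <- i0:i1
    d <- sum(haversine_km(f$lat[idx[-length(idx)]], f$lon[idx[-length(idx)]],
                          f$lat[idx[-1]], f$lon[idx[-1]]))
    data.table::data.table(
      start = f$time[i0], end = f$time[i1],
      duration_h = as.numeric(difftime(f$time[i1], f$time[i0], units = "hours")),
      distance_km = d)
  })
  trips <- data.table::rbindlist(trips)
  span_h <- as.numeric(difftime(f$time[n], f$time[1], units = "hours"))
  out <- list(trips = trips,
              total_distance_km = sum(trips$distance_km),
              n_trips = nrow(trips),
              time_at_sea_h = sum(trips$duration_h),
              prop_at_sea = if (span_h > 0) sum(trips$duration_h) / span_h else 0)
  class(out) <- "trip_summary"
  out
}
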