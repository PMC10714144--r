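#' Cluster spectral frames with k-means
#'
#' Standardises the per-second wavelet spectra (plus the dynamic RMS) and
#' partitions them with k-means. Over-clustering (k larger than the number of
#' behaviours) followed by a many-to-one mapping onto behaviours is the
#' standard workflow for unsupervised accelerometry ethograms.
#'
#' @param frames A `spectral_frames` object from [wavelet_frames()].
#' @param k Number of clusters (default 12, mapped onto 6 behaviours later).
#' @param seed RNG seed for reproducible clustering.
#' @return Integer vector of cluster labels, one per second.
#' @export
cluster_frames <- function(frames, k = 12, seed = 42L) {
  feats <- cbind(frames$spectrum, rms = frames$rms_dynamic)
  if (k > nrow(feats)) stop("k exceeds the number of frames")
  feats <- scale(feats)
  feats[!is.finite(feats)] <- 0   # zero-variance columns
  set.seed(seed)
  km <- stats::kmeans(feats, centers = k, nstart = 5, iter.max = 100)
  km$cluster
}

#' Map clusters onto provisional behaviours
#'
#' Applies ordered heuristics to per-cluster statistics: clusters whose mean
#' dynamic RMS exceeds `dive_rms_g` are high-amplitude bursts and become
#' provisional dives; remaining clusters with a spectral peak inside the
#' wingbeat band and appreciable amplitude become flapping; everything else
#' is `low` (gliding vs resting, disambiguated later by GPS speed and
#' location). The cluster-to-behaviour mapping table is attached as an
#' attribute for logging.
#'
#' @param clusters Integer cluster labels from [cluster_frames()].
#' @param frames The matching `spectral_frames`.
#' @param dive_rms_g RMS threshold (g) above which a cluster is a dive burst.
#' @param flap_band Wingbeat frequency band (Hz).
#' @param flap_min_rms Minimum mean RMS (g) for a flapping cluster.
#' @return Character vector of provisional labels in
#'   `c("dive", "flapping", "low")` with attribute `mapping` (data.table of
#'   per-cluster statistics and assigned label).
#' @export
assign_behaviours <- function(clusters, frames, dive_rms_g = 1.5,
                              flap_band = c(2.5, 5), flap_min_rms = 0.3) {
  ids <- sort(unique(clusters))
  if (length(ids) < max(clusters))
    warning("empty cluster(s): no behaviour assigned to them")
  stats_tab <- data.table::data.table(
    cluster = ids,
    mean_rms = vapply(ids, function(i) mean(frames$rms_dynamic[clusters == i]),
                      numeric(1)),
    peak_freq = vapply(ids, function(i) {
      frames$freqs[which.max(colMeans(frames$spectrum[clusters == i, ,
                                                      drop = FALSE]))]
    }, numeric(1))
  )
  lab <- ifelse(stats_tab$mean_rms >= dive_rms_g, "dive",
         ifelse(stats_tab$peak_freq >= flap_band[1] &
                stats_tab$peak_freq <= flap_band[2] &
                stats_tab$mean_rms >= flap_min_rms, "flapping", "low"))
  stats_tab$behaviour <- lab
  out <- lab[match(clusters, ids)]
  attr(out, "mapping") <- stats_tab
  out
}

#' Correct provisional labels with GPS speed and location rules
#'
#' Low-dynamic seconds moving at or above `glide_speed_kmh` become gliding;
#' slower low-dynamic seconds are resting, split into resting on land (within
#' the colony radius) and resting at sea. Seconds with no GPS overlap are
#' set to `NA` and excluded from activity budgets. The pass is idempotent.
#'
#' @param labels Provisional labels from [assign_behaviours()] (values
#'   `dive`, `flapping`, `low`, or already-final behaviours).
#' @param speed_kmh Travelling speed (km h^-1) on the 1-s grid (NA where GPS
#'   is missing).
#' @param dist_colony_km Distance from the colony (km) on the 1-s grid.
#' @param glide_speed_kmh Speed threshold separating gliding from resting.
#' @param colony_radius_km Radius (km) within which a resting bird is on land.
#' @return Character labels with `low` resolved; attribute `n_flagged` counts
#'   seconds dropped for missing GPS.
#' @export
apply_rules <- function(labels, speed_kmh, dist_colony_km,
                        glide_speed_kmh = 10, colony_radius_km = 0.5) {
  stopifnot(length(speed_kmh) == length(labels),
            length(dist_colony_km) == length(labels))
  out <- as.character(labels)
  low <- out %in% c("low", "gliding", "rest_sea", "rest_land")
  miss <- low & (is.na(speed_kmh) | is.na(dist_colony_km))
  out[low & !miss & speed_kmh >= glide_speed_kmh] <- "gliding"
  rest <- low & !miss & speed_kmh < glide_speed_kmh
  out[rest & dist_colony_km <= colony_radius_km] <- "rest_land"
  out[rest & dist_colony_km > colony_radius_km] <- "rest_sea"
  out[miss] <- NA_character_
  attr(out, "n_flagged") <- sum(miss)
  out
}

#' Cluster-consensus refinement of the gliding vs sea-resting split
#'
#' GPS speed at a 2-min fix interval is coarse relative to 1-s behaviour, so
#' the per-second speed rule smears flight speed into resting seconds near
#' behavioural transitions. Since seconds in the same spectral cluster share
#' one acceleration regime, each cluster's gliding/rest_sea members are
#' relabelled to that cluster's majority of the two -- a smoothing pass that
#' keeps the speed rule's decision but applies it at the cluster level.
#' Clusters without a clear majority (below `purity`) are left on their
#' per-second labels, so a genuinely mixed cluster is never flipped
#' wholesale. Dive, flapping and on-land labels are untouched.
#'
#' @param labels Labels after [apply_rules()].
#' @param clusters Integer cluster labels from [cluster_frames()].
#' @param purity Minimum majority fraction required to relabel a cluster.
#' @return Relabelled character vector.
#' @export
consensus_glide_rest <- function(labels, clusters, purity = 0.7) {
  stopifnot(length(labels) == length(clusters))
  out <- as.character(labels)
  amb <- !is.na(out) & out %in% c("gliding", "rest_sea")
  for (cl in unique(clusters[amb])) {
    m <- amb & clusters == cl
    frac_glide <- mean(out[m] == "gliding")
    if (frac_glide >= purity) out[m] <- "gliding"
    else if (frac_glide <= 1 - purity) out[m] <- "rest_sea"
  }
  out
}

#' Split dives into plunge and duck dives
#'
#' Merges contiguous dive seconds (gaps up to `merge_gap_s` belong to the
#' same bout) and assigns each bout a type from the behaviour preceding it:
#' a bird in flight (flapping or gliding) within `lookback_s` before the
#' bout performed a plunge dive; a bird resting on the surface performed a
#' duck dive. Any flight label inside the look-back window counts as flight,
#' making the decision robust to the mixed spectral frame at the
#' flight-to-dive boundary (surface rest lasts minutes, so flight seconds
#' shortly before a genuine duck dive are rare). Bouts with no preceding
#' non-dive label (e.g. at the trace start) cannot be typed from context and
#' default to plunge diving, with a warning.
#'
#' @param labels Labels containing `dive` seconds (other values final).
#' @param merge_gap_s Maximum gap (s) merged into one bout.
#' @param lookback_s How far back (s) to look for the preceding behaviour.
#' @param guard_s Seconds immediately before the bout skipped by the
#'   look-back: the wavelet support of the dive burst contaminates the
#'   adjacent frames, so their labels are unreliable.
#' @return Labels with dives typed; attributes `n_plunge`, `n_duck` count
#'   bouts.
#' @export
classify_dives <- function(labels, merge_gap_s = 2, lookback_s = 5,
                           guard_s = 2) {
  out <- as.character(labels)
  is_dive <- !is.na(out) & out %in% c("dive", "plunge_dive", "duck_dive")
  if (!any(is_dive)) {
    attr(out, "n_plunge") <- 0L; attr(out, "n_duck") <- 0L
    return(out)
  }
  # merge short gaps between dive seconds into the bout
  r <- rle(is_dive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap_runs <- which(!r$values & r$lengths <= merge_gap_s)
  for (g in gap_runs) {
    if (g > 1L && g < length(r$values))
      is_dive[starts[g]:ends[g]] <- TRUE
  }
  r <- rle(is_dive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_plunge <- 0L; n_duck <- 0L; n_untyped <- 0L
  for (b in which(r$values)) {
    hi <- starts[b] - 1L - guard_s
    look <- if (hi >= 1L) max(1L, hi - lookback_s + 1L):hi else integer(0)
    prev <- out[look]
    prev <- prev[!is.na(prev) & !(prev %in% c("dive", "plunge_dive", "duck_dive"))]
    type <- if (length(prev)) {
      # rest takes priority: coarse GPS speed smears flight into genuinely
      # resting seconds far more often than the reverse
      if (any(prev == "rest_sea")) "duck_dive"
      else if (any(prev %in% c("flapping", "gliding"))) "plunge_dive"
      else "plunge_dive"   # rest_land before a dive should not occur; treat as plunge
    } else {
      n_untyped <- n_untyped + 1L
      "plunge_dive"
    }
    out[starts[b]:ends[b]] <- type
    if (type == "plunge_dive") n_plunge <- n_plunge + 1L else n_duck <- n_duck + 1L
  }
  if (n_untyped > 0L)
    warning(sprintf("%d dive bout(s) with no preceding behaviour; defaulted to plunge", n_untyped))
  attr(out, "n_plunge") <- n_plunge
  attr(out, "n_duck") <- n_duck
  out
}

#' Activity budget from an ethogram
#'
#' Tallies per-behaviour time, summed VeDBA and time proportions, counts
#' dive bouts and computes dive rates per hour at sea. Seconds with `NA`
#' labels (missing GPS overlap) are excluded.
#'
#' @param behaviour Character or factor per-second behaviour labels over
#'   [behaviour_levels()].
#' @param vedba_1s Per-second mean VeDBA (g), same length.
#' @return List of class `activity_budget`: `table` (data.table: behaviour,
#'   `T_h` hours, `vedba_sum` g s, `proportion`), `n_plunge`, `n_duck`,
#'   `dive_rate` (bouts per at-sea hour), `time_at_sea_h`, `deployment_h`.
#' @export
budget <- function(behaviour, vedba_1s) {
  stopifnot(length(behaviour) == length(vedba_1s))
  beh <- as.character(behaviour)
  ok <- !is.na(beh)
  tab <- data.table::data.table(behaviour = factor(beh[ok], levels = BEHAVIOURS),
                                vedba = vedba_1s[ok])
  agg <- tab[, list(T_h = .N / 3600, vedba_sum = sum(vedba)), by = "behaviour"]
  full <- data.table::data.table(behaviour = factor(BEHAVIOURS, levels = BEHAVIOURS))
  agg <- merge(full, agg, by = "behaviour", all.x = TRUE)
  agg[is.na(agg$T_h), c("T_h", "vedba_sum")] <- 0
  agg$proportion <- agg$T_h / sum(agg$T_h)

  r <- rle(beh[ok])
  n_plunge <- sum(r$values == "plunge_dive", na.rm = TRUE)
  n_duck <- sum(r$values == "duck_dive", na.rm = TRUE)
  t_sea <- sum(agg$T_h[agg$behaviour %in% .at_sea_behaviours])
  structure(list(table = agg, n_plunge = n_plunge, n_duck = n_duck,
                 dive_rate = if (t_sea > 0) (n_plunge + n_duck) / t_sea else 0,
                 time_at_sea_h = t_sea, deployment_h = sum(agg$T_h)),
            class = "activity_budget")
}

#' Full unsupervised ethogram from raw accelerometry and GPS
#'
#' Runs the complete classification chain: static/dynamic separation,
#' per-second VeDBA, 1-s Morlet wavelet frames on the heave axis, k-means
#' clustering, cluster-to-behaviour mapping, GPS speed/location rule
#' corrections and dive typing.
#'
#' @param trace Raw `accel_trace`.
#' @param fixes GPS fix table (`time`, `lat`, `lon`).
#' @param colony_latlon `c(lat, lon)` of the colony.
#' @param start_time POSIXct of the first accelerometer sample.
#' @param window_s Running-mean window (s) for the static component.
#' @param k,seed Clustering parameters, see [cluster_frames()].
#' @param glide_speed_kmh,colony_radius_km Rule thresholds, see
#'   [apply_rules()].
#' @param dive_rms_g Dive-burst threshold, see [assign_behaviours()].
#' @param consensus Apply the cluster-consensus smoothing of the
#'   gliding/rest_sea split ([consensus_glide_rest()]); default `TRUE`.
#' @return data.table: `second`, `behaviour` (factor), `vedba` (g, 1-s mean).
#' @export
classify_ethogram <- function(trace, fixes, colony_latlon,
                              start_time = attr(trace, "start_time"),
                              window_s = 2, k = 12, seed = 42L,
                              glide_speed_kmh = 10, colony_radius_km = 0.5,
                              dive_rms_g = 1.5, consensus = TRUE) {
  rate <- attr(trace, "rate")
  parts <- split_static_dynamic(trace, window_s = window_s, rate = rate)
  ved <- compute_vedba(parts$dynamic)
  v1 <- vedba_per_second(ved)

  frames <- wavelet_frames(parts$dynamic$z, rate)
  cl <- cluster_frames(frames, k = k, seed = seed)
  prov <- assign_behaviours(cl, frames, dive_rms_g = dive_rms_g)

  n_sec <- length(frames$second)
  grid <- gps_on_grid(fixes, start_time, n_sec, colony_latlon)
  lab <- apply_rules(prov, grid$speed_kmh, grid$dist_colony_km,
                     glide_speed_kmh = glide_speed_kmh,
                     colony_radius_km = colony_radius_km)
  if (consensus) lab <- consensus_glide_rest(lab, cl)
  lab <- classify_dives(lab)
  out <- data.table::data.table(
    second = frames$second,
    behaviour = factor(lab, levels = BEHAVIOURS),
    vedba = v1$vedba[match(frames$second, v1$second)]
  )
  attr(out, "n_plunge") <- attr(lab, "n_plunge")
  attr(out, "n_duck") <- attr(lab, "n_duck")
  out
}

#' Interpolate GPS speed and colony distance onto the 1-s grid
#'
#' Each second takes the travelling speed of the GPS leg containing it
#' (piecewise constant: the leg distance divided by its duration), which
#' confines speed smearing to legs that genuinely straddle a behaviour
#' change; positions are interpolated linearly in latitude/longitude
#' (adequate at 2-min spacing) to give the distance from the colony.
#' Seconds more than one fix interval outside the GPS record get `NA`.
#'
#' @param fixes Fix table (`time` POSIXct, `lat`, `lon`).
#' @param start_time POSIXct of second 0.
#' @param n_sec Number of seconds on the grid.
#' @param colony_latlon `c(lat, lon)`.
#' @return data.table: `second`, `speed_kmh`, `dist_colony_km`.
#' @export
gps_on_grid <- function(fixes, start_time, n_sec, colony_latlon) {
  ft <- as.numeric(fixes$time) - as.numeric(start_time)
  secs <- seq_len(n_sec) - 1L
  legs_km <- haversine_km(fixes$lat[-nrow(fixes)], fixes$lon[-nrow(fixes)],
                          fixes$lat[-1], fixes$lon[-1])
  dt_h <- diff(ft) / 3600
  v <- legs_km / dt_h
  leg <- findInterval(secs, ft)
  speed <- v[pmin(pmax(leg, 1L), length(v))]
  lat <- stats::approx(ft, fixes$lat, xout = secs, rule = 2)$y
  lon <- stats::approx(ft, fixes$lon, xout = secs, rule = 2)$y
  dist <- haversine_km(lat, lon, colony_latlon[1], colony_latlon[2])
  interval <- if (length(ft) >= 2) max(diff(ft)) else Inf
  outside <- secs < min(ft) - interval | secs > max(ft) + interval
  speed[outside] <- NA_real_
  dist[outside] <- NA_real_
  data.table::data.table(second = secs, speed_kmh = speed, dist_colony_km = dist)
}
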