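#' Read and write the deployment CSV dialects
#'
#' Plain-CSV interchange for the pipeline's inputs: accelerometry
#' (`time` ISO-8601 UTC, `x_g`, `y_g`, `z_g`), GPS fixes (`time`, `lat`,
#' `lon`) and per-bird isotope records (one row per bird, isotope-record
#' columns). Writers are the exact inverses of the readers.
#'
#' @param trace An `accel_trace`.
#' @param path File path.
#' @name deployment_io
NULL

#' @rdname deployment_io
#' @export
write_accel_csv <- function(trace, path) {
  start <- attr(trace, "start_time")
  out <- data.table::data.table(
    time = format(start + trace$t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
    x_g = trace$x, y_g = trace$y, z_g = trace$z)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname deployment_io
#' @param rate Sampling rate (Hz) to attach.
#' @export
read_accel_csv <- function(path, rate = 25) {
  d <- data.table::fread(path)
  tt <- as.POSIXct(d$time, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  out <- data.table::data.table(t = as.numeric(tt) - as.numeric(tt[1]),
                                x = d$x_g, y = d$y_g, z = d$z_g)
  data.table::setattr(out, "rate", rate)
  data.table::setattr(out, "start_time", tt[1])
  data.table::setattr(out, "class", c("accel_trace", class(out)))
  out
}

#' @rdname deployment_io
#' @param fixes GPS fix table (`time`, `lat`, `lon`).
#' @export
write_gps_csv <- function(fixes, path) {
  out <- data.table::data.table(
    time = format(fixes$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lat = fixes$lat, lon = fixes$lon)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname deployment_io
#' @export
read_gps_csv <- function(path) {
  d <- data.table::fread(path)
  data.table::data.table(
    time = as.POSIXct(d$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lat = d$lat, lon = d$lon)
}

#' @rdname deployment_io
#' @param records Isotope-record table.
#' @export
write_isotopes_csv <- function(records, path) {
  out <- data.table::copy(data.table::as.data.table(records))
  for (cl in c("t_eq", "t_fin"))
    out[[cl]] <- format(out[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname deployment_io
#' @export
read_isotopes_csv <- function(path) {
  d <- data.table::fread(path)
  for (cl in c("t_eq", "t_fin"))
    d[[cl]] <- as.POSIXct(d[[cl]], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  d
}
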