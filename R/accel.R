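#' Separate static and dynamic acceleration
#'
#' The static (gravity/orientation) component of each axis is a centred
#' running mean over `window_s` seconds; the dynamic component is the
#' residual. The window is truncated at trace edges (no padding), so
#' `static + dynamic` reconstructs the input exactly everywhere. Gaps larger
#' than two sample intervals split the trace into segments that are smoothed
#' independently (and flagged with a warning, never silently filled).
#'
#' A calibration warning is emitted when the mean static vector norm falls
#' outside [0.8, 1.2] g.
#'
#' @param trace An `accel_trace` (or data.frame with columns `t`, `x`, `y`,
#'   `z` and a sampling-rate attribute `rate`).
#' @param window_s Smoothing window in seconds (default 2: longer than one
#'   wingbeat period, inside the conventional 1.5-3 s range for dynamic
#'   body acceleration work).
#' @param rate Sampling rate (Hz); taken from the trace attribute if absent.
#' @return List with `static` and `dynamic`, each a data.table with columns
#'   `t`, `x`, `y`, `z` (same rows as the input).
#' @export
split_static_dynamic <- function(trace, window_s = 2, rate = attr(trace, "rate")) {
  if (is.null(rate)) stop("sampling rate not given and not attached to trace")
  if (window_s <= 0) stop("window_s must be positive")
  n <- nrow(trace)
  if (n == 0L) stop("empty trace")
  w <- max(1L, round(window_s * rate))
  if (n < w) stop("trace shorter than the smoothing window")

  segs <- .trace_segments(trace$t, rate)
  if (length(segs) > 1L)
    warning(sprintf("%d gaps > 2 sample intervals: trace split into %d segments",
                    length(segs) - 1L, length(segs)))

  static <- data.table::data.table(t = trace$t,
                                   x = numeric(n), y = numeric(n), z = numeric(n))
  for (s in segs) {
    for (ax in c("x", "y", "z"))
      data.table::set(static, s, ax, .runmean_trunc(trace[[ax]][s], w))
  }
  dynamic <- data.table::data.table(
    t = trace$t, x = trace$x - static$x,
    y = trace$y - static$y, z = trace$z - static$z)

  g_norm <- mean(sqrt(static$x^2 + static$y^2 + static$z^2))
  if (g_norm < 0.8 || g_norm > 1.2)
    warning(sprintf("mean static vector norm %.2f g outside [0.8, 1.2]: check device calibration",
                    g_norm))
  list(static = static, dynamic = dynamic)
}

# indices of contiguous runs; a gap is a step > 2 sample intervals
.trace_segments <- function(t, rate) {
  if (length(t) < 2L) return(list(seq_along(t)))
  gap <- which(diff(t) > 2 / rate + 1e-9)
  bounds <- c(0L, gap, length(t))
  lapply(seq_len(length(bounds) - 1L),
         function(i) (bounds[i] + 1L):bounds[i + 1L])
}

# centred running mean with window truncated at the edges (cumsum-based)
.runmean_trunc <- function(x, w) {
  n <- length(x)
  h_lo <- (w - 1L) %/% 2L
  h_hi <- w - 1L - h_lo
  i <- seq_len(n)
  lo <- pmax(i - h_lo, 1L)
  hi <- pmin(i + h_hi, n)
  S <- c(0, cumsum(x))
  (S[hi + 1L] - S[lo]) / (hi - lo + 1L)
}

#' Per-sample vectorial dynamic body acceleration
#'
#' VeDBA (g) is the Euclidean norm of the three dynamic acceleration
#' components: sqrt(X^2 + Y^2 + Z^2). Preferred over the absolute-sum ODBA
#' for devices that cannot be aligned with the animal's centre of gravity
#' (tail mounts).
#'
#' @param dynamic Dynamic trace (columns `t`, `x`, `y`, `z` in g).
#' @return data.table with columns `t` and `vedba` (g, non-negative).
#' @export
#' @examples
#' compute_vedba(data.frame(t = 0, x = 0.3, y = 0.4, z = 0))$vedba  # 0.5
compute_vedba <- function(dynamic) {
  data.table::data.table(t = dynamic$t,
                         vedba = sqrt(dynamic$x^2 + dynamic$y^2 + dynamic$z^2))
}

#' Overall dynamic body acceleration (absolute-sum variant)
#'
#' Provided as a cross-check only; the calibration pipeline uses VeDBA.
#'
#' @inheritParams compute_vedba
#' @return data.table with columns `t` and `odba` (g).
#' @export
compute_odba <- function(dynamic) {
  data.table::data.table(t = dynamic$t,
                         odba = abs(dynamic$x) + abs(dynamic$y) + abs(dynamic$z))
}

#' Summarise a VeDBA series over a masked period
#'
#' Computes the summed (g s) and mean (g) VeDBA over the samples selected by
#' `mask` -- the whole deployment, the at-sea period, or one behaviour. When
#' the trace contains gaps the statistics are computed per contiguous segment
#' and combined duration-weighted, which for uniform sampling reduces to the
#' overall sum and mean.
#'
#' @param series data.table from [compute_vedba()].
#' @param mask Logical vector selecting samples (default: all).
#' @param rate Sampling rate (Hz), used to convert a per-sample sum into g s.
#' @return Named list: `vedba_sum` (g s), `vedba_mean` (g), `n` samples.
#' @export
summarize_vedba <- function(series, mask = rep(TRUE, nrow(series)), rate = 25) {
  if (length(mask) != nrow(series)) stop("mask length must match series")
  v <- series$vedba[mask]
  if (length(v) == 0L) stop("empty mask: nothing to summarise")
  list(vedba_sum = sum(v) / rate, vedba_mean = mean(v), n = length(v))
}

#' Per-second mean VeDBA
#'
#' Averages a per-sample VeDBA series within each whole second, producing the
#' 1-s resolution series attached to the ethogram.
#'
#' @inheritParams summarize_vedba
#' @return data.table with columns `second` (0-based) and `vedba` (g).
#' @export
vedba_per_second <- function(series) {
  second <- vedba <- NULL
  dt <- data.table::data.table(second = as.integer(floor(series$t)),
                               vedba = series$vedba)
  dt[, list(vedba = mean(vedba)), by = second]
}
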