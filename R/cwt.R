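#' Morlet continuous wavelet transform amplitude
#'
#' FFT-based Morlet (omega0 = 6) CWT of a uniformly sampled signal at a set
#' of analysis frequencies. Scales are mapped to frequencies through the
#' exact Morlet centre frequency, so a pure sinusoid peaks at its own
#' frequency. Long traces are transformed in overlapping chunks (the overlap
#' exceeds the support of the largest wavelet) so memory stays bounded; the
#' result is identical to a whole-trace transform away from the trace ends.
#'
#' @param x Numeric signal (dynamic heave acceleration, g).
#' @param rate Sampling rate (Hz).
#' @param freqs Analysis frequencies (Hz), increasing.
#' @param chunk_len Chunk length in samples for long traces.
#' @return Matrix `length(x)` x `length(freqs)` of wavelet amplitudes.
#' @export
morlet_cwt <- function(x, rate, freqs, chunk_len = 2^17) {
  n <- length(x)
  if (n < 2L) stop("signal too short")
  omega0 <- 6
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs)  # seconds
  pad <- ceiling(10 * max(scales) * rate)                     # wavelet support

  if (n <= chunk_len) return(.cwt_block(x, rate, scales))

  out <- matrix(0, n, length(freqs))
  start <- 1L
  while (start <= n) {
    end <- min(n, start + chunk_len - 1L)
    lo <- max(1L, start - pad)
    hi <- min(n, end + pad)
    blk <- .cwt_block(x[lo:hi], rate, scales)
    out[start:end, ] <- blk[(start - lo + 1L):(end - lo + 1L), , drop = FALSE]
    start <- end + 1L
  }
  out
}

.cwt_block <- function(x, rate, scales) {
  n <- length(x)
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  k <- 0:(nfft - 1)
  omega <- 2 * pi * ifelse(k <= nfft / 2, k, k - nfft) * rate / nfft
  out <- matrix(0, n, length(scales))
  omega0 <- 6
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- sqrt(s * rate) * pi^(-1/4) * exp(-0.5 * (s * omega - omega0)^2)
    psi_hat[omega <= 0] <- 0
    w <- stats::fft(X * psi_hat, inverse = TRUE) / nfft
    out[, j] <- Mod(w[seq_len(n)])
  }
  out
}

#' One-second spectral frames from the heave axis
#'
#' Computes the Morlet CWT of the dynamic heave signal over 0.5-12 Hz and
#' averages the amplitudes within each whole second, yielding one spectral
#' frame per second of trace plus the per-second RMS of the dynamic signal.
#' These frames are the clustering features for behaviour identification.
#'
#' @param heave Dynamic heave-axis signal (g) at `rate` Hz.
#' @param rate Sampling rate (Hz).
#' @param n_freq Number of log-spaced analysis frequencies.
#' @param frange Frequency range (Hz).
#' @return List of class `spectral_frames`: `second` (0-based), `spectrum`
#'   (matrix seconds x frequencies), `rms_dynamic` (g), `freqs` (Hz).
#' @export
wavelet_frames <- function(heave, rate, n_freq = 16, frange = c(0.5, 12)) {
  n_sec <- floor(length(heave) / rate)
  if (n_sec < 1L) stop("trace shorter than one second")
  freqs <- exp(seq(log(frange[1]), log(frange[2]), length.out = n_freq))
  m <- length(heave)
  amp <- morlet_cwt(heave, rate, freqs)
  sec <- floor((seq_len(m) - 1L) / rate)
  keep <- sec < n_sec
  grp <- sec[keep] + 1L
  spectrum <- apply(amp[keep, , drop = FALSE], 2,
                    function(col) tapply(col, grp, mean))
  spectrum <- matrix(spectrum, nrow = n_sec)
  rms <- sqrt(as.numeric(tapply(heave[keep]^2, grp, mean)))
  structure(list(second = seq_len(n_sec) - 1L, spectrum = spectrum,
                 rms_dynamic = rms, freqs = freqs),
            class = "spectral_frames")
}
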