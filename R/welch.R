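# Averaged-periodogram (Welch) spectral estimation built on stats::fft.
# One-sided density scaling: sum(psd) * df recovers the variance of a
# zero-mean signal (Parseval). Segments are Hann-windowed, mean-detrended,
# 50% overlapped by default.

default_segment <- function(n) {
  target <- min(1024, floor(n / 4))
  if (target < 8) return(min(n, 8))
  2^floor(log2(target))
}

# Core segment-averaged auto/cross spectra. With y = NULL returns the PSD of
# x; otherwise the cross-spectral density S_xy = <conj(X) Y>.
welch_core <- function(xv, yv = NULL, fs, segment_length = NULL,
                       overlap = 0.5, window = c("hann", "rect")) {
  window <- match.arg(window)
  n <- length(xv)
  if (is.null(segment_length)) segment_length <- default_segment(n)
  segment_length <- check_count(segment_length, "segment_length", min = 2)
  if (segment_length > n) abort("`segment_length` exceeds the signal length.")
  hop <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  w <- if (window == "hann") hann_window(segment_length) else
    rep(1, segment_length)
  scale <- fs * sum(w^2)

  fx <- frame_segments_fft(xv, segment_length, hop, w)
  fy <- if (is.null(yv)) fx else frame_segments_fft(yv, segment_length, hop, w)
  sxy <- rowMeans(Conj(fx) * fy) / scale

  half <- floor(segment_length / 2) + 1L
  s <- sxy[seq_len(half)]
  # fold negative frequencies into the one-sided density
  dbl <- seq(2L, half - if (segment_length %% 2 == 0) 1L else 0L)
  s[dbl] <- 2 * s[dbl]
  list(frequency = (seq_len(half) - 1) * fs / segment_length,
       spectrum = s, n_segments = ncol(fx), segment_length = segment_length)
}

frame_segments_fft <- function(v, seg, hop, w) {
  m <- frame_signal(v, seg, hop)
  m <- sweep(m, 2, colMeans(m))          # per-segment mean detrend
  stats::mvfft(m * w)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann window, 50% segment overlap and
#' per-segment mean removal. Density scaling: for a zero-mean signal,
#' `sum(power) * df` approximates its variance.
#'
#' @param x Signal: a data frame with `time`/`value` columns or a numeric
#'   vector (then `sample_rate` is required).
#' @param segment_length Samples per segment; default
#'   `min(1024, n/4)` rounded down to a power of two.
#' @param overlap Fractional overlap between consecutive segments.
#' @param window `"hann"` (default) or `"rect"`.
#' @param sample_rate Sampling frequency in Hz for vector input.
#' @return A tibble of class `psd_tbl` with columns `frequency` (Hz) and
#'   `power` (units^2/Hz), and `n_segments` attribute.
#' @examples
#' x <- sin(2 * pi * 50 * seq(0, 1, by = 1e-3))
#' p <- welch_psd(x, sample_rate = 1000)
#' p$frequency[which.max(p$power)] # ~ 50 Hz
#' @export
welch_psd <- function(x, segment_length = NULL, overlap = 0.5,
                      window = c("hann", "rect"), sample_rate = NULL) {
  s <- as_sig(x, sample_rate)
  res <- welch_core(s$values, NULL, s$fs, segment_length, overlap,
                    match.arg(window))
  out <- tibble(frequency = res$frequency, power = pmax(Re(res$spectrum), 0))
  attr(out, "n_segments") <- res$n_segments
  attr(out, "sample_rate") <- s$fs
  class(out) <- c("psd_tbl", class(out))
  out
}

#' Spectrogram (short-time Fourier transform magnitude)
#'
#' Hann-windowed STFT magnitude on a uniform time-frequency grid.
#'
#' @inheritParams welch_psd
#' @param window_length Samples per analysis window.
#' @param hop Samples between window starts (> 0).
#' @return A long tibble of class `stft_tbl` with columns `time` (window
#'   centre, s), `frequency` (Hz) and `magnitude`.
#' @export
spectrogram <- function(x, window_length = NULL, hop = NULL,
                        sample_rate = NULL) {
  s <- as_sig(x, sample_rate)
  n <- length(s$values)
  if (is.null(window_length)) window_length <- default_segment(n)
  window_length <- check_count(window_length, "window_length", min = 2)
  if (window_length > n) abort("`window_length` exceeds the signal length.")
  if (is.null(hop)) hop <- max(1L, window_length %/% 4)
  if (hop <= 0) abort("`hop` must be positive.")
  w <- hann_window(window_length)
  m <- frame_signal(s$values, window_length, as.integer(hop))
  fx <- stats::mvfft(m * w)
  half <- floor(window_length / 2) + 1L
  mag <- abs(fx[seq_len(half), , drop = FALSE])
  centers <- s$t0 + ((seq_len(ncol(m)) - 1) * hop + window_length / 2) / s$fs
  out <- tidyr::expand_grid(
    time = centers,
    frequency = (seq_len(half) - 1) * s$fs / window_length
  )
  out$magnitude <- as.vector(mag)      # column-major: frequency fastest
  out <- out[order(out$time, out$frequency), ]
  class(out) <- c("stft_tbl", class(out))
  out
}
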