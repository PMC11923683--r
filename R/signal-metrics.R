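# Input/output signal metrics: SNR, RMSE/MAE/PSNR/Pearson, cross-correlation,
# band powers, transfer and impulse response, bispectrum, paired t-test, and
# the combined metrics report.

#' Signal-to-noise ratio in dB
#'
#' Treats the discrepancy `output - input` as the noise:
#' `SNR = 10 log10(mean(input^2) / mean((output - input)^2))`.
#' Identical signals give `Inf` (zero noise power), flagged via the
#' `zero_noise` attribute.
#'
#' @param input,output Equal-length signals (data frames with
#'   `time`/`value`, or numeric vectors with `sample_rate`).
#' @param sample_rate Sampling frequency for vector input.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_db <- function(input, output, sample_rate = NULL) {
  p <- as_sig_pair(input, output, sample_rate %||% 1)
  p_sig <- mean(p$x$values^2)
  p_noise <- mean((p$y$values - p$x$values)^2)
  if (p_noise == 0) {
    return(structure(Inf, zero_noise = TRUE))
  }
  10 * log10(p_sig / p_noise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Error metrics between input and output
#'
#' RMSE, MAE, PSNR (`20 log10(max|input| / RMSE)`) and the Pearson
#' correlation coefficient, computed sample-wise on the pair.
#'
#' @inheritParams snr_db
#' @return A one-row tibble with columns `rmse`, `mae`, `psnr_db`,
#'   `pearson_r`.
#' @export
error_metrics <- function(input, output, sample_rate = NULL) {
  p <- as_sig_pair(input, output, sample_rate %||% 1)
  d <- p$y$values - p$x$values
  rmse <- sqrt(mean(d^2))
  mae <- mean(abs(d))
  psnr <- if (rmse == 0) Inf else 20 * log10(max(abs(p$x$values)) / rmse)
  if (stats::sd(p$x$values) == 0) {
    abort("Pearson correlation undefined for a zero-variance input.")
  }
  # a constant output leaves the correlation undefined but the error
  # metrics well-posed
  r <- if (stats::sd(p$y$values) == 0) NA_real_ else
    stats::cor(p$x$values, p$y$values)
  tibble(rmse = rmse, mae = mae, psnr_db = psnr, pearson_r = r)
}

#' Cross-correlation between two signals
#'
#' Full discrete cross-correlation over all lags. The normalized variant
#' removes the means and divides by `sqrt(sum(x^2) * sum(y^2))` (coefficient
#' normalization), bounding values in [-1, 1]. Positive lag means the
#' second signal is delayed relative to the first.
#'
#' @inheritParams snr_db
#' @param x,y The two signals.
#' @param normalize Normalize to correlation coefficients (default TRUE).
#' @return A tibble of class `xcorr_tbl` with columns `lag` (s) and `value`,
#'   plus attributes `max_value` and `lag_at_max` (s).
#' @export
cross_correlation <- function(x, y, normalize = TRUE, sample_rate = NULL) {
  p <- as_sig_pair(x, y, sample_rate %||% 1)
  xv <- p$x$values
  yv <- p$y$values
  if (normalize) {
    xv <- xv - mean(xv)
    yv <- yv - mean(yv)
    denom <- sqrt(sum(xv^2) * sum(yv^2))
    if (denom == 0) abort("normalized cross-correlation undefined for an all-constant signal.")
  }
  n <- length(xv)
  # r[k] = sum_t x[t] y[t + k]; convolve(open) of x and rev(y)
  vals <- rev(convolve(xv, yv, type = "open"))
  lags <- (-(n - 1)):(n - 1)
  if (normalize) vals <- vals / denom
  i_max <- which.max(vals)
  out <- tibble(lag = lags / p$x$fs, value = vals)
  attr(out, "max_value") <- vals[i_max]
  attr(out, "lag_at_max") <- lags[i_max] / p$x$fs
  class(out) <- c("xcorr_tbl", class(out))
  out
}

#' Welch power at specific frequencies
#'
#' Evaluates the Welch PSD at the bin nearest each requested frequency
#' (e.g. the Fibonacci tone set 144, 233, 377, 610, 987 Hz).
#'
#' @inheritParams welch_psd
#' @param freqs Frequencies in Hz, all below Nyquist.
#' @return A tibble with columns `frequency` (requested), `bin_frequency`
#'   (nearest PSD bin) and `power` (units^2/Hz).
#' @export
power_at_frequencies <- function(x, freqs, segment_length = NULL,
                                 sample_rate = NULL) {
  s <- as_sig(x, sample_rate)
  if (any(freqs >= s$fs / 2) || any(freqs < 0)) {
    abort("`freqs` must lie in [0, Nyquist).")
  }
  psd <- welch_psd(s$values, segment_length = segment_length,
                   sample_rate = s$fs)
  idx <- vapply(freqs, function(f) which.min(abs(psd$frequency - f)),
                integer(1))
  tibble(frequency = freqs, bin_frequency = psd$frequency[idx],
         power = psd$power[idx])
}

#' Empirical frequency response H(f)
#'
#' Welch estimate `H(f) = S_xy(f) / (S_xx(f) + eps * max(S_xx))`, the
#' cross-spectrum over the (regularized) input auto-spectrum. For
#' `output = a * input` the magnitude is `a` with zero phase at every
#' excited frequency; a pure delay d gives phase slope `-2 pi f d`.
#'
#' @inheritParams snr_db
#' @param regularization Relative additive regularization `eps` of the
#'   denominator (default 1e-8).
#' @param segment_length Welch segment length.
#' @param window Welch window (`"hann"`, or `"rect"` for bias-free
#'   single-segment estimates).
#' @return A tibble of class `freqresp_tbl` with columns `frequency`,
#'   `response` (complex), `magnitude`, `phase_rad`.
#' @export
frequency_response <- function(input, output, regularization = 1e-8,
                               segment_length = NULL, sample_rate = NULL,
                               window = c("hann", "rect")) {
  window <- match.arg(window)
  p <- as_sig_pair(input, output, sample_rate %||% 1)
  sxx <- welch_core(p$x$values, NULL, p$x$fs, segment_length, window = window)
  sxy <- welch_core(p$x$values, p$y$values, p$x$fs, segment_length,
                    window = window)
  den <- Re(sxx$spectrum) + regularization * max(Re(sxx$spectrum))
  h <- sxy$spectrum / den
  out <- tibble(frequency = sxx$frequency, response = h,
                magnitude = Mod(h), phase_rad = Arg(h))
  attr(out, "sample_rate") <- p$x$fs
  class(out) <- c("freqresp_tbl", class(out))
  out
}

#' Impulse response from a frequency response
#'
#' Inverse DFT of the Hermitian extension of a one-sided `H(f)` defined on a
#' uniform frequency grid starting at 0, yielding a real time-domain kernel.
#'
#' @param H A `freqresp_tbl` from [frequency_response()], or any data frame
#'   with `frequency` and complex `response` columns on a uniform grid.
#' @return A tibble with columns `time` (s) and `value` (kernel h(t)).
#' @export
impulse_response <- function(H) {
  f <- H$frequency
  h <- H$response
  df <- diff(f)
  if (length(f) < 2 || f[1] != 0 || any(abs(df - df[1]) > 1e-9 * df[1])) {
    abort("`H` must be on a uniform frequency grid starting at 0.")
  }
  half <- length(h)
  nfft <- 2L * (half - 1L)            # assume even-length origin
  full <- complex(length.out = nfft)
  full[seq_len(half)] <- h
  full[half] <- Re(h[half])           # Nyquist bin must be real
  full[1] <- Re(h[1])
  full[nfft - seq_len(half - 2) + 1] <- Conj(h[seq_len(half - 2) + 1])
  kernel <- Re(fft(full, inverse = TRUE)) / nfft
  fs <- 2 * f[length(f)]
  tibble(time = (seq_len(nfft) - 1) / fs, value = kernel)
}

#' Direct bispectrum estimate
#'
#' Segment-averaged third-order spectrum
#' `B(f1, f2) = <X(f1) X(f2) conj(X(f1 + f2))>`, whose magnitude peaks where
#' frequency pairs are quadratically phase-coupled (f1, f2 and f1+f2 present
#' with locked phases). Random-phase or Gaussian signals average toward 0.
#'
#' @inheritParams welch_psd
#' @param segment_length Samples per segment; the signal must be at least 4
#'   segments long.
#' @return A long tibble of class `bispec_tbl` with columns `f1`, `f2` (Hz)
#'   and `magnitude`, covering `f1, f2 >= 0, f1 + f2 <= Nyquist`.
#' @export
bispectrum <- function(x, segment_length = 128, sample_rate = NULL) {
  s <- as_sig(x, sample_rate)
  segment_length <- check_count(segment_length, "segment_length", min = 8)
  if (length(s$values) < 4 * segment_length) {
    abort("signal must be at least 4 segments long.")
  }
  w <- hann_window(segment_length)
  fx <- frame_segments_fft(s$values, segment_length, segment_length, w)
  half <- segment_length %/% 2 + 1L
  n_seg <- ncol(fx)
  acc <- matrix(0 + 0i, half, half)
  for (k in seq_len(n_seg)) {
    X <- fx[, k]
    Xh <- X[seq_len(half)]
    outerXX <- outer(Xh, Xh)
    i_sum <- outer(seq_len(half) - 1L, seq_len(half) - 1L, `+`)  # bin of f1+f2
    valid <- i_sum <= segment_length %/% 2
    conj_sum <- matrix(0 + 0i, half, half)
    conj_sum[valid] <- Conj(X[i_sum[valid] + 1L])
    acc <- acc + outerXX * conj_sum
  }
  B <- abs(acc) / n_seg
  freqs <- (seq_len(half) - 1) * s$fs / segment_length
  out <- tidyr::expand_grid(f1 = freqs, f2 = freqs)
  out$magnitude <- as.vector(t(B))   # row-major: f2 fastest within f1
  keep <- out$f1 + out$f2 <= s$fs / 2
  out <- out[keep, ]
  class(out) <- c("bispec_tbl", class(out))
  out
}

#' Paired t-test between input and output samples
#'
#' Two-sided paired t-test on the sample pairs, as used alongside the other
#' input/output metrics. Zero-variance differences (e.g. a pure constant
#' offset) are degenerate: the p-value is reported as 0 with a
#' `degenerate` attribute, except for identical signals, which return 1.
#'
#' @inheritParams snr_db
#' @return The p-value (possibly with a `degenerate` attribute).
#' @export
paired_ttest <- function(input, output, sample_rate = NULL) {
  p <- as_sig_pair(input, output, sample_rate %||% 1)
  if (length(p$x$values) < 3) abort("need at least 3 sample pairs.")
  d <- p$y$values - p$x$values
  if (stats::sd(d) == 0) {
    pv <- if (all(d == 0)) 1 else 0
    return(structure(pv, degenerate = TRUE))
  }
  stats::t.test(p$y$values, p$x$values, paired = TRUE)$p.value
}

#' Combined input/output metrics report
#'
#' One-row tibble collecting every summary metric for a stimulus/response
#' pair: means and SDs, SNR, RMSE, MAE, PSNR, Pearson r, the normalized
#' cross-correlation peak and its lag, the paired t-test p-value, and
#' (optionally) Welch power at a set of probe frequencies.
#'
#' @inheritParams snr_db
#' @param fib_freqs Optional probe frequencies (Hz) for band powers; powers
#'   are returned in the `band_power` list-column.
#' @return A one-row tibble of class `metrics_report`.
#' @export
signal_report <- function(input, output, fib_freqs = NULL,
                          sample_rate = NULL) {
  p <- as_sig_pair(input, output, sample_rate %||% 1)
  em <- error_metrics(input, output, sample_rate)
  xc <- cross_correlation(input, output, sample_rate = sample_rate)
  out <- tibble(
    mean_in = mean(p$x$values), sd_in = stats::sd(p$x$values),
    mean_out = mean(p$y$values), sd_out = stats::sd(p$y$values),
    snr_db = as.numeric(snr_db(input, output, sample_rate)),
    rmse = em$rmse, mae = em$mae, psnr_db = em$psnr_db,
    pearson_r = em$pearson_r,
    max_xcorr = attr(xc, "max_value"),
    lag_at_max = attr(xc, "lag_at_max"),
    ttest_p = as.numeric(paired_ttest(input, output, sample_rate))
  )
  if (!is.null(fib_freqs)) {
    out$band_power <- list(power_at_frequencies(input, fib_freqs,
                                                sample_rate = sample_rate))
  }
  class(out) <- c("metrics_report", class(out))
  out
}
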