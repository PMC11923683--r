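# Histogram (plug-in) information measures: entropy, mutual information,
# transfer entropy, band-limited variants, magnitude-squared coherence and
# transfer efficiency. All information quantities are in bits.

bin_index <- function(v, n_bins, range = NULL) {
  if (is.null(range)) range <- range(v)
  if (range[1] == range[2]) return(rep(1L, length(v)))     # constant signal
  b <- findInterval(v, seq(range[1], range[2], length.out = n_bins + 1),
                    rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(b)
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

joint_counts <- function(ix, iy, n_bins) {
  tabulate((iy - 1L) * n_bins + ix, nbins = n_bins * n_bins) |>
    matrix(nrow = n_bins)
}

#' Histogram mutual information
#'
#' Plug-in mutual information `I(X;Y)` in bits from a joint equal-width
#' histogram over the data ranges:
#' `I = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`. Nonnegative and symmetric
#' in its arguments. A constant input occupies a single bin and yields 0 by
#' convention. The plug-in estimator is biased upward by roughly
#' `(n_bins - 1)^2 / (2 N ln 2)` bits under independence; the optional
#' Miller-Madow correction subtracts the analogous entropy biases.
#'
#' @param x,y Equal-length numeric vectors or `time`/`value` data frames.
#' @param n_bins Bins per axis (default 16), or `"fd"` for a
#'   Freedman-Diaconis choice (shared by both axes, capped at 64).
#' @param correction `"none"` (plain plug-in, default) or `"miller-madow"`.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, n_bins = 16,
                               correction = c("none", "miller-madow")) {
  correction <- match.arg(correction)
  xv <- if (is.data.frame(x)) x$value else as.numeric(x)
  yv <- if (is.data.frame(y)) y$value else as.numeric(y)
  if (length(xv) != length(yv)) abort("`x` and `y` must have the same length.")
  n_bins <- resolve_bins(n_bins, xv, yv)
  if (length(xv) < n_bins) abort("need at least `n_bins` samples.")
  ix <- bin_index(xv, n_bins)
  iy <- bin_index(yv, n_bins)
  jc <- joint_counts(ix, iy, n_bins)
  N <- length(xv)
  pj <- jc / N
  mi <- entropy_bits(rowSums(pj)) + entropy_bits(colSums(pj)) -
    entropy_bits(as.vector(pj))
  if (correction == "miller-madow") {
    kx <- sum(rowSums(jc) > 0)
    ky <- sum(colSums(jc) > 0)
    kxy <- sum(jc > 0)
    mi <- mi + (kx - 1) / (2 * N * log(2)) + (ky - 1) / (2 * N * log(2)) -
      (kxy - 1) / (2 * N * log(2))
  }
  max(mi, 0)
}

resolve_bins <- function(n_bins, ...) {
  if (identical(n_bins, "fd")) {
    vs <- list(...)
    nb <- max(vapply(vs, function(v) {
      h <- 2 * stats::IQR(v) / length(v)^(1 / 3)
      if (h <= 0) return(1L)
      as.integer(ceiling(diff(range(v)) / h))
    }, integer(1)))
    return(max(2L, min(nb, 64L)))
  }
  check_count(n_bins, "n_bins", min = 2)
}

#' Channel-capacity bound on mutual information
#'
#' The Shannon bound `I_max = log2(1 + SNR)` with the SNR given either on a
#' linear or a dB scale.
#'
#' @param snr Signal-to-noise ratio.
#' @param scale `"db"` or `"linear"`.
#' @return `I_max` in bits.
#' @examples
#' channel_capacity_bound(1, scale = "linear") # 1 bit
#' @export
channel_capacity_bound <- function(snr, scale = c("db", "linear")) {
  scale <- match.arg(scale)
  lin <- if (scale == "db") 10^(snr / 10) else snr
  if (any(lin <= -1)) abort("linear SNR must exceed -1.")
  log2(1 + lin)
}

#' Information transfer efficiency
#'
#' `eta = 100 * I / I_max`, the measured mutual information as a percentage
#' of the channel-capacity bound.
#'
#' @param mi_bits Measured mutual information (bits).
#' @param mi_max_bits Capacity bound (bits, > 0).
#' @return Efficiency in percent.
#' @examples
#' transfer_efficiency(0.0801, 1.23) # ~ 6.5
#' @export
transfer_efficiency <- function(mi_bits, mi_max_bits) {
  if (any(mi_max_bits <= 0)) abort("`mi_max_bits` must be positive.")
  100 * mi_bits / mi_max_bits
}

#' Histogram transfer entropy
#'
#' Plug-in transfer entropy `T(X -> Y)` with embedding `k = l = history`
#' (unit lag): the extra predictability of `y[t+1]` from `x[t]`'s history
#' beyond `y[t]`'s own history, in bits. Estimated from equal-width
#' histogram bins on each variable:
#' `T = sum p(y+, y, x) log2( p(y+ | y, x) / p(y+ | y) )`.
#'
#' @inheritParams mutual_information
#' @param history Embedding length for both signals (default 1).
#' @return Transfer entropy in bits (nonnegative up to estimator noise).
#' @export
transfer_entropy <- function(x, y, n_bins = 16, history = 1) {
  xv <- if (is.data.frame(x)) x$value else as.numeric(x)
  yv <- if (is.data.frame(y)) y$value else as.numeric(y)
  if (length(xv) != length(yv)) abort("`x` and `y` must have the same length.")
  history <- check_count(history, "history")
  n <- length(xv)
  if (n < history + 2) abort("series too short for the requested history.")
  n_bins <- resolve_bins(n_bins, xv, yv)
  ix <- bin_index(xv, n_bins)
  iy <- bin_index(yv, n_bins)
  t_idx <- seq(history + 1L, n)        # predict y[t] from histories ending t-1
  key <- function(idx_mat) {
    # collapse a (rows = time, cols = lags) integer matrix to one symbol
    out <- idx_mat[, 1]
    if (ncol(idx_mat) > 1) {
      for (j in 2:ncol(idx_mat)) out <- (out - 1L) * n_bins + idx_mat[, j]
    }
    out
  }
  lag_mat <- function(iv) {
    sapply(seq_len(history), function(l) iv[t_idx - l])
  }
  yp <- iy[t_idx]
  yh <- key(matrix(lag_mat(iy), ncol = history))
  xh <- key(matrix(lag_mat(ix), ncol = history))
  # joint entropies via interaction keys
  H <- function(...) {
    f <- interaction(..., drop = TRUE)
    entropy_bits(tabulate(f) / length(f))
  }
  # T = H(y+|y) - H(y+|y,x) = H(y+,y) - H(y) - H(y+,y,x) + H(y,x)
  te <- H(yp, yh) - H(yh) - H(yp, yh, xh) + H(yh, xh)
  max(te, 0)
}

#' Band-limited information measure
#'
#' Zero-phase band-pass filters both signals (4th-order Butterworth,
#' forward-backward) and applies the chosen histogram measure to the
#' filtered pair. A band `(f_lo, Inf)` acts as a high-pass at `f_lo`;
#' `(0, f_hi)` as a low-pass.
#'
#' @inheritParams mutual_information
#' @param band Numeric `c(f_lo, f_hi)` in Hz within `(0, Nyquist)`.
#' @param measure `"mi"` or `"te"`.
#' @param sample_rate Sampling frequency for vector input.
#' @param ... Passed to the underlying measure.
#' @return The band-limited measure in bits.
#' @export
band_limited_measure <- function(x, y, band, measure = c("mi", "te"),
                                 n_bins = 16, sample_rate = NULL, ...) {
  measure <- match.arg(measure)
  p <- as_sig_pair(x, y, sample_rate)
  xf <- bandpass_filter(p$x$values, band, p$x$fs)
  yf <- bandpass_filter(p$y$values, band, p$y$fs)
  switch(measure,
         mi = mutual_information(xf, yf, n_bins, ...),
         te = transfer_entropy(xf, yf, n_bins, ...))
}

bandpass_filter <- function(v, band, fs) {
  nyq <- fs / 2
  lo <- band[1]
  hi <- band[2]
  if (length(band) != 2 || hi <= lo) abort("`band` must be c(f_lo, f_hi) with f_hi > f_lo.")
  if (lo < 0 || lo >= nyq) abort("`band` must lie within (0, Nyquist).")
  if (lo <= 0 && !is.finite(hi) ) return(v)
  bf <- if (lo <= 0) {
    signal::butter(4, hi / nyq, type = "low")
  } else if (!is.finite(hi) || hi >= nyq) {
    signal::butter(4, lo / nyq, type = "high")
  } else {
    signal::butter(2, c(lo, hi) / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, v))
}

#' Magnitude-squared coherence
#'
#' Welch-based `gamma^2(f) = |S_xy|^2 / (S_xx S_yy)`, in [0, 1] at every
#' frequency. Requires at least 8 averaged segments (a single segment gives
#' the degenerate `gamma^2 = 1` identically).
#'
#' @inheritParams cross_correlation
#' @param segment_length Welch segment length; default gives >= 8 segments.
#' @return A tibble of class `coherence_tbl` with columns `frequency`,
#'   `coherence`.
#' @export
coherence <- function(x, y, segment_length = NULL, sample_rate = NULL) {
  p <- as_sig_pair(x, y, sample_rate)
  n <- length(p$x$values)
  if (is.null(segment_length)) {
    segment_length <- min(default_segment(n), 2^floor(log2(n / 4.5)))
  }
  sxx <- welch_core(p$x$values, NULL, p$x$fs, segment_length)
  if (sxx$n_segments < 8) {
    abort("coherence needs >= 8 Welch segments; shorten `segment_length`.")
  }
  syy <- welch_core(p$y$values, NULL, p$y$fs, segment_length)
  sxy <- welch_core(p$x$values, p$y$values, p$x$fs, segment_length)
  g2 <- Mod(sxy$spectrum)^2 / (Re(sxx$spectrum) * Re(syy$spectrum))
  out <- tibble(frequency = sxx$frequency,
                coherence = pmin(pmax(g2, 0), 1))
  class(out) <- c("coherence_tbl", class(out))
  out
}

#' Normalized mutual information per frequency band
#'
#' For each band, band-pass filters the pair, then reports
#' `I_norm = I(X_f; Y_f) / H(X_f)` — the in-band mutual information as a
#' fraction of the filtered input's histogram entropy. `I_norm` is ~1 when
#' the band is transmitted losslessly and ~0 for an independent pair. A
#' constant filtered input (H = 0) is flagged with `NA`.
#'
#' @inheritParams band_limited_measure
#' @param bands List of `c(f_lo, f_hi)` pairs.
#' @return A tibble with columns `f_lo`, `f_hi`, `mi_bits`,
#'   `entropy_bits`, `normalized_mi`.
#' @export
normalized_mi_per_band <- function(x, y, bands, n_bins = 16,
                                   sample_rate = NULL) {
  p <- as_sig_pair(x, y, sample_rate)
  rows <- map(bands, function(band) {
    xf <- bandpass_filter(p$x$values, band, p$x$fs)
    yf <- bandpass_filter(p$y$values, band, p$y$fs)
    ix <- bin_index(xf, n_bins)
    hx <- entropy_bits(tabulate(ix, n_bins) / length(ix))
    mi <- mutual_information(xf, yf, n_bins)
    tibble(f_lo = band[1], f_hi = band[2], mi_bits = mi, entropy_bits = hx,
           normalized_mi = if (hx > 0) mi / hx else NA_real_)
  })
  bind_rows(rows)
}

#' Combined information report
#'
#' Collects the package's information measures for one stimulus/response
#' pair: overall MI, the capacity bound from the measured SNR, the transfer
#' efficiency, per-band transfer entropy and normalized MI, and coherence.
#'
#' @inheritParams band_limited_measure
#' @param bands List of frequency bands (Hz pairs); default
#'   `list(c(0, 10), c(30, 50), c(100, Inf))`.
#' @return A list of class `info_report` with elements `summary` (one-row
#'   tibble: `mi_bits`, `mi_max_bits`, `efficiency_pct`), `bands` (per-band
#'   tibble with `te_bits` and `normalized_mi`) and `coherence` (tibble).
#' @export
info_report <- function(x, y, bands = list(c(0, 10), c(30, 50), c(100, Inf)),
                        n_bins = 16, sample_rate = NULL) {
  p <- as_sig_pair(x, y, sample_rate)
  mi <- mutual_information(p$x$values, p$y$values, n_bins)
  snr <- as.numeric(snr_db(x, y, sample_rate))
  mi_max <- channel_capacity_bound(snr, scale = "db")
  te <- map_dbl(bands, function(b) {
    band_limited_measure(x, y, b, measure = "te", n_bins = n_bins,
                         sample_rate = sample_rate)
  })
  nmi <- normalized_mi_per_band(x, y, bands, n_bins, sample_rate)
  nmi$te_bits <- te
  out <- list(
    summary = tibble(mi_bits = mi, mi_max_bits = mi_max,
                     efficiency_pct = transfer_efficiency(mi, mi_max)),
    bands = nmi,
    coherence = coherence(x, y, sample_rate = sample_rate)
  )
  class(out) <- "info_report"
  out
}

#' @export
print.info_report <- function(x, ...) {
  cat("<info_report>\n")
  print(x$summary)
  cat("per-band measures:\n")
  print(x$bands)
  invisible(x)
}
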