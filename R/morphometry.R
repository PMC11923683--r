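# Microsphere size-distribution statistics: summary moments, a normality
# battery (KS, Jarque-Bera, Q-Q, KDE), and the pairwise size-ratio
# distribution compared against the Golden Ratio.

diam_vec <- function(x) {
  v <- if (is.data.frame(x)) {
    col <- intersect(c("diameter_nm", "diameter", "value"), names(x))[1]
    if (is.na(col)) abort("`x` needs a diameter column (diameter_nm).")
    x[[col]]
  } else as.numeric(x)
  if (any(!is.finite(v)) || any(v <= 0)) abort("diameters must be positive and finite.")
  v
}

sample_skewness <- function(v) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  mean((v - m)^3) / s^3
}

sample_excess_kurtosis <- function(v) {
  m <- mean(v)
  s2 <- mean((v - m)^2)
  mean((v - m)^4) / s2^2 - 3
}

#' Microsphere diameter summary statistics
#'
#' Sample mean, SD (n-1), median, IQR, coefficient of variation
#' (`100 * sd / mean`, percent), skewness and excess kurtosis of a diameter
#' population.
#'
#' @param x Diameters in nm: a numeric vector or a data frame with a
#'   `diameter_nm` column.
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `median`,
#'   `iqr`, `cv_pct`, `skewness`, `excess_kurtosis`.
#' @export
sphere_summary <- function(x) {
  v <- diam_vec(x)
  if (length(v) < 2) abort("need at least 2 diameters.")
  tibble(n = length(v), mean = mean(v), sd = stats::sd(v),
         median = median(v), iqr = stats::IQR(v),
         cv_pct = 100 * stats::sd(v) / mean(v),
         skewness = sample_skewness(v),
         excess_kurtosis = sample_excess_kurtosis(v))
}

#' Gaussian density and distribution function
#'
#' Thin wrappers over [stats::dnorm()] / [stats::pnorm()] for the normal
#' model fitted to diameter populations; provided so size-model curves use
#' one documented entry point.
#'
#' @param x Quantiles.
#' @param mu Mean.
#' @param sigma Standard deviation (> 0).
#' @return Density values (`normal_pdf`) or probabilities (`normal_cdf`).
#' @export
normal_pdf <- function(x, mu, sigma) {
  check_positive(sigma, "sigma")
  dnorm(x, mu, sigma)
}

#' @rdname normal_pdf
#' @export
normal_cdf <- function(x, mu, sigma) {
  check_positive(sigma, "sigma")
  pnorm(x, mu, sigma)
}

#' Normality battery for a diameter population
#'
#' Kolmogorov-Smirnov test against `N(mean, sd)` with parameters estimated
#' from the sample (plain KS, no Lilliefors correction), a Jarque-Bera test
#' built from sample skewness and excess kurtosis (chi-squared with 2 df),
#' Q-Q quantile pairs against the fitted normal, a Gaussian-kernel KDE
#' (Silverman bandwidth), and the sup-gap between the empirical and fitted
#' normal CDFs.
#'
#' @inheritParams sphere_summary
#' @return A list of class `normality_battery`: `ks_p`, `jarque_bera_p`,
#'   `jb_stat`, `qq` (tibble `theoretical`, `sample`), `kde` (tibble
#'   `x`, `density`), `cdf_sup_gap`, `n`.
#' @export
normality_battery <- function(x) {
  v <- diam_vec(x)
  n <- length(v)
  if (n < 8) abort("need at least 8 observations.")
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) abort("degenerate (constant) sample.")
  ks <- suppressWarnings(ks.test(v, "pnorm", m, s))
  jb <- n / 6 * (sample_skewness(v)^2 + sample_excess_kurtosis(v)^2 / 4)
  qq <- qqnorm(v, plot.it = FALSE)
  kde <- density(v, bw = "nrd0")
  sorted <- sort(v)
  ecdf_hi <- seq_len(n) / n
  ecdf_lo <- (seq_len(n) - 1) / n
  th <- pnorm(sorted, m, s)
  gap <- max(abs(ecdf_hi - th), abs(ecdf_lo - th))
  structure(list(
    ks_p = ks$p.value,
    jarque_bera_p = pchisq(jb, df = 2, lower.tail = FALSE),
    jb_stat = jb,
    qq = tibble(theoretical = m + s * sort(qq$x), sample = sort(qq$y)),
    kde = tibble(x = kde$x, density = kde$y),
    cdf_sup_gap = gap,
    n = n
  ), class = "normality_battery")
}

#' @export
print.normality_battery <- function(x, ...) {
  cat(sprintf("<normality_battery> n = %d, KS p = %.4g, Jarque-Bera p = %.4g, sup CDF gap = %.4g\n",
              x$n, x$ks_p, x$jarque_bera_p, x$cdf_sup_gap))
  invisible(x)
}

#' Pairwise size-ratio distribution against the Golden Ratio
#'
#' All unordered pair ratios taken larger/smaller (so every ratio is >= 1
#' and the phi reference is one-sided), histogrammed, with the fraction of
#' ratios within `tol` of phi.
#'
#' @inheritParams sphere_summary
#' @param bins Number of histogram bins.
#' @param tol Half-width of the "near phi" window (default 0.05).
#' @return A list of class `size_ratio_dist`: `ratios` (numeric),
#'   `histogram` (tibble `mid`, `lo`, `hi`, `count`), `frac_near_phi`,
#'   `modal_bin` (the `c(lo, hi)` of the most populated bin), `phi`.
#' @export
size_ratio_distribution <- function(x, bins = 30, tol = 0.05) {
  v <- diam_vec(x)
  if (length(v) < 2) abort("need at least 2 diameters.")
  bins <- check_count(bins, "bins")
  pairs <- utils::combn(v, 2)
  r <- pmax(pairs[1, ], pairs[2, ]) / pmin(pairs[1, ], pairs[2, ])
  brk <- seq(1, max(r) * (1 + 1e-12), length.out = bins + 1)
  if (max(r) == 1) brk <- seq(1, 1 + 1e-9, length.out = bins + 1)
  h <- graphics::hist(r, breaks = brk, plot = FALSE)
  i_mode <- which.max(h$counts)
  phi <- golden_ratio()
  structure(list(
    ratios = r,
    histogram = tibble(mid = h$mids, lo = brk[-length(brk)], hi = brk[-1],
                       count = h$counts),
    frac_near_phi = mean(abs(r - phi) <= tol),
    modal_bin = c(brk[i_mode], brk[i_mode + 1]),
    phi = phi
  ), class = "size_ratio_dist")
}

#' @export
print.size_ratio_dist <- function(x, ...) {
  cat(sprintf("<size_ratio_dist> %d ratios, modal bin [%.3f, %.3f], %.2f%% within +/-0.05 of phi\n",
              length(x$ratios), x$modal_bin[1], x$modal_bin[2],
              100 * x$frac_near_phi))
  invisible(x)
}
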