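# SNR, error metrics, cross-correlation, transfer/impulse response,
# bispectrum and the paired t-test.

test_that("snr_db follows the output-minus-input noise definition", {
  set.seed(31)
  x <- rnorm(5000, sd = 2)
  e <- rnorm(5000, sd = 1)
  # rescale the error so mean(x^2) = 4 * mean(e^2) exactly
  e <- e * sqrt(mean(x^2) / (4 * mean(e^2)))
  expect_equal(snr_db(x, x + e, sample_rate = 1), 10 * log10(4),
               tolerance = 1e-12)
  s_inf <- snr_db(x, x, sample_rate = 1)
  expect_identical(as.numeric(s_inf), Inf)
  expect_true(attr(s_inf, "zero_noise"))
  # output == 0 means noise = -input, so P_noise = P_signal: 0 dB
  expect_equal(snr_db(x, numeric(5000), sample_rate = 1), 0)
})

test_that("error metrics match hand-computed values", {
  em <- error_metrics(c(0, 1), c(0, 0), sample_rate = 1)
  expect_equal(em$rmse, 1 / sqrt(2))
  expect_equal(em$mae, 0.5)
  em2 <- error_metrics(c(-1, 0, 1), c(1, 0, -1), sample_rate = 1)
  expect_equal(em2$pearson_r, -1)
  x <- sin(1:100)
  em3 <- error_metrics(x, x, sample_rate = 1)
  expect_equal(em3$rmse, 0)
  expect_equal(em3$mae, 0)
  expect_equal(em3$pearson_r, 1)
  expect_identical(em3$psnr_db, Inf)
  expect_error(error_metrics(rep(1, 10), rnorm(10), sample_rate = 1),
               "zero-variance")
})

test_that("PSNR uses the input peak over the RMSE", {
  x <- c(-2, 0, 2, 0)
  y <- x + 0.5
  expect_equal(error_metrics(x, y, sample_rate = 1)$psnr_db,
               20 * log10(2 / 0.5))
})

test_that("cross-correlation finds identity, delay and sign", {
  set.seed(32)
  x <- rnorm(400)
  xc <- cross_correlation(x, x, sample_rate = 100)
  expect_equal(attr(xc, "max_value"), 1, tolerance = 1e-9)
  expect_equal(attr(xc, "lag_at_max"), 0)
  y <- c(rep(0, 7), x[1:393])
  xc2 <- cross_correlation(x, y, sample_rate = 100)
  expect_equal(attr(xc2, "lag_at_max"), 7 / 100)
  xc3 <- cross_correlation(x, -x, sample_rate = 100)
  expect_equal(min(xc3$value), -1, tolerance = 1e-9)
  expect_equal(xc3$value[xc3$lag == 0], -1, tolerance = 1e-9)
  expect_true(all(abs(xc2$value) <= 1 + 1e-12))
  expect_error(cross_correlation(rep(0, 10), rnorm(10), sample_rate = 1),
               "all-constant")
})

test_that("band power isolates the excited tone", {
  fs <- 4096
  tone <- make_tone(144, fs, 1)
  bp <- power_at_frequencies(tone, c(144, 233), sample_rate = fs)
  expect_gt(bp$power[1] / max(bp$power[2], 1e-300), 100)
  silence <- numeric(4096)
  expect_lt(max(power_at_frequencies(silence, c(144), sample_rate = fs)$power),
            1e-20)
  set.seed(33)
  two <- make_tone(100, fs, 4) + make_tone(300, fs, 4)
  bp2 <- power_at_frequencies(two, c(100, 300), sample_rate = fs)
  expect_equal(bp2$power[1], bp2$power[2], tolerance = 0.05)
  expect_error(power_at_frequencies(tone, 3000, sample_rate = fs), "Nyquist")
})

test_that("frequency response recovers gain and delay phase", {
  set.seed(34)
  x <- rnorm(2^13)
  H <- frequency_response(x, 0.5 * x, sample_rate = 200)
  mid <- H$magnitude[H$frequency > 5 & H$frequency < 95]
  expect_true(all(abs(mid - 0.5) < 0.01))
  expect_true(all(abs(H$phase_rad[H$frequency > 5 & H$frequency < 95]) < 0.01))
  H1 <- frequency_response(x, x, sample_rate = 200)
  expect_true(all(abs(H1$magnitude[-1] - 1) < 0.01))
  # pure delay: phase slope -2 pi f d
  d <- 5
  y <- c(rep(0, d), x[1:(length(x) - d)])
  Hd <- frequency_response(x, y, segment_length = 512, sample_rate = 200)
  sel <- Hd$frequency > 2 & Hd$frequency < 20
  fit <- lm(ph ~ f, data = data.frame(f = Hd$frequency[sel],
                                      ph = Hd$phase_rad[sel]))
  expect_equal(unname(coef(fit)[2]), -2 * pi * d / 200, tolerance = 0.02)
})

test_that("impulse response inverts analytic transfer functions", {
  fs <- 1000
  half <- 513
  f <- (0:(half - 1)) * fs / 1024
  H1 <- tibble::tibble(frequency = f,
                       response = complex(real = rep(1, half)))
  h1 <- impulse_response(H1)
  expect_equal(h1$value[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(h1$value[-1])), 1e-12)
  # pure delay phase -> shifted impulse
  d <- 10
  H2 <- tibble::tibble(frequency = f, response = exp(-2i * pi * f * d / fs))
  h2 <- impulse_response(H2)
  expect_equal(which.max(h2$value), d + 1)
  expect_error(impulse_response(tibble::tibble(frequency = c(1, 2),
                                               response = c(1, 1))), "grid")
})

test_that("first-order low-pass inverts to an exponential kernel", {
  fs <- 1000
  fc <- 20                       # tau = 1/(2 pi fc) = 7.96 ms
  half <- 2049
  f <- (0:(half - 1)) * fs / 4096
  H <- tibble::tibble(frequency = f, response = 1 / (1 + 1i * f / fc))
  h <- impulse_response(H)
  sel <- 2:40
  fit <- lm(log(v) ~ t, data = data.frame(t = h$time[sel], v = h$value[sel]))
  tau_est <- -1 / coef(fit)[2]
  expect_equal(unname(tau_est), 1 / (2 * pi * fc), tolerance = 0.05)
})

test_that("welch round-trip recovers an FIR kernel almost exactly", {
  set.seed(35)
  n <- 2048
  kernel <- c(0.5, 0.3, -0.2, -0.6)       # zero-sum: DC is genuinely empty
  x <- rnorm(n)
  x <- x - mean(x)
  kpad <- c(kernel, rep(0, n - length(kernel)))
  y <- Re(fft(fft(x) * fft(kpad), inverse = TRUE)) / n  # circular convolution
  H <- frequency_response(x, y, regularization = 1e-12, segment_length = n,
                          sample_rate = 1, window = "rect")
  h <- impulse_response(H)
  expect_lt(max(abs(h$value[1:4] - kernel)), 1e-6)
  expect_lt(max(abs(h$value[5:100])), 1e-6)
})

test_that("bispectrum detects quadratic phase coupling", {
  fs <- 256
  seglen <- 128
  n_seg <- 128
  t <- (0:(seglen * n_seg - 1)) / fs
  f1 <- 20; f2 <- 36                       # on-bin; f1 + f2 = 56 also on-bin
  coupled <- cos(2 * pi * f1 * t) + cos(2 * pi * f2 * t) +
    cos(2 * pi * (f1 + f2) * t)
  b <- bispectrum(coupled, seglen, sample_rate = fs)
  peak <- b[which.max(b$magnitude), ]
  expect_setequal(c(peak$f1, peak$f2), c(f1, f2))
  # same tones with independent random phases per segment: peak suppressed
  seg_t <- (0:(seglen - 1)) / fs
  set.seed(36)
  # the incoherent residual shrinks only as 1/sqrt(n_seg); average enough
  # segments that the suppression dominates its own fluctuation
  n_seg <- 1024
  shuffled <- unlist(lapply(seq_len(n_seg), function(i) {
    ph <- runif(3, 0, 2 * pi)
    cos(2 * pi * f1 * seg_t + ph[1]) + cos(2 * pi * f2 * seg_t + ph[2]) +
      cos(2 * pi * (f1 + f2) * seg_t + ph[3])
  }))
  br <- bispectrum(shuffled, seglen, sample_rate = fs)
  # phase randomization collapses the coupled-bin peak itself
  at_peak <- function(bs) bs$magnitude[bs$f1 == f1 & bs$f2 == f2]
  expect_gt(at_peak(b) / at_peak(br), 10)
  set.seed(37)
  bg <- bispectrum(rnorm(seglen * n_seg), seglen, sample_rate = fs)
  expect_gt(max(b$magnitude) / max(bg$magnitude), 10)
  expect_error(bispectrum(rnorm(100), 128, sample_rate = fs), "4 segments")
})

test_that("paired t-test behaves across degenerate, shifted and null pairs", {
  x <- sin(1:1000)
  p_same <- paired_ttest(x, x, sample_rate = 1)
  expect_identical(as.numeric(p_same), 1)
  expect_true(attr(p_same, "degenerate"))
  set.seed(38)
  noisy <- rnorm(1000)
  expect_lt(paired_ttest(noisy, noisy + 10, sample_rate = 1), 1e-6)
  # null calibration: p-values uniform for independent identical distributions
  set.seed(39)
  pvals <- replicate(200, paired_ttest(rnorm(50), rnorm(50), sample_rate = 1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("metrics are invariant to a common time offset", {
  set.seed(40)
  v1 <- rnorm(512)
  v2 <- v1 + rnorm(512, sd = 0.1)
  fs <- 64
  s1 <- tibble::tibble(time = (0:511) / fs, value = v1)
  s2 <- tibble::tibble(time = (0:511) / fs, value = v2)
  s1o <- dplyr::mutate(s1, time = time + 1000)
  s2o <- dplyr::mutate(s2, time = time + 1000)
  expect_equal(snr_db(s1, s2), snr_db(s1o, s2o))
  expect_equal(error_metrics(s1, s2), error_metrics(s1o, s2o))
  expect_equal(attr(cross_correlation(s1, s2), "lag_at_max"),
               attr(cross_correlation(s1o, s2o), "lag_at_max"))
  expect_equal(welch_psd(s1)$power, welch_psd(s1o)$power)
})
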