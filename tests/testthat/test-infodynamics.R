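# Histogram information measures: MI, capacity, efficiency, TE, coherence,
# band-limited and normalized variants.

test_that("MI of a 16-level identity channel equals log2(16) bits", {
  set.seed(51)
  levels <- seq(0, 15) / 15
  x <- sample(rep(levels, each = 1000))       # exactly equiprobable
  expect_equal(mutual_information(x, x, n_bins = 16), 4, tolerance = 1e-12)
})

test_that("MI of independent signals stays within the plug-in bias", {
  set.seed(52)
  n <- 1e5
  x <- runif(n)
  y <- runif(n)
  bias <- (16 - 1)^2 / (2 * n * log(2))
  expect_lt(mutual_information(x, y, 16), bias + 0.01)
})

test_that("MI recovers the Gaussian closed form", {
  pair <- make_gaussian_pair(1e5, 0.9, seed = 53)
  truth <- -0.5 * log2(1 - 0.9^2)
  expect_equal(mutual_information(pair$x, pair$y, 32,
                                  correction = "miller-madow"),
               truth, tolerance = 0.1 / truth)
})

test_that("MI is symmetric and respects data processing", {
  pair <- make_gaussian_pair(2e4, 0.6, seed = 54)
  mi_xy <- mutual_information(pair$x, pair$y, 16)
  mi_yx <- mutual_information(pair$y, pair$x, 16)
  expect_lt(abs(mi_xy - mi_yx), 1e-12)
  # binwise-coarser deterministic transform cannot add information
  y_coarse <- round(pair$y * 2) / 2
  expect_lte(mutual_information(pair$x, y_coarse, 16), mi_xy + 0.02)
  # constant input -> MI 0 by convention
  expect_equal(mutual_information(rep(1, 100), rnorm(100), 16), 0)
})

test_that("capacity bound and efficiency follow their closed forms", {
  expect_equal(channel_capacity_bound(1, scale = "linear"), 1)
  expect_equal(channel_capacity_bound(0, scale = "linear"), 0)
  expect_equal(channel_capacity_bound(3, scale = "linear"), 2)
  expect_equal(channel_capacity_bound(10 * log10(3), scale = "db"), 2)
  expect_error(channel_capacity_bound(-2, scale = "linear"), "exceed")
  expect_equal(transfer_efficiency(0.0801, 1.23), 6.512195121951219)
  expect_equal(transfer_efficiency(0.5, 0.5), 100)
  expect_equal(transfer_efficiency(0, 2), 0)
  expect_error(transfer_efficiency(1, 0), "positive")
})

test_that("transfer entropy is directional on a lag-1 copy channel", {
  ch <- make_copy_channel(1e5, seed = 55)
  te_xy <- transfer_entropy(ch$x, ch$y, n_bins = 2)
  te_yx <- transfer_entropy(ch$y, ch$x, n_bins = 2)
  expect_equal(te_xy, 1, tolerance = 0.01)
  expect_lt(te_yx, 0.01)
  expect_gt(te_xy - te_yx, 0.8)
})

test_that("transfer entropy vanishes without directed coupling", {
  set.seed(56)
  x <- rnorm(2e4)
  y <- rnorm(2e4)
  expect_lt(transfer_entropy(x, y, 8), 0.02)
  # y driven purely by its own past
  y_ar <- as.numeric(stats::filter(rnorm(2e4), 0.8, method = "recursive"))
  expect_lt(transfer_entropy(x, y_ar, 8), 0.02)
  expect_error(transfer_entropy(1:3, 1:3, history = 5), "short")
})

test_that("band-limited measures concentrate where the signal lives", {
  set.seed(57)
  fs <- 200
  n <- 2^13
  x <- make_tone(5, fs, n / fs) + 0.05 * rnorm(n)
  y <- make_tone(5, fs, n / fs) + 0.05 * rnorm(n)   # shared tone, own noise
  mi_in <- band_limited_measure(x, y, c(2, 10), "mi", sample_rate = fs)
  mi_out <- band_limited_measure(x, y, c(60, 90), "mi", sample_rate = fs)
  expect_gt(mi_in, 10 * max(mi_out, 0.01))
  # full-band measure approximates the unbanded one
  mi_full <- band_limited_measure(x, y, c(0, fs / 2 * 0.999), "mi",
                                  sample_rate = fs)
  expect_equal(mi_full, mutual_information(x, y, 16), tolerance = 0.15)
  expect_error(band_limited_measure(x, y, c(10, 10), sample_rate = fs),
               "f_hi")
})

test_that("coherence separates clean, noisy and independent channels", {
  set.seed(58)
  n <- 2^13
  fs <- 200
  x <- rnorm(n)
  bf <- signal::butter(2, 0.4)
  y <- as.numeric(signal::filtfilt(bf, x))          # filtered, noise-free
  co <- coherence(x, y, sample_rate = fs)
  mid <- co$coherence[co$frequency > 5 & co$frequency < 70]
  expect_gt(mean(mid), 0.95)
  co_ind <- coherence(rnorm(n), rnorm(n), sample_rate = fs)
  n_seg <- 2 * n / 512 - 1
  expect_lt(mean(co_ind$coherence), 2 / 8)
  # corrupting one band depresses coherence only there
  noise_band <- as.numeric(signal::filtfilt(
    signal::butter(4, c(40, 60) / (fs / 2), type = "pass"), rnorm(n)))
  y2 <- x + 8 * noise_band
  co2 <- coherence(x, y2, sample_rate = fs)
  inside <- co2$coherence[co2$frequency > 44 & co2$frequency < 56]
  outside <- co2$coherence[co2$frequency > 5 & co2$frequency < 35]
  expect_lt(mean(inside), 0.5)
  expect_gt(mean(outside), 0.9)
  expect_error(coherence(rnorm(256), rnorm(256), segment_length = 256,
                         sample_rate = fs), "8 Welch segments")
})

test_that("normalized MI per band tracks transmission fidelity", {
  set.seed(59)
  fs <- 200
  n <- 2^13
  x <- rnorm(n)
  res <- normalized_mi_per_band(x, x, list(c(5, 20)), sample_rate = fs)
  expect_gt(res$normalized_mi, 0.95)
  res_ind <- normalized_mi_per_band(x, rnorm(n), list(c(5, 20)),
                                    sample_rate = fs)
  expect_lt(res_ind$normalized_mi, 0.1)
  # monotone degradation with in-band noise
  levels <- c(0.2, 1, 5)
  vals <- vapply(levels, function(s) {
    set.seed(60)
    normalized_mi_per_band(x, x + s * rnorm(n), list(c(5, 20)),
                           sample_rate = fs)$normalized_mi
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("info_report assembles consistent summaries", {
  set.seed(61)
  fs <- 200
  x <- rnorm(2^12)
  y <- 0.5 * x + 0.1 * rnorm(2^12)
  rep <- info_report(x, y, bands = list(c(1, 10), c(20, 40)),
                     sample_rate = fs)
  expect_gt(rep$summary$mi_bits, 0)
  expect_equal(rep$summary$efficiency_pct,
               100 * rep$summary$mi_bits / rep$summary$mi_max_bits)
  expect_identical(nrow(rep$bands), 2L)
  expect_true(all(rep$coherence$coherence >= 0 &
                    rep$coherence$coherence <= 1))
})
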