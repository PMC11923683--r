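# MSD computation, confined/anomalous fits and step-size ratios.

test_that("mean displacement averages positions per frame", {
  one <- tibble::tibble(time = 0:4, particle = 1L, x = 2, y = 3)
  md <- mean_displacement(one, frame_interval = 1)
  expect_equal(md$x_mean, rep(2, 5))
  expect_equal(md$y_mean, rep(3, 5))
  mirrored <- dplyr::bind_rows(
    tibble::tibble(time = 0:4, particle = 1L, x = 1:5, y = -(1:5)),
    tibble::tibble(time = 0:4, particle = 2L, x = -(1:5), y = 1:5))
  md2 <- mean_displacement(mirrored, frame_interval = 1)
  expect_equal(md2$x_mean, rep(0, 5))
  expect_equal(md2$y_mean, rep(0, 5))
  # common velocity appears in the ensemble mean
  v <- c(0.5, -0.25)
  ball <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(time = 0:9, particle = i, x = i + v[1] * (0:9),
                   y = i + v[2] * (0:9))
  }))
  md3 <- mean_displacement(ball, frame_interval = 1)
  expect_equal(diff(md3$x_mean), rep(v[1], 9))
  expect_equal(diff(md3$y_mean), rep(v[2], 9))
})

test_that("msd matches closed forms for static and ballistic motion", {
  static <- tibble::tibble(time = 0:9, particle = 1L, x = 1, y = 2)
  m <- msd(static, max_lag = 5, frame_interval = 1)
  expect_equal(m$msd, rep(0, 6))
  expect_equal(m$lag, 0:5)
  vx <- 2; vy <- -1
  ball <- tibble::tibble(time = 0:19, particle = 1L, x = vx * (0:19),
                         y = vy * (0:19))
  mb <- msd(ball, max_lag = 8, frame_interval = 1)
  expect_equal(mb$msd, (vx^2 + vy^2) * mb$lag^2, tolerance = 1e-12)
  expect_error(msd(static, max_lag = 50, frame_interval = 1), "record")
})

test_that("Brownian MSD slope recovers 4D", {
  sig <- 1.5
  tr <- simulate_particles(NULL, n_particles = 200, box = c(1e6, 1e6),
                           noise_sigma = sig, dt = 0.1, t_end = 50, seed = 71)
  m <- msd(tr, max_lag = 10)
  fit <- lm(msd ~ 0 + lag, data = m[m$lag > 0, ])
  D_true <- sig^2 / 2
  expect_equal(unname(coef(fit)[1]) / 4, D_true, tolerance = 0.1)
})

test_that("exponential fit recovers printed-scale confined parameters", {
  lags <- seq(0.005, 0.6, by = 0.005)
  truth <- c(y0 = 3853, A = -3853, R0 = -12.90)
  curve <- tibble::tibble(lag = c(0, lags),
                          msd = c(0, truth["y0"] +
                                    truth["A"] * exp(truth["R0"] * lags)),
                          n_pairs = 1)
  class(curve) <- c("msd_tbl", class(curve))
  fit <- fit_msd_exponential(curve)
  expect_true(fit$converged)
  est <- fit$params
  expect_equal(est[["y0"]], 3853, tolerance = 0.01)
  expect_equal(est[["A"]], -3853, tolerance = 0.01)
  expect_equal(est[["R0"]], -12.90, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)
  expect_equal(fit$characteristic_time, 1 / 12.90, tolerance = 1e-9)
  expect_equal(fit$characteristic_time, 0.0775, tolerance = 0.01)
  # constant MSD data is flagged degenerate
  flat <- tibble::tibble(lag = 0:10, msd = c(0, rep(5, 10)) * 0 + 5,
                         n_pairs = 1)
  flat$msd[1] <- 5
  fit_flat <- fit_msd_exponential(flat)
  expect_false(fit_flat$converged)
  expect_true(fit_flat$degenerate)
})

test_that("tidy and glance expose fit terms and quality", {
  tc <- gen_confined_trajectories(n_particles = 100, frames = 150,
                                  frame_interval = 0.005, y0 = 100,
                                  R0 = -10, seed = 72)
  fit <- fit_msd_exponential(msd(tc, max_lag = 100))
  td <- tidy(fit)
  expect_identical(td$term, c("y0", "A", "R0"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lte(gl$r.squared, 1)
  expect_gte(gl$reduced.chisq, 0)
  expect_identical(gl$nobs, 100L)
})

test_that("power-law exponent separates diffusion regimes", {
  # ballistic: alpha = 2 exactly
  ball <- tibble::tibble(time = 0:49, particle = 1L, x = 3 * (0:49), y = 0)
  mb <- msd(ball, max_lag = 20, frame_interval = 1)
  fb <- fit_msd_powerlaw(mb)
  expect_equal(fb$params[["alpha"]], 2, tolerance = 0.05)
  # Brownian: alpha ~ 1
  tr <- simulate_particles(NULL, n_particles = 150, box = c(1e6, 1e6),
                           noise_sigma = 1, dt = 0.1, t_end = 30, seed = 73)
  fm <- fit_msd_powerlaw(msd(tr, max_lag = 10))
  expect_equal(fm$params[["alpha"]], 1, tolerance = 0.1)
  # confined saturation reads as subdiffusive over long lags
  tc <- gen_confined_trajectories(n_particles = 200, frames = 200,
                                  frame_interval = 0.01, y0 = 500, R0 = -8,
                                  seed = 74)
  fc <- fit_msd_powerlaw(msd(tc, max_lag = 150))
  expect_lt(fc$params[["alpha"]], 0.9)
  expect_error(fit_msd_powerlaw(tibble::tibble(lag = 0:3, msd = c(0, -1, 1, 1))),
               "positive")
})

test_that("diffusion coefficient tracks the model's initial slope", {
  # confined motion with plateau y0 and rate R0 has short-lag slope
  # y0 * |R0|, i.e. D = y0 * |R0| / 4 in 2-D
  fit_for <- function(y0, seed) {
    tc <- gen_confined_trajectories(n_particles = 250, frames = 300,
                                    frame_interval = 0.004, y0 = y0,
                                    R0 = -10, seed = seed)
    fit_msd_exponential(msd(tc, max_lag = 200))
  }
  f1 <- fit_for(100, 75)
  D1 <- diffusion_coefficient(f1)
  expect_error(diffusion_coefficient(f1, dimensions = 4), "dimensions")
  expect_equal(D1, 100 * 10 / 4, tolerance = 0.15)
  # doubling the plateau doubles the short-lag mobility
  D2 <- diffusion_coefficient(fit_for(200, 76))
  expect_equal(D2 / D1, 2, tolerance = 0.2)
  # static data has zero initial slope
  static <- tibble::tibble(time = 0:9, particle = 1L, x = 0, y = 0)
  fs <- fit_msd_exponential(msd(static, max_lag = 6, frame_interval = 1))
  expect_equal(diffusion_coefficient(fs), 0)
})

test_that("step ratios reproduce constructed and symmetric cases", {
  equal_steps <- make_walk(rep(2, 10), runif(10, 0, 2 * pi))
  sr <- step_ratios(equal_steps, frame_interval = 1)
  expect_equal(sr$summary$median, 1)
  expect_equal(sr$ratios$ratio, rep(1, nrow(sr$ratios)), tolerance = 1e-12)
  phi_walk <- make_walk(PHI^(0:6), rep(0.3, 7))
  srp <- step_ratios(phi_walk, frame_interval = 1)
  expect_equal(srp$ratios$ratio, rep(PHI, 6), tolerance = 1e-12)
  expect_equal(srp$summary$frac_near_phi, 1)
  # isotropic Gaussian steps: ratio distribution is reciprocal-symmetric
  set.seed(77)
  n <- 1e5
  gw <- tibble::tibble(time = 0:n, particle = 1L,
                       x = cumsum(c(0, rnorm(n))), y = cumsum(c(0, rnorm(n))))
  srg <- step_ratios(gw, frame_interval = 1)
  expect_equal(srg$summary$median, 1, tolerance = 0.02)
  r <- srg$ratios$ratio
  expect_gt(suppressWarnings(ks.test(r, 1 / r))$p.value, 0.01)
  expect_error(step_ratios(make_walk(c(0, 0), c(0, 0)), frame_interval = 1),
               "zero length")
})

test_that("msd is invariant under rigid motions of all trajectories", {
  tc <- gen_confined_trajectories(n_particles = 30, frames = 60,
                                  frame_interval = 0.02, y0 = 50, R0 = -5,
                                  seed = 78)
  m0 <- msd(tc, max_lag = 20)
  th <- 0.7
  rot <- dplyr::mutate(tc,
                       xr = cos(th) * x - sin(th) * y + 100,
                       yr = sin(th) * x + cos(th) * y - 40)
  rot <- dplyr::transmute(rot, time, particle, x = xr, y = yr)
  attr(rot, "frame_interval") <- 0.02
  m1 <- msd(rot, max_lag = 20)
  expect_equal(m1$msd, m0$msd, tolerance = 1e-10)
})
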