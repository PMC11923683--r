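# Seeded synthetic-data generators that stand in for laboratory recordings:
# attenuated, DC-shifted, noisy RC-filtered responses; confined-diffusion
# (Ornstein-Uhlenbeck) trajectories with a saturating-exponential MSD;
# normal microsphere diameter populations; and a phi-growing positive
# control walk for the step-ratio analysis. All outputs are synthetic and
# bit-reproducible under a fixed seed.

#' Synthetic proteinoid response recording
#'
#' Emulates a recorded output channel:
#' `output = gain * RC_lowpass(stimulus) + dc_offset + N(0, noise_sd^2)`.
#' The RC stage is the discrete one-pole low-pass
#' `y[k] = y[k-1] + (1 - exp(-dt/tau)) * (x[k] - y[k-1])`; with `rc = NULL`
#' (or `tau -> 0`) the stage is the identity. Defaults give a strongly
#' attenuated, slightly negative-offset output whose standard deviation is
#' about 1% of the stimulus SD, the regime the analysis pipeline is built
#' for.
#'
#' @param stimulus Input signal (`time`/`value` data frame, or numeric with
#'   `sample_rate`).
#' @param gain Attenuation in (0, 1]; default 0.011.
#' @param dc_offset Additive offset in volts; default -0.01.
#' @param rc Optional [rc_params()] low-pass stage; `NULL` disables it.
#' @param noise_sd Gaussian noise SD in volts.
#' @param seed Integer seed.
#' @param sample_rate Sampling frequency for vector input.
#' @return A signal tibble (`time`, `value`) at the stimulus sample rate.
#' @export
gen_response_recording <- function(stimulus, gain = 0.011, dc_offset = -0.01,
                                   rc = NULL, noise_sd = 0.001, seed = 1L,
                                   sample_rate = NULL) {
  s <- as_sig(stimulus, sample_rate, "stimulus")
  if (gain <= 0 || gain > 1) abort("`gain` must be in (0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  v <- s$values
  if (!is.null(rc)) {
    if (!inherits(rc, "rc_params")) abort("`rc` must be an rc_params object.")
    a <- 1 - exp(-(1 / s$fs) / rc$tau)
    v <- rc_lowpass(v, a)
  }
  set.seed(seed)
  out <- gain * v + dc_offset + rnorm(length(v), 0, noise_sd)
  sig_tbl(out, s$fs, t0 = s$t0)
}

rc_lowpass <- function(x, a) {
  y <- numeric(length(x))
  y[1] <- a * x[1]
  for (k in seq_along(x)[-1]) y[k] <- y[k - 1] + a * (x[k] - y[k - 1])
  y
}

#' Synthetic confined-diffusion trajectories
#'
#' 2-D Ornstein-Uhlenbeck motion around per-particle anchor points, with
#' relaxation rate `|R0|` and stationary per-axis variance `y0 / 4`, so the
#' ensemble MSD follows the saturating form `y0 * (1 - exp(R0 * tau))`
#' (plateau `y0`, rate `R0 < 0`). Optional Gaussian localization noise is
#' added to the recorded positions.
#'
#' @param n_particles Number of particles.
#' @param frames Frames per particle.
#' @param frame_interval Seconds between frames.
#' @param y0 MSD plateau in squared coordinate units (e.g. um^2).
#' @param R0 Relaxation rate in 1/s; must be negative.
#' @param noise Localization noise SD added to each recorded coordinate.
#' @param seed Integer seed.
#' @return A `trajectory_tbl` (long tibble `time`, `particle`, `x`, `y`).
#' @export
gen_confined_trajectories <- function(n_particles = 100, frames = 200,
                                      frame_interval = 0.01, y0 = 3853,
                                      R0 = -12.9, noise = 0, seed = 1L) {
  n_particles <- check_count(n_particles, "n_particles")
  frames <- check_count(frames, "frames", min = 2)
  check_positive(frame_interval, "frame_interval")
  check_positive(y0, "y0")
  if (R0 >= 0) abort("`R0` must be negative (confined relaxation).")
  if (noise < 0) abort("`noise` must be >= 0.")
  theta <- -R0
  sigma2 <- y0 / 4                      # stationary per-axis variance
  rho <- exp(-theta * frame_interval)
  innov_sd <- sqrt(sigma2 * (1 - rho^2))
  set.seed(seed)
  # anchors spread the ensemble out; OU displacement stats are unaffected
  ax <- runif(n_particles, 0, 200)
  ay <- runif(n_particles, 0, 200)
  X <- matrix(NA_real_, frames, n_particles)
  Y <- matrix(NA_real_, frames, n_particles)
  X[1, ] <- rnorm(n_particles, 0, sqrt(sigma2))
  Y[1, ] <- rnorm(n_particles, 0, sqrt(sigma2))
  for (k in 2:frames) {
    X[k, ] <- rho * X[k - 1, ] + rnorm(n_particles, 0, innov_sd)
    Y[k, ] <- rho * Y[k - 1, ] + rnorm(n_particles, 0, innov_sd)
  }
  X <- sweep(X, 2, ax, "+") + if (noise > 0)
    matrix(rnorm(frames * n_particles, 0, noise), frames) else 0
  Y <- sweep(Y, 2, ay, "+") + if (noise > 0)
    matrix(rnorm(frames * n_particles, 0, noise), frames) else 0
  out <- tibble(
    time = rep((seq_len(frames) - 1) * frame_interval, each = n_particles),
    particle = rep(seq_len(n_particles), times = frames),
    x = as.vector(t(X)),
    y = as.vector(t(Y))
  )
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("trajectory_tbl", class(out))
  out
}

#' Synthetic microsphere diameter population
#'
#' Seeded draws from `N(mu, sigma)` truncated to positive values (redrawing
#' any nonpositive values), the normal size model used for proteinoid
#' nanosphere populations.
#'
#' @param n Population size.
#' @param mu Mean diameter in nm (default 1581.27).
#' @param sigma SD in nm (default 302.02).
#' @param seed Integer seed.
#' @return A tibble with one column `diameter_nm`.
#' @export
gen_sphere_diameters <- function(n = 200, mu = 1581.27, sigma = 302.02,
                                 seed = 1L) {
  n <- check_count(n, "n")
  check_positive(mu, "mu")
  check_positive(sigma, "sigma")
  set.seed(seed)
  d <- rnorm(n, mu, sigma)
  while (any(d <= 0)) d[d <= 0] <- rnorm(sum(d <= 0), mu, sigma)
  tibble(diameter_nm = d)
}

#' Golden-Ratio walk (step-ratio positive control)
#'
#' A single 2-D walk whose consecutive step lengths grow by exactly phi
#' (optionally perturbed by multiplicative log-normal noise) with uniform
#' random turning angles: every consecutive step-length ratio equals phi,
#' making it a positive control for [step_ratios()].
#'
#' @param n_steps Number of steps (>= 3).
#' @param seed Integer seed.
#' @param length_noise Multiplicative noise SD on step lengths (0 = exact).
#' @return A `trajectory_tbl` with one particle and `n_steps + 1` frames.
#' @export
gen_golden_walk <- function(n_steps = 20, seed = 1L, length_noise = 0) {
  n_steps <- check_count(n_steps, "n_steps", min = 3)
  if (length_noise < 0) abort("`length_noise` must be >= 0.")
  set.seed(seed)
  phi <- golden_ratio()
  len <- phi^(seq_len(n_steps) - 1)
  if (length_noise > 0) len <- len * exp(rnorm(n_steps, 0, length_noise))
  ang <- runif(n_steps, 0, 2 * pi)
  x <- cumsum(c(0, len * cos(ang)))
  y <- cumsum(c(0, len * sin(ang)))
  out <- tibble(time = seq_len(n_steps + 1) - 1, particle = 1L, x = x, y = y)
  attr(out, "frame_interval") <- 1
  class(out) <- c("trajectory_tbl", class(out))
  out
}
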