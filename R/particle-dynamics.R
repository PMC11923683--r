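# Signal-modulated Brownian dynamics of proteinoid microspheres in a 2-D
# box: Euler-Maruyama integration of
#   dr_i = alpha * S(t) * u_i dt + sigma dW_t
# where u_i is a fixed random unit heading per particle, so the stimulus
# modulates each particle's drift speed while the ensemble stays isotropic.

#' Simulate signal-modulated Brownian microsphere motion
#'
#' Particles start uniformly distributed in the box and evolve by
#' Euler-Maruyama: per step, a drift `alpha * S(t) * u_i * dt` along the
#' particle's fixed random unit heading `u_i`, plus independent Gaussian
#' increments of standard deviation `noise_sigma * sqrt(dt)` per axis.
#' Boundaries either reflect or wrap (periodic). The same seed reproduces
#' the trace exactly.
#'
#' @param signal Driving signal `S(t)`: a `time`/`value` data frame covering
#'   at least `t_end` seconds (values expected in [-1, 1]), or `NULL` for
#'   pure Brownian motion (`S = 0`).
#' @param n_particles Number of particles (default 100).
#' @param box Box dimensions `c(Lx, Ly)` in nm (default 1000 x 1000).
#' @param alpha Drift gain, nm per unit signal per second.
#' @param noise_sigma Wiener scale, nm per sqrt(second).
#' @param dt Time step in seconds (default 0.01).
#' @param t_end End time in seconds (default 50).
#' @param seed Integer seed.
#' @param boundary `"reflect"` (default) or `"periodic"`.
#' @return A long tibble of class `trajectory_tbl` with columns `time` (s),
#'   `particle` (id), `x`, `y` (nm), and attributes `frame_interval`,
#'   `box`, `boundary`.
#' @export
simulate_particles <- function(signal = NULL, n_particles = 100,
                               box = c(1000, 1000), alpha = 0,
                               noise_sigma = 10, dt = 0.01, t_end = 50,
                               seed = 1L,
                               boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  n_particles <- check_count(n_particles, "n_particles")
  check_positive(dt, "dt")
  check_positive(t_end, "t_end")
  if (dt >= t_end) abort("`dt` must be smaller than `t_end`.")
  if (noise_sigma < 0 || alpha < 0) abort("`alpha` and `noise_sigma` must be >= 0.")
  n_steps <- as.integer(round(t_end / dt))
  times <- (0:n_steps) * dt
  s_fun <- if (is.null(signal)) {
    function(t) 0
  } else {
    sg <- as_sig(signal)
    dur <- (length(sg$values) - 1) / sg$fs
    if (dur + 1e-9 < t_end) abort("`signal` must cover at least `t_end` seconds.")
    function(t) approx(sg$t0 + (seq_along(sg$values) - 1) / sg$fs,
                       sg$values, xout = t, rule = 2)$y
  }
  set.seed(seed)
  x <- runif(n_particles, 0, box[1])
  y <- runif(n_particles, 0, box[2])
  headings <- runif(n_particles, 0, 2 * pi)
  ux <- cos(headings)
  uy <- sin(headings)
  s_vals <- s_fun(times[-length(times)])
  if (length(s_vals) == 1) s_vals <- rep(s_vals, n_steps)
  X <- matrix(NA_real_, n_steps + 1, n_particles)
  Y <- matrix(NA_real_, n_steps + 1, n_particles)
  X[1, ] <- x
  Y[1, ] <- y
  sq <- noise_sigma * sqrt(dt)
  for (k in seq_len(n_steps)) {
    drift <- alpha * s_vals[k] * dt
    x <- x + drift * ux + rnorm(n_particles, 0, sq)
    y <- y + drift * uy + rnorm(n_particles, 0, sq)
    if (boundary == "reflect") {
      x <- reflect_coord(x, box[1])
      y <- reflect_coord(y, box[2])
    } else {
      x <- x %% box[1]
      y <- y %% box[2]
    }
    X[k + 1, ] <- x
    Y[k + 1, ] <- y
  }
  out <- tibble(
    time = rep(times, each = n_particles),
    particle = rep(seq_len(n_particles), times = n_steps + 1),
    x = as.vector(t(X)),
    y = as.vector(t(Y))
  )
  attr(out, "frame_interval") <- dt
  attr(out, "box") <- box
  attr(out, "boundary") <- boundary
  class(out) <- c("trajectory_tbl", class(out))
  out
}

# Reflect positions into [0, L] (handles multiple bounces).
reflect_coord <- function(v, L) {
  v <- v %% (2 * L)
  ifelse(v > L, 2 * L - v, v)
}

#' Mean inter-particle distance of one frame
#'
#' Mean Euclidean distance over all unordered particle pairs. For points
#' uniform in an `L x L` box the expectation is `0.52141 * L`.
#'
#' @param positions A data frame with `x` and `y` columns (one row per
#'   particle), e.g. one frame of a `trajectory_tbl`.
#' @return Mean pairwise distance (same units as the coordinates).
#' @examples
#' mean_interparticle_distance(data.frame(x = c(0, 3), y = c(0, 4))) # 5
#' @export
mean_interparticle_distance <- function(positions) {
  if (nrow(positions) < 2) abort("need at least 2 particles.")
  mean(dist(cbind(positions$x, positions$y)))
}

#' Histogram of pairwise inter-particle distances
#'
#' @inheritParams mean_interparticle_distance
#' @param bins Number of equal-width bins (default 30).
#' @return A tibble with columns `mid` (bin centre), `lo`, `hi` and `count`;
#'   counts sum to `n(n-1)/2`.
#' @export
distance_histogram <- function(positions, bins = 30) {
  if (nrow(positions) < 2) abort("need at least 2 particles.")
  bins <- check_count(bins, "bins")
  d <- as.numeric(dist(cbind(positions$x, positions$y)))
  brk <- seq(0, max(d) * (1 + 1e-12), length.out = bins + 1)
  h <- graphics::hist(d, breaks = brk, plot = FALSE)
  tibble(mid = h$mids, lo = brk[-length(brk)], hi = brk[-1], count = h$counts)
}

#' Mean inter-particle distance over time
#'
#' @param trace A `trajectory_tbl` (long tibble `time`, `particle`, `x`,
#'   `y`).
#' @return A signal tibble with columns `time` and `value` (the mean
#'   pairwise distance of each frame).
#' @export
distance_timeseries <- function(trace) {
  out <- trace |>
    group_by(.data$time) |>
    summarise(value = mean_interparticle_distance(
      data.frame(x = .data$x, y = .data$y)), .groups = "drop")
  fi <- attr(trace, "frame_interval")
  if (!is.null(fi)) attr(out, "sample_rate") <- 1 / fi
  out
}
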