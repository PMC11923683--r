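# Trajectory analysis: mean displacement, time-and-ensemble MSD, exponential
# (confined) and power-law (anomalous) fits, diffusion coefficient, and
# consecutive step-size ratios against the Golden Ratio.

#' Coerce a trajectory table
#'
#' Accepts the long tibble produced by [simulate_particles()] /
#' [gen_confined_trajectories()], or any data frame with columns
#' `particle` (or `particle_id`) and `x`, `y`, ordered in time per particle
#' (via a `time` or `frame` column).
#'
#' @param traj Trajectory data frame.
#' @param frame_interval Seconds between consecutive frames; taken from the
#'   `frame_interval` attribute if absent.
#' @return A standardized `trajectory_tbl`.
#' @export
as_trajectory <- function(traj, frame_interval = NULL) {
  nm <- names(traj)
  pid <- intersect(c("particle", "particle_id"), nm)[1]
  if (is.na(pid) || !all(c("x", "y") %in% nm)) {
    abort("`traj` needs columns particle/particle_id, x, y.")
  }
  ord <- intersect(c("time", "frame"), nm)[1]
  out <- tibble(particle = traj[[pid]], x = traj$x, y = traj$y)
  if (!is.na(ord)) {
    out$time <- traj[[ord]]
    out <- arrange(out, .data$particle, .data$time)
  }
  fi <- frame_interval %||% attr(traj, "frame_interval")
  if (is.null(fi)) {
    fi <- if (!is.na(ord) && ord == "time") {
      median(diff(sort(unique(out$time))))
    } else 1
  }
  attr(out, "frame_interval") <- fi
  class(out) <- unique(c("trajectory_tbl", class(out)))
  out
}

#' Read a trajectory CSV
#'
#' Reads `frame,particle_id,x_um,y_um` (or `x`,`y`) trajectory tables.
#'
#' @param path CSV path.
#' @param frame_interval Seconds per frame.
#' @return A `trajectory_tbl`.
#' @export
read_trajectories <- function(path, frame_interval = 1) {
  df <- utils::read.csv(path)
  names(df) <- sub("^x_um$", "x", sub("^y_um$", "y", names(df)))
  as_trajectory(df, frame_interval = frame_interval)
}

traj_split <- function(traj) {
  split(traj[c("x", "y")], traj$particle)
}

#' Ensemble mean displacement per frame
#'
#' Arithmetic mean of particle positions at each frame, the ensemble
#' centre-of-mass track.
#'
#' @inheritParams as_trajectory
#' @return A tibble with columns `time`, `x_mean`, `y_mean`.
#' @export
mean_displacement <- function(traj, frame_interval = NULL) {
  traj <- as_trajectory(traj, frame_interval)
  if (nrow(traj) == 0) abort("empty trajectory set.")
  fi <- attr(traj, "frame_interval")
  per <- traj_split(traj)
  n_frames <- min(vapply(per, nrow, integer(1)))
  xm <- rowMeans(vapply(per, function(p) p$x[seq_len(n_frames)],
                        numeric(n_frames)))
  ym <- rowMeans(vapply(per, function(p) p$y[seq_len(n_frames)],
                        numeric(n_frames)))
  tibble(time = (seq_len(n_frames) - 1) * fi, x_mean = xm, y_mean = ym)
}

#' Mean squared displacement
#'
#' Time-and-ensemble averaged MSD: for each lag `tau = k * frame_interval`,
#' the mean over particles and over all (overlapping, by default) start
#' times of `|r(t + tau) - r(t)|^2`. `MSD(0) = 0` by definition. Pure-mode
#' averages are available: `"time"` keeps the per-particle time average but
#' still averages the resulting curves, `"ensemble"` uses only the start
#' time t = 0.
#'
#' @inheritParams as_trajectory
#' @param max_lag Largest lag in frames; default half the shortest record.
#' @param average `"both"` (default), `"time"` (overlapping windows,
#'   identical to `"both"`) or `"ensemble"` (origin-based displacements
#'   only).
#' @return A tibble of class `msd_tbl` with columns `lag` (s), `msd`
#'   (squared coordinate units) and `n_pairs`.
#' @export
msd <- function(traj, max_lag = NULL, average = c("both", "time", "ensemble"),
                frame_interval = NULL) {
  average <- match.arg(average)
  traj <- as_trajectory(traj, frame_interval)
  fi <- attr(traj, "frame_interval")
  per <- traj_split(traj)
  n_min <- min(vapply(per, nrow, integer(1)))
  if (n_min < 2) abort("need at least 2 frames per particle.")
  if (is.null(max_lag)) max_lag <- max(1L, (n_min - 1L) %/% 2L)
  max_lag <- check_count(max_lag, "max_lag")
  if (max_lag >= n_min) abort("`max_lag` must be below the record length.")
  acc <- numeric(max_lag)
  cnt <- numeric(max_lag)
  for (p in per) {
    np <- nrow(p)
    for (k in seq_len(min(max_lag, np - 1L))) {
      if (average == "ensemble") {
        d2 <- (p$x[1 + k] - p$x[1])^2 + (p$y[1 + k] - p$y[1])^2
        acc[k] <- acc[k] + d2
        cnt[k] <- cnt[k] + 1
      } else {
        i <- seq_len(np - k)
        d2 <- (p$x[i + k] - p$x[i])^2 + (p$y[i + k] - p$y[i])^2
        acc[k] <- acc[k] + sum(d2)
        cnt[k] <- cnt[k] + length(i)
      }
    }
  }
  out <- tibble(lag = c(0, seq_len(max_lag) * fi),
                msd = c(0, acc / pmax(cnt, 1)),
                n_pairs = c(length(per), cnt))
  class(out) <- c("msd_tbl", class(out))
  out
}

#' Exponential (confined-diffusion) fit of an MSD curve
#'
#' Nonlinear least-squares fit of the saturating model
#' `MSD(tau) = y0 + A * exp(R0 * tau)`. For confined motion `A < 0` and
#' `R0 < 0`: the curve rises quickly on the time scale `1/|R0|` and levels
#' off at the plateau `y0`. Initial values follow the curve geometry
#' (`y0` from the plateau, `R0` from the half-saturation lag), with a small
#' multi-start sweep on failure.
#'
#' @param curve An `msd_tbl` from [msd()] (the zero lag is dropped for
#'   fitting).
#' @param weights Optional per-lag weights (e.g. `n_pairs`).
#' @return An object of class `msd_fit` supporting [tidy()], [glance()] and
#'   `autoplot()`; elements include `params` (`y0`, `A`, `R0`), standard
#'   errors, `r_squared`, `adj_r_squared`, `reduced_chi2`,
#'   `characteristic_time` (`1/|R0|`), `converged`.
#' @export
fit_msd_exponential <- function(curve, weights = NULL) {
  d <- as.data.frame(curve[curve$lag > 0, c("lag", "msd")])
  if (nrow(d) < 4) abort("need at least 4 positive-lag MSD points.")
  if (stats::sd(d$msd) == 0) {
    return(new_msd_fit("exponential",
                       params = c(y0 = d$msd[1], A = 0, R0 = 0),
                       se = c(y0 = NA, A = NA, R0 = NA), fitted = d$msd,
                       data = d, converged = FALSE, degenerate = TRUE))
  }
  y0_init <- max(d$msd)
  a_init <- d$msd[1] - y0_init
  half_lag <- d$lag[which.min(abs(d$msd - (y0_init + a_init / 2)))]
  r0_init <- -1 / max(half_lag, d$lag[1])
  w <- weights %||% rep(1, nrow(d))
  starts <- list(c(y0_init, a_init, r0_init),
                 c(y0_init, a_init, r0_init * 5),
                 c(y0_init, a_init, r0_init / 5),
                 c(mean(d$msd), -mean(d$msd), -1 / mean(d$lag)))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(msd ~ y0 + A * exp(R0 * lag), data = d,
                        start = list(y0 = st[1], A = st[2], R0 = st[3]),
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(new_msd_fit("exponential",
                       params = c(y0 = y0_init, A = a_init, R0 = r0_init),
                       se = c(y0 = NA, A = NA, R0 = NA),
                       fitted = rep(mean(d$msd), nrow(d)), data = d,
                       converged = FALSE, degenerate = FALSE))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(y0 = NA, A = NA, R0 = NA))
  new_msd_fit("exponential", params = cf, se = se, fitted = fitted(fit),
              data = d, converged = TRUE, degenerate = FALSE)
}

new_msd_fit <- function(model, params, se, fitted, data, converged,
                        degenerate, extra = list()) {
  resid <- data$msd - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((data$msd - mean(data$msd))^2)
  n <- nrow(data)
  k <- length(params)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  obj <- c(list(
    model = model,
    params = params,
    se = se,
    data = as_tibble(data),
    fitted = as.numeric(fitted),
    r_squared = r2,
    adj_r_squared = if (n > k + 1 && ss_tot > 0)
      1 - (1 - r2) * (n - 1) / (n - k - 1) else NA_real_,
    reduced_chi2 = if (n > k) ss_res / (n - k) else NA_real_,
    converged = converged,
    degenerate = degenerate
  ), extra)
  if (model == "exponential") {
    obj$characteristic_time <- if (params[["R0"]] != 0)
      1 / abs(params[["R0"]]) else Inf
  }
  class(obj) <- "msd_fit"
  obj
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit: %s>\n", x$model))
  print(tidy(x))
  cat(sprintf("R^2 = %.4f, adj R^2 = %.4f, reduced chi^2 = %.4g\n",
              x$r_squared, x$adj_r_squared, x$reduced_chi2))
  if (!x$converged) cat("NOTE: fit did not converge; values are diagnostics.\n")
  invisible(x)
}

#' Power-law (anomalous-diffusion) fit of an MSD curve
#'
#' Fits `MSD = K * tau^alpha` by linear regression of `log(msd)` on
#' `log(lag)` over positive lags. `alpha = 1` indicates normal Brownian
#' diffusion, `alpha < 1` subdiffusion, `alpha > 1` superdiffusion
#' (ballistic motion gives 2).
#'
#' @inheritParams fit_msd_exponential
#' @return An `msd_fit` object with `params` (`K`, `alpha`).
#' @export
fit_msd_powerlaw <- function(curve) {
  d <- as.data.frame(curve[curve$lag > 0, c("lag", "msd")])
  if (any(d$msd <= 0)) abort("power-law fit needs strictly positive MSD values.")
  if (nrow(d) < 2) abort("need at least 2 positive-lag points.")
  fit <- lm(log(msd) ~ log(lag), data = d)
  cf <- coef(fit)
  params <- c(K = exp(cf[[1]]), alpha = cf[[2]])
  # SEs are meaningless (and warned about) on numerically perfect fits
  se_log <- suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  se <- c(K = exp(cf[[1]]) * se_log[[1]], alpha = se_log[[2]])
  new_msd_fit("powerlaw", params = params, se = se,
              fitted = exp(fitted(fit)), data = d, converged = TRUE,
              degenerate = FALSE)
}

#' Diffusion coefficient from an exponential MSD fit
#'
#' Uses the model's initial slope: `d MSD/d tau` at `tau = 0` equals
#' `A * R0`, so `D = A * R0 / (2 * dimensions)` (in 2-D, `MSD = 4 D tau`
#' for small lags).
#'
#' @param fit An exponential `msd_fit`.
#' @param dimensions Spatial dimensionality (1, 2 or 3).
#' @return Diffusion coefficient in squared coordinate units per second.
#' @export
diffusion_coefficient <- function(fit, dimensions = 2) {
  if (!inherits(fit, "msd_fit") || fit$model != "exponential") {
    abort("`fit` must be an exponential msd_fit.")
  }
  if (!dimensions %in% c(1, 2, 3)) abort("`dimensions` must be 1, 2 or 3.")
  slope0 <- fit$params[["A"]] * fit$params[["R0"]]
  max(slope0, 0) / (2 * dimensions)
}

#' Consecutive step-size ratios
#'
#' For each particle, the ratio of consecutive displacement magnitudes
#' `R_i = |dr_{i+1}| / |dr_i|`, summarized against the Golden Ratio.
#' Ratios whose denominator step has zero length are dropped (and counted)
#' unless `keep_singular = TRUE`, which keeps them as `Inf`-prone raw
#' ratios (zero/zero becomes `NaN` and is still dropped).
#'
#' @inheritParams as_trajectory
#' @param keep_singular Keep ratios with zero-length denominator steps.
#' @param phi_tol Half-width of the "near phi" window (default 0.05).
#' @return A list of class `step_ratio_summary`: `ratios` (tibble
#'   `particle`, `step`, `ratio`) and `summary` (one-row tibble with
#'   `mean`, `median`, `sd`, `n`, `n_singular`, `frac_near_phi`, `phi`).
#' @export
step_ratios <- function(traj, keep_singular = FALSE, phi_tol = 0.05,
                        frame_interval = NULL) {
  traj <- as_trajectory(traj, frame_interval)
  per <- traj_split(traj)
  if (any(vapply(per, nrow, integer(1)) < 3)) {
    abort("need at least 3 frames per particle.")
  }
  rows <- imap(per, function(p, id) {
    step_len <- sqrt(diff(p$x)^2 + diff(p$y)^2)
    num <- step_len[-1]
    den <- step_len[-length(step_len)]
    r <- num / den
    keep <- if (keep_singular) is.finite(r) | is.infinite(r) else den > 0
    keep <- keep & !is.nan(r)
    tibble(particle = id, step = which(keep), ratio = r[keep],
           n_singular = sum(den == 0))
  })
  all <- bind_rows(rows)
  if (nrow(all) == 0 || all(!is.finite(all$ratio))) {
    abort("all steps have zero length; ratios undefined.")
  }
  fin <- all$ratio[is.finite(all$ratio)]
  phi <- golden_ratio()
  summary <- tibble(
    mean = mean(fin), median = median(fin),
    sd = stats::sd(fin), n = length(fin),
    n_singular = sum(all$n_singular[!duplicated(all$particle)]),
    frac_near_phi = mean(abs(fin - phi) <= phi_tol),
    phi = phi
  )
  structure(list(ratios = all[c("particle", "step", "ratio")],
                 summary = summary),
            class = "step_ratio_summary")
}

#' @export
print.step_ratio_summary <- function(x, ...) {
  cat("<step_ratio_summary>\n")
  print(x$summary)
  invisible(x)
}
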