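# Capacitive (RC) model of the proteinoid's electrical response: time
# constant, phi-decay charging response, and parallel-RC impedance.

#' RC parameter set
#'
#' Bundles resistance, capacitance, the derived time constant
#' `tau = R * C`, and the time step that maps a discrete stimulus index to
#' physical time.
#'
#' @param R Resistance in ohms (> 0).
#' @param C Capacitance in farads (> 0).
#' @param dt Seconds per discrete stimulus step (> 0); default 1 ms.
#' @return A list of class `rc_params` with elements `R`, `C`, `tau`, `dt`.
#' @examples
#' rc_params(128, 2.888e-6)$tau * 1e6 # 369.664 us
#' @export
rc_params <- function(R, C, dt = 1e-3) {
  check_positive(R, "R")
  check_positive(C, "C")
  check_positive(dt, "dt")
  structure(list(R = R, C = C, tau = R * C, dt = dt), class = "rc_params")
}

#' @export
print.rc_params <- function(x, ...) {
  cat(sprintf("<rc_params> R = %g ohm, C = %g F, tau = %g s, dt = %g s\n",
              x$R, x$C, x$tau, x$dt))
  invisible(x)
}

#' RC time constant
#'
#' @param R Resistance in ohms (> 0).
#' @param C Capacitance in farads (> 0).
#' @return `R * C` in seconds.
#' @examples
#' time_constant(128, 2.888e-6) # 369.664e-6 s
#' @export
time_constant <- function(R, C) {
  check_positive(R, "R")
  check_positive(C, "C")
  R * C
}

#' Capacitive response to the Golden-Ratio decay stimulus
#'
#' The charging response of the capacitive proteinoid membrane driven by the
#' phi-decay input: `V_c(t_n) = v0 * phi^(-n/scale) * (1 - exp(-t_n/tau))`
#' with `t_n = n * dt`. The response starts at 0, stays strictly below the
#' instantaneous input for `n > 0`, and converges to the input envelope once
#' `t >> tau`. With `scale = Inf` (no decay) this is the textbook RC step
#' response `v0 * (1 - exp(-t/tau))`.
#'
#' @param v0 Initial stimulus voltage (> 0).
#' @param params An [rc_params()] object.
#' @param n_steps Number of discrete steps.
#' @param scale Decay divisor of the phi exponent (as in
#'   [golden_ratio_decay()]); may be `Inf` for pure charging.
#' @return A signal tibble (`time`, `value`) with a `sample_rate` attribute
#'   of `1/dt`, plus the driving `input` voltage as a column.
#' @export
golden_capacitive_response <- function(v0 = 10, params, n_steps = 1000,
                                       scale = 100) {
  check_positive(v0, "v0")
  if (!inherits(params, "rc_params")) abort("`params` must be an rc_params object.")
  n_steps <- check_count(n_steps, "n_steps")
  if (!(is.numeric(scale) && scale > 0)) abort("`scale` must be positive.")
  n <- seq_len(n_steps) - 1
  t_n <- n * params$dt
  input <- v0 * golden_ratio()^(-n / scale)
  vc <- input * (1 - exp(-t_n / params$tau))
  out <- sig_tbl(vc, 1 / params$dt)
  out$input <- input
  out
}

#' Parallel-RC impedance
#'
#' Magnitude and phase of the parallel resistor-capacitor impedance
#' `|Z| = R / sqrt(1 + (2 pi f R C)^2)`, `theta = -atan(2 pi f R C)`.
#' At DC this is `(R, 0 deg)`; with rising frequency the magnitude falls
#' toward 0 and the phase toward -90 deg, the capacitive lag.
#'
#' @param params An [rc_params()] object.
#' @param frequency Frequencies in Hz (>= 0); vectorized.
#' @return A tibble with columns `frequency` (Hz), `magnitude` (ohm) and
#'   `phase_deg` (degrees, in (-90, 0]).
#' @examples
#' rc_impedance(rc_params(128, 2.888e-6), c(0, 200))
#' @export
rc_impedance <- function(params, frequency) {
  if (!inherits(params, "rc_params")) abort("`params` must be an rc_params object.")
  if (any(frequency < 0)) abort("`frequency` must be nonnegative.")
  wRC <- 2 * pi * frequency * params$R * params$C
  tibble(frequency = frequency,
         magnitude = params$R / sqrt(1 + wRC^2),
         phase_deg = -atan(wRC) * 180 / pi)
}
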