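#' Inverse-Fibonacci voltage sequence
#'
#' Builds the stepped stimulus obtained by dividing an initial voltage by
#' successive Fibonacci numbers: `value[k] = v0 / F(k + 1)` for the 0-based
#' step index `k`. The first two steps equal `v0` (since `F(1) = F(2) = 1`)
#' and the series is non-increasing thereafter.
#'
#' @param v0 Initial voltage in volts (> 0). Default 10 V.
#' @param n_steps Number of steps (>= 1).
#' @return A tibble with columns `step` (0-based index) and `value` (volts),
#'   of class `stimulus_tbl`, carrying `kind` and `params` attributes.
#' @examples
#' inverse_fibonacci_voltage(10, 10)
#' @export
inverse_fibonacci_voltage <- function(v0 = 10, n_steps = 1000) {
  check_positive(v0, "v0")
  n_steps <- check_count(n_steps, "n_steps")
  f <- fibonacci_numbers(n_steps)
  out <- tibble(step = seq_len(n_steps) - 1L, value = v0 / f)
  new_stimulus(out, kind = "inverse_fibonacci",
               params = list(v0 = v0, n_steps = n_steps))
}

#' Golden-Ratio voltage decay sequence
#'
#' Exponential decay governed by the Golden Ratio:
#' `value[n] = v0 * phi^(-n / scale)` for 0-based step `n`. With the defaults
#' (`v0 = 10`, 1000 steps, `scale = 100`) the sequence ends near 0.0817 V.
#' On a log scale the sequence is a straight line of slope
#' `-log(phi) / scale` per step.
#'
#' @param v0 Initial voltage in volts (> 0).
#' @param n_steps Number of steps (>= 1).
#' @param scale Decay-slowing divisor in the exponent (> 0); 100 reproduces
#'   the gradual decline used throughout this package.
#' @return A `stimulus_tbl` tibble with columns `step`, `value`.
#' @examples
#' tail(golden_ratio_decay(10, 1000, 100), 1) # ~ 0.0817 V
#' @export
golden_ratio_decay <- function(v0 = 10, n_steps = 1000, scale = 100) {
  check_positive(v0, "v0")
  check_positive(scale, "scale")
  n_steps <- check_count(n_steps, "n_steps")
  n <- seq_len(n_steps) - 1
  out <- tibble(step = as.integer(n), value = v0 * golden_ratio()^(-n / scale))
  new_stimulus(out, kind = "golden_decay",
               params = list(v0 = v0, n_steps = n_steps, scale = scale))
}

new_stimulus <- function(tbl, kind, params) {
  attr(tbl, "kind") <- kind
  attr(tbl, "params") <- params
  class(tbl) <- c("stimulus_tbl", class(tbl))
  tbl
}

#' Fibonacci tone bank
#'
#' Synthesizes one pure sinusoid per Fibonacci frequency and their combined
#' superposition, renormalized so that `max(|y|) = 1`. The default set is the
#' six Fibonacci-number frequencies 144, 233, 377, 610, 987 and 1597 Hz, 5 s
#' each. The per-tone amplitudes weight the sum before renormalization;
#' equal weights are the default.
#'
#' @param frequencies Tone frequencies in Hz; all must lie below the Nyquist
#'   frequency `sample_rate / 2`.
#' @param duration Tone duration in seconds.
#' @param sample_rate Sampling frequency in Hz.
#' @param amplitudes Per-tone weights, recycled to the number of tones.
#' @param mode How the combined stimulus is formed: `"sum"` superposes the
#'   tones over a common `duration`; `"concat"` plays them back to back.
#' @return A list with elements `tones` (list of audio tibbles, columns
#'   `time`, `value`, each with `sample_rate` and `components` attributes)
#'   and `combined` (one audio tibble normalized to peak 1).
#' @examples
#' bank <- fibonacci_tone_bank(duration = 0.05, sample_rate = 8000,
#'                             frequencies = c(144, 233))
#' max(abs(bank$combined$value))
#' @export
fibonacci_tone_bank <- function(frequencies = c(144, 233, 377, 610, 987, 1597),
                                duration = 5, sample_rate = 44100,
                                amplitudes = 1, mode = c("sum", "concat")) {
  mode <- match.arg(mode)
  check_positive(duration, "duration")
  check_positive(sample_rate, "sample_rate")
  if (any(frequencies >= sample_rate / 2)) {
    abort("all `frequencies` must be below the Nyquist frequency.")
  }
  if (any(frequencies <= 0)) abort("`frequencies` must be positive.")
  amplitudes <- rep_len(amplitudes, length(frequencies))
  t <- seq(0, duration, by = 1 / sample_rate)
  t <- t[-length(t)]
  tones <- map2(frequencies, amplitudes, function(f, a) {
    sig_tbl(sin(2 * pi * f * t), sample_rate, class = "audio_tbl",
            components = tibble(frequency = f, amplitude = a, phase = 0))
  })
  raw <- map2(tones, amplitudes, function(tn, a) a * tn$value)
  combined_v <- switch(mode,
    sum = Reduce(`+`, raw),
    concat = unlist(raw, use.names = FALSE)
  )
  peak <- max(abs(combined_v))
  if (peak > 0) combined_v <- combined_v / peak
  combined <- sig_tbl(combined_v, sample_rate, class = "audio_tbl",
                      components = tibble(frequency = frequencies,
                                          amplitude = amplitudes / peak,
                                          phase = 0))
  list(tones = tones, combined = combined)
}

#' Golden-Ratio fractal soundscape
#'
#' Additive synthesis over a geometric progression of harmonics
#' `f_n = f0 * phi^n`, `n = 0..n_harmonics`, each with a random phase drawn
#' from a seeded generator, then amplitude-modulated at `f_mod = f0 / phi^5`
#' and normalized to peak amplitude 1. Harmonics at or above the Nyquist
#' frequency are dropped with a warning (with the defaults,
#' `220 * phi^10` ~ 27.1 kHz exceeds the 22.05 kHz Nyquist).
#'
#' The modulation law is `z_mod(t) = z(t) * (1 - depth/2 + (depth/2) *
#' sin(2 pi f_mod t))`: depth 1 gives the half-raised sine envelope
#' `(1 + sin)/2` with mean 1/2.
#'
#' @param f0 Base frequency in Hz.
#' @param n_harmonics Number of phi-spaced harmonics above `f0`.
#' @param sample_rate Sampling frequency in Hz.
#' @param duration Duration in seconds.
#' @param seed Integer seed for the random phases (default 1).
#' @param mod_depth Amplitude-modulation depth in [0, 1].
#' @return An audio tibble (`time`, `value`) with `sample_rate`,
#'   `components` and `f_mod` attributes; `max(|value|) = 1`.
#' @export
fractal_soundscape <- function(f0 = 220, n_harmonics = 10,
                               sample_rate = 44100, duration = 5,
                               seed = 1L, mod_depth = 1) {
  check_positive(f0, "f0")
  check_positive(duration, "duration")
  n_harmonics <- check_count(n_harmonics, "n_harmonics", min = 0)
  if (mod_depth < 0 || mod_depth > 1) abort("`mod_depth` must be in [0, 1].")
  phi <- golden_ratio()
  freqs <- f0 * phi^(0:n_harmonics)
  keep <- freqs < sample_rate / 2
  if (any(!keep)) {
    warn(sprintf("dropping %d harmonic(s) at or above Nyquist (%.0f Hz): %s",
                 sum(!keep), sample_rate / 2,
                 paste(sprintf("%.1f", freqs[!keep]), collapse = ", ")))
    freqs <- freqs[keep]
  }
  t <- seq(0, duration, by = 1 / sample_rate)
  t <- t[-length(t)]
  rng <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    phases <- runif(length(freqs), 0, 2 * pi)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
    phases
  })
  z <- Reduce(`+`, map2(freqs, rng, function(f, th) sin(2 * pi * f * t + th)))
  f_mod <- f0 / phi^5
  env <- 1 - mod_depth / 2 + (mod_depth / 2) * sin(2 * pi * f_mod * t)
  z <- z * env
  z <- z / max(abs(z))
  sig_tbl(z, sample_rate, class = "audio_tbl",
          components = tibble(frequency = freqs, amplitude = 1, phase = rng),
          f_mod = f_mod)
}
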