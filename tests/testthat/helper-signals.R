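# Fixture builders shared across tests. Everything is generated in code;
# seeds are fixed so expectations are stable.

PHI <- (1 + sqrt(5)) / 2

make_tone <- function(freq, fs, duration, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

# Correlated standard-normal pair with exact population correlation rho.
make_gaussian_pair <- function(n, rho, seed) {
  set.seed(seed)
  a <- rnorm(n)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  list(x = a, y = b)
}

# Binary lag-1 copy channel: y[t+1] = x[t].
make_copy_channel <- function(n, seed) {
  set.seed(seed)
  x <- sample(0:1, n, replace = TRUE)
  list(x = x, y = c(0L, x[-n]))
}

sig_tbl_for_test <- function(value, fs) {
  tibble::tibble(time = (seq_along(value) - 1) / fs, value = value)
}

# Single-particle trajectory from per-step lengths and angles.
make_walk <- function(step_lengths, angles) {
  tibble::tibble(
    time = seq_len(length(step_lengths) + 1) - 1,
    particle = 1L,
    x = cumsum(c(0, step_lengths * cos(angles))),
    y = cumsum(c(0, step_lengths * sin(angles)))
  )
}
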