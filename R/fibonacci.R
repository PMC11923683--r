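# Exact Fibonacci numbers. F(1000) has 209 decimal digits, far beyond both
# 32-bit integers and the 2^53 exact range of doubles, so terms are carried as
# little-endian base-1e7 limb vectors and rendered to decimal strings.

BIG_BASE <- 1e7

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BIG_BASE
    s[i] <- s[i] %% BIG_BASE
  }
  if (carry > 0) s <- c(s, carry)
  s
}

big_format <- function(a) {
  hi <- length(a)
  parts <- sprintf("%07.0f", rev(a[-hi]))
  paste0(c(sprintf("%.0f", a[hi]), parts), collapse = "")
}

big_to_double <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

#' Fibonacci numbers, exactly
#'
#' Computes `F(1), ..., F(n_terms)` with `F(1) = F(2) = 1` and
#' `F(k) = F(k-1) + F(k-2)` in exact arbitrary-precision integer arithmetic.
#' Terms are returned as decimal strings because large terms (e.g. `F(1000)`,
#' 209 digits) cannot be represented exactly in any native numeric type.
#'
#' @param n_terms Number of terms, a positive integer.
#' @return Character vector of `n_terms` exact decimal integers.
#' @seealso [fibonacci_numbers()] for a double-precision variant.
#' @examples
#' fibonacci_sequence(5) # "1" "1" "2" "3" "5"
#' @export
fibonacci_sequence <- function(n_terms) {
  n_terms <- check_count(n_terms, "n_terms")
  terms <- vector("list", n_terms)
  a <- 1
  b <- 1
  for (k in seq_len(n_terms)) {
    terms[[k]] <- a
    nxt <- big_add(a, b)
    a <- b
    b <- nxt
  }
  vapply(terms, big_format, character(1))
}

#' Fibonacci numbers as doubles
#'
#' Convenience variant of [fibonacci_sequence()] returning doubles. Exact up
#' to `F(78)` (the last term below 2^53); beyond that the nearest
#' representable double is returned.
#'
#' @inheritParams fibonacci_sequence
#' @return Numeric vector of length `n_terms`.
#' @export
fibonacci_numbers <- function(n_terms) {
  n_terms <- check_count(n_terms, "n_terms")
  out <- numeric(n_terms)
  a <- 1
  b <- 1
  for (k in seq_len(n_terms)) {
    out[k] <- a
    nxt <- a + b
    a <- b
    b <- nxt
  }
  out
}
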