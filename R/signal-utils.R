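# Internal canonical signal representation and coercion.
#
# User-facing functions accept either a data frame with `time` and `value`
# columns (the tibbles this package produces) or a bare numeric vector plus an
# explicit `sample_rate`. Internally everything is a list(values, fs, t0).

as_sig <- function(x, sample_rate = NULL, arg = "x") {
  if (is.data.frame(x)) {
    cols <- names(x)
    vcol <- if ("value" %in% cols) "value" else setdiff(cols, "time")[1]
    if (!"time" %in% cols || is.null(vcol)) {
      abort(sprintf("`%s` must have `time` and `value` columns.", arg))
    }
    tm <- as.numeric(x[["time"]])
    v <- as.numeric(x[[vcol]])
    if (length(v) < 2) abort(sprintf("`%s` must contain at least 2 samples.", arg))
    dt <- diff(tm)
    if (any(dt <= 0)) abort(sprintf("`%s` must be sampled at increasing times.", arg))
    sr <- attr(x, "sample_rate")
    if (is.null(sr)) sr <- 1 / median(dt)   # time column wins over the arg
    list(values = v, fs = sr, t0 = tm[1])
  } else if (is.numeric(x)) {
    if (is.null(sample_rate)) {
      abort(sprintf("`sample_rate` is required when `%s` is a bare vector.", arg))
    }
    list(values = as.numeric(x), fs = sample_rate, t0 = 0)
  } else {
    abort(sprintf("`%s` must be a data frame or numeric vector.", arg))
  }
}

as_sig_pair <- function(x, y, sample_rate = NULL) {
  sx <- as_sig(x, sample_rate, "x")
  sy <- as_sig(y, sample_rate, "y")
  if (length(sx$values) != length(sy$values)) {
    abort("`x` and `y` must have the same length.")
  }
  if (abs(sx$fs - sy$fs) > 1e-9 * sx$fs) {
    abort("`x` and `y` must share one sample rate.")
  }
  list(x = sx, y = sy)
}

# Build the tibble form of a signal: columns time, value.
sig_tbl <- function(values, sample_rate, t0 = 0, class = "phonoid_signal",
                    ...) {
  out <- tibble(time = t0 + (seq_along(values) - 1L) / sample_rate,
                value = as.numeric(values))
  attr(out, "sample_rate") <- sample_rate
  extras <- list(...)
  for (nm in names(extras)) attr(out, nm) <- extras[[nm]]
  class(out) <- c(class, class(out))
  out
}

#' Sample rate of a signal tibble
#'
#' Returns the `sample_rate` attribute if present, otherwise infers it from
#' the median spacing of the `time` column.
#'
#' @param x A signal tibble with a `time` column.
#' @return Sampling frequency in Hz.
#' @export
sample_rate <- function(x) {
  sr <- attr(x, "sample_rate")
  if (!is.null(sr)) return(sr)
  as_sig(x)$fs
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Hann window of length n (periodic form used for spectral framing).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

# Frame a vector into overlapping segments (columns); drops the ragged tail.
frame_signal <- function(v, seg, hop) {
  n_seg <- if (length(v) < seg) 0L else 1L + (length(v) - seg) %/% hop
  if (n_seg < 1) abort("segment longer than signal")
  idx <- outer(seq_len(seg), (seq_len(n_seg) - 1L) * hop, "+")
  matrix(v[idx], nrow = seg)
}
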