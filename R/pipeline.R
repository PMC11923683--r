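# End-to-end orchestration: stimulus -> (synthetic or recorded) response ->
# metric and information reports -> files + manifest, fully seeded.

pipeline_defaults <- function() {
  list(
    stimulus = list(kind = "golden_decay", v0 = 10, n_steps = 1000,
                    scale = 100, sample_rate = 2000,
                    frequencies = c(144, 233, 377, 610, 987, 1597),
                    duration = 5, f0 = 220, n_harmonics = 10),
    response = list(source = "synthetic", path = NULL, gain = 0.011,
                    dc_offset = -0.01, noise_sd = 0.001,
                    rc = list(R = 128, C = 2.888e-6)),
    analysis = list(n_bins = 16, bands = list(c(0, 10), c(30, 50),
                                              c(100, Inf)),
                    fib_freqs = c(144, 233, 377, 610, 987),
                    segment_length = NULL),
    seed = 1L
  )
}

validate_config <- function(config) {
  defaults <- pipeline_defaults()
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or YAML path.")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (sec in intersect(names(config), c("stimulus", "response", "analysis"))) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      abort(sprintf("unknown config key(s) in `%s`: %s", sec,
                    paste(bad, collapse = ", ")))
    }
    defaults[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  if (!is.null(config$seed)) defaults$seed <- as.integer(config$seed)
  defaults
}

#' Run the stimulus-response-analysis pipeline
#'
#' Generates the configured stimulus, obtains a response (synthetic by
#' default, or a recorded CSV), and computes the metric and information
#' reports. All artifacts (stimulus/response CSVs, JSON reports, a manifest
#' with the seed and a config hash) are written under `out_dir`. Reruns
#' with the same config and seed are bit-identical.
#'
#' @param config A nested list (or YAML file path) with optional sections
#'   `stimulus` (`kind` one of `"golden_decay"`, `"inverse_fibonacci"`,
#'   `"fib_tones"`, `"soundscape"`, plus its parameters and `sample_rate`),
#'   `response` (`source` `"synthetic"` or `"csv"`, `path`, `gain`,
#'   `dc_offset`, `noise_sd`, `rc`), `analysis` (`n_bins`, `bands`,
#'   `fib_freqs`, `segment_length`) and `seed`. Unknown keys are rejected
#'   by name.
#' @param out_dir Output directory (created if missing).
#' @return A list of class `phonoid_run`: `metrics` (one-row tibble),
#'   `info` (`info_report`), `manifest` (list), `paths` (named character).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("phonoid_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- cfg$stimulus
  stim <- switch(st$kind,
    golden_decay = {
      s <- golden_ratio_decay(st$v0, st$n_steps, st$scale)
      sig_tbl(s$value, st$sample_rate)
    },
    inverse_fibonacci = {
      s <- inverse_fibonacci_voltage(st$v0, st$n_steps)
      sig_tbl(s$value, st$sample_rate)
    },
    fib_tones = fibonacci_tone_bank(st$frequencies, st$duration,
                                    st$sample_rate)$combined,
    soundscape = fractal_soundscape(st$f0, st$n_harmonics, st$sample_rate,
                                    st$duration, seed = cfg$seed),
    abort(sprintf("unknown stimulus kind `%s`", st$kind))
  )
  rs <- cfg$response
  response <- if (identical(rs$source, "csv")) {
    if (is.null(rs$path) || !file.exists(rs$path)) {
      abort("response source is `csv` but `response$path` does not exist.")
    }
    read_stimulus(rs$path)
  } else {
    rc <- if (!is.null(rs$rc)) rc_params(rs$rc$R, rs$rc$C) else NULL
    gen_response_recording(stim, gain = rs$gain, dc_offset = rs$dc_offset,
                           rc = rc, noise_sd = rs$noise_sd, seed = cfg$seed)
  }
  an <- cfg$analysis
  fs <- sample_rate(stim)
  probe <- an$fib_freqs[an$fib_freqs < fs / 2]
  metrics <- signal_report(stim, response,
                           fib_freqs = if (length(probe)) probe else NULL)
  bands <- map(an$bands, function(b) {
    c(b[1], min(b[2], fs / 2 * 0.99))
  })
  bands <- purrr::keep(bands, function(b) b[2] > b[1] && b[1] < fs / 2)
  info <- info_report(stim, response, bands = bands, n_bins = an$n_bins)
  check_finite_report(metrics, "metrics")
  paths <- c(stimulus = file.path(out_dir, "stimulus.csv"),
             response = file.path(out_dir, "response.csv"),
             metrics = file.path(out_dir, "metrics.json"),
             info = file.path(out_dir, "info.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write_stimulus(stim, paths[["stimulus"]])
  write_stimulus(response, paths[["response"]])
  m_out <- as.list(metrics[setdiff(names(metrics), "band_power")])
  if (!is.null(metrics$band_power)) {
    m_out$band_power <- metrics$band_power[[1]]
  }
  jsonlite::write_json(m_out, paths[["metrics"]], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  jsonlite::write_json(list(summary = info$summary, bands = info$bands),
                       paths[["info"]], auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  manifest <- list(
    schema = "phonoid-run/1",
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stimulus_kind = st$kind,
    n_samples = nrow(stim),
    created_with = as.character(utils::packageVersion("phonoid"))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  structure(list(metrics = metrics, info = info, manifest = manifest,
                 paths = paths, config = cfg),
            class = "phonoid_run")
}

# Polynomial rolling hash over the deparsed config: a stable,
# dependency-free fingerprint (not cryptographic).
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

check_finite_report <- function(report, stage) {
  num <- vapply(report, is.numeric, logical(1))
  vals <- unlist(report[num])
  bad <- !is.finite(vals) & !is.na(vals)
  if (any(bad)) {
    abort(sprintf("non-finite value produced in stage `%s`: %s", stage,
                  paste(names(vals)[bad], collapse = ", ")))
  }
  invisible(report)
}

#' @export
print.phonoid_run <- function(x, ...) {
  cat("<phonoid_run>\n seed:", x$manifest$seed,
      " config:", x$manifest$config_hash, "\n")
  print(x$metrics)
  invisible(x)
}
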