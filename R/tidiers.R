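# broom-style methods for fitted MSD models.

#' Tidy an MSD fit
#'
#' @param x An `msd_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy msd_fit
#' @export
tidy.msd_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = unname(x$params),
         std.error = unname(x$se[names(x$params)]))
}

#' Glance at an MSD fit
#'
#' @param x An `msd_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `r.squared`, `adj.r.squared`,
#'   `reduced.chisq`, `nobs`, `converged`, and (for the exponential model)
#'   `characteristic.time`.
#' @method glance msd_fit
#' @export
glance.msd_fit <- function(x, ...) {
  out <- tibble(r.squared = x$r_squared,
                adj.r.squared = x$adj_r_squared,
                reduced.chisq = x$reduced_chi2,
                nobs = nrow(x$data),
                converged = x$converged)
  if (!is.null(x$characteristic_time)) {
    out$characteristic.time <- x$characteristic_time
  }
  out
}
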