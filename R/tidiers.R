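#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bootstrap calibration
#'
#' One row per phytoplankton group with the point estimate, bootstrap median
#' and robust standard deviation.
#'
#' @param x a [bootstrap_fit()] result.
#' @param ... unused.
#' @return A tibble with columns `wavelength`, `group`, `estimate`, `median`,
#'   `robust_sd`, `at_bound`.
#' @export
tidy.fourpop_boot <- function(x, ...) {
  tibble::tibble(
    wavelength = x$band,
    group = fourpop_groups,
    estimate = x$fit$estimate,
    median = unname(x$median),
    robust_sd = unname(x$robust_sd),
    at_bound = x$fit$at_bound
  )
}

#' Glance at a bootstrap calibration
#'
#' @inheritParams tidy.fourpop_boot
#' @return A one-row tibble with `wavelength`, `n_obs`, `n_boot`, `n_fail`,
#'   `converged` and `seed`.
#' @export
glance.fourpop_boot <- function(x, ...) {
  tibble::tibble(
    wavelength = x$band,
    n_obs = x$n_obs,
    n_boot = x$n_boot,
    n_fail = x$n_fail,
    converged = all(x$fit$converged),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}
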