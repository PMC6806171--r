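# Evaluation statistics computed in log10 space, the convention for
# absorption and chlorophyll quantities, which are close to lognormal.

check_pairs <- function(estimated, measured) {
  if (length(estimated) != length(measured)) {
    stop("`estimated` and `measured` must have equal length", call. = FALSE)
  }
  keep <- !is.na(estimated) & !is.na(measured)
  estimated <- estimated[keep]
  measured <- measured[keep]
  if (any(estimated <= 0) || any(measured <= 0)) {
    stop("values must be positive for log10-space statistics", call. = FALSE)
  }
  list(e = log10(estimated), m = log10(measured))
}

#' Root mean square error in log10 space
#'
#' `sqrt(mean((log10(estimated) - log10(measured))^2))`. A constant decade
#' offset between the vectors gives exactly 1; the statistic is symmetric in
#' its arguments and invariant to a common multiplicative rescaling of both.
#'
#' @param estimated,measured positive numeric vectors of equal length
#'   (pairs with `NA` in either are dropped).
#' @return A single non-negative number (log10 units).
#' @examples
#' rmse_log10(c(2, 1), c(1, 2)) # 0.30103
#' @export
rmse_log10 <- function(estimated, measured) {
  p <- check_pairs(estimated, measured)
  if (length(p$e) < 1) stop("need at least one pair", call. = FALSE)
  sqrt(mean((p$e - p$m)^2))
}

#' Pearson correlation in log10 space
#'
#' @inheritParams rmse_log10
#' @return Pearson r of the log10-transformed pairs, in `[-1, 1]`.
#' @export
pearson_log10 <- function(estimated, measured) {
  p <- check_pairs(estimated, measured)
  if (length(p$e) < 3) stop("need at least three pairs", call. = FALSE)
  if (stats::sd(p$e) == 0 || stats::sd(p$m) == 0) {
    stop("correlation undefined: zero variance in log10 values", call. = FALSE)
  }
  stats::cor(p$e, p$m)
}

#' Compare two log10 RMSE values by confidence-interval overlap
#'
#' Builds a confidence interval for each model's log10 RMSE from the standard
#' error of the mean squared log10 error and the t distribution, and reports
#' whether the intervals overlap. With residuals treated as centred normal
#' with standard deviation psi, the squared errors have variance `2 psi^4`,
#' so the mean squared error carries standard error `psi^2 sqrt(2/n)`; the
#' interval on the mean square is mapped to the root scale.
#'
#' @param psi_a,psi_b log10 RMSE of the two models.
#' @param n number of validation pairs (shared).
#' @param confidence confidence level (default 0.95).
#' @return A list with `ci_a`, `ci_b` (length-2 numeric) and `overlap`
#'   (logical).
#' @examples
#' compare_rmse_ci(0.21, 0.26, n = 484)
#' @export
compare_rmse_ci <- function(psi_a, psi_b, n, confidence = 0.95) {
  stopifnot(n >= 3, psi_a >= 0, psi_b >= 0)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  ci_one <- function(psi) {
    se_msq <- psi^2 * sqrt(2 / n)
    sqrt(pmax(psi^2 + c(-1, 1) * tq * se_msq, 0))
  }
  ci_a <- ci_one(psi_a)
  ci_b <- ci_one(psi_b)
  list(ci_a = ci_a, ci_b = ci_b,
       overlap = ci_a[1] <= ci_b[2] && ci_b[1] <= ci_a[2])
}

#' Compare two correlation coefficients (Fisher r-to-z)
#'
#' Standard two-sample z test on Fisher-transformed correlations.
#'
#' @param r_a,r_b the two correlation coefficients, in (-1, 1).
#' @param n_a,n_b the sample sizes (each > 3).
#' @return A list with `z` and the two-sided `p_value`.
#' @export
compare_correlations <- function(r_a, r_b, n_a, n_b = n_a) {
  stopifnot(abs(r_a) < 1, abs(r_b) < 1, n_a > 3, n_b > 3)
  z <- (atanh(r_a) - atanh(r_b)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Grouped validation statistics
#'
#' Computes log10-space r and RMSE per group of a paired data set, in the
#' layout of a wavelength-by-model validation table.
#'
#' @param data a data frame of paired values.
#' @param estimated,measured tidy-selected positive-value columns.
#' @param ... tidy-selected grouping columns (e.g. wavelength, model).
#' @return A tibble with the grouping columns plus `n`, `r` and `psi`.
#' @examples
#' obs <- simulate_observations(50, noise_log10_sd = 0.1, bands = 443, seed = 1)
#' pred <- aph_four_pop(obs$chl, obs$sst, bands = 443) |>
#'   dplyr::filter(group == "total")
#' validation_stats(
#'   tibble::tibble(est = pred$aph, meas = obs$aph_443, wavelength = 443),
#'   est, meas, wavelength
#' )
#' @export
validation_stats <- function(data, estimated, measured, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = pearson_log10(dplyr::pick({{ estimated }})[[1]],
                        dplyr::pick({{ measured }})[[1]]),
      psi = rmse_log10(dplyr::pick({{ estimated }})[[1]],
                       dplyr::pick({{ measured }})[[1]]),
      .groups = "drop"
    )
}
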