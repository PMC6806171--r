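#' Root-sum-square propagation of relative uncertainty
#'
#' Group-specific absorption is the product of a specific-absorption
#' coefficient and a group chlorophyll, so to first order its relative
#' uncertainty is the root-sum-square of the two relative uncertainties:
#' `f_a = sqrt(f_a_star^2 + f_C^2)`.
#'
#' @param f_a_star relative uncertainty of the specific-absorption
#'   coefficient (dimensionless, >= 0); vectorised.
#' @param f_C relative uncertainty of the group chlorophyll (dimensionless,
#'   >= 0); recycled against `f_a_star`.
#' @return Numeric vector of relative uncertainties.
#' @examples
#' propagate_relative(0.3, 0.4) # 0.5
#' @export
propagate_relative <- function(f_a_star, f_C) {
  if (any(f_a_star < 0, na.rm = TRUE) || any(f_C < 0, na.rm = TRUE)) {
    stop("relative uncertainties must be non-negative", call. = FALSE)
  }
  sqrt(f_a_star^2 + f_C^2)
}

#' Relative uncertainty of the packaged a* coefficients
#'
#' Ratio of the tabulated robust standard deviation to the coefficient, per
#' group and band.
#'
#' @inheritParams aph_four_pop
#' @return A tibble with columns `wavelength`, `group`, `f_a_star`.
#' @examples
#' relative_astar() |> dplyr::filter(wavelength == 443, group == "pico")
#' @export
relative_astar <- function(table = astar_table()) {
  dplyr::transmute(table, .data$wavelength, .data$group,
                   f_a_star = .data$sd / .data$a_star)
}

#' Transform log10-space uncertainty to linear space
#'
#' Treats the linear variable as lognormal: a value with log10 mean `mu_log`,
#' log10 standard deviation `sigma_log` and log10 bias `bias_log` maps to a
#' bias-corrected linear mean `exp(m + s^2/2)` and standard deviation
#' `mean * sqrt(exp(s^2) - 1)`, where `s = sigma_log * ln(10)` and
#' `m = (mu_log - bias_log) * ln(10)`. The relative standard deviation
#' `sqrt(exp(s^2) - 1)` is scale-free: it depends only on `sigma_log`.
#'
#' @param mu_log log10 of the value; vectorised.
#' @param sigma_log log10 standard deviation (>= 0); recycled.
#' @param bias_log log10 bias, subtracted before transforming; recycled.
#' @return A tibble with columns `mean`, `sd` (linear units) and `f_rel`
#'   (dimensionless relative standard deviation).
#' @examples
#' log_to_linear(0, 0.3)
#' @export
log_to_linear <- function(mu_log, sigma_log, bias_log = 0) {
  if (any(sigma_log < 0, na.rm = TRUE)) {
    stop("`sigma_log` must be non-negative", call. = FALSE)
  }
  s <- sigma_log * log(10)
  m <- (mu_log - bias_log) * log(10)
  mean <- exp(m + s^2 / 2)
  f_rel <- sqrt(exp(s^2) - 1)
  tibble::tibble(mean = mean, sd = mean * f_rel,
                 f_rel = rep_len(f_rel, length(mean)))
}

#' Map per-pixel uncertainty in group-specific absorption
#'
#' Applies the scalar uncertainty pipeline pixel-wise to gridded chlorophyll
#' and SST: partitions each pixel's chlorophyll into the four groups,
#' converts per-group log10 uncertainties to linear relative uncertainties
#' (`f_C`), combines them with the tabulated a* relative uncertainties by
#' root-sum-square, and reports group absorption at the requested band with
#' its percent uncertainty. Masked pixels (`NA` chlorophyll or SST)
#' propagate `NA`.
#'
#' @param raster a long-format raster tibble with columns `lon`, `lat`,
#'   `chl` (mg m^-3) and `sst` (degrees C); see [simulate_raster()].
#' @param logerr per-group log10 uncertainty: either a tibble with columns
#'   `group`, `sigma_log`, `bias_log` (one row per group, applied to every
#'   pixel) or a per-pixel tibble additionally keyed by `lon`, `lat` (as
#'   produced by [owt_uncertainty()]).
#' @param band waveband (nm) at which to report absorption.
#' @inheritParams aph_four_pop
#' @return A tibble with one row per pixel and group: `lon`, `lat`, `group`,
#'   `chl_group` (mg m^-3), `f_C`, `aph` (m^-1), `f_a` and `uncert_pct`
#'   (percent).
#' @examples
#' r <- simulate_raster(4, 4, seed = 1)
#' le <- tibble::tibble(group = fourpop_groups, sigma_log = 0.2, bias_log = 0)
#' map_uncertainty(r, le, band = 443)
#' @export
map_uncertainty <- function(raster, logerr, band, table = astar_table(),
                            params = community_params()) {
  stopifnot(all(c("lon", "lat", "chl", "sst") %in% names(raster)))
  stopifnot(all(c("group", "sigma_log") %in% names(logerr)))
  if (!"bias_log" %in% names(logerr)) logerr$bias_log <- 0
  am <- astar_matrix(table, band)
  fas <- relative_astar(table)
  fas <- fas[fas$wavelength == band, ]
  masked <- is.na(raster$chl) | is.na(raster$sst)
  g <- group_chlorophyll(ifelse(masked, NA_real_, raster$chl),
                         ifelse(masked, NA_real_, raster$sst), params)
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(raster[, c("lon", "lat")], g[, fourpop_groups]),
    cols = dplyr::all_of(fourpop_groups),
    names_to = "group", values_to = "chl_group"
  )
  join_keys <- if (all(c("lon", "lat") %in% names(logerr))) {
    c("lon", "lat", "group")
  } else {
    "group"
  }
  long <- dplyr::left_join(long, logerr, by = join_keys)
  # relative linear-space uncertainty depends only on sigma_log
  long$f_C <- sqrt(exp((long$sigma_log * log(10))^2) - 1)
  long$aph <- long$chl_group * unname(am[long$group, 1])
  long$f_a <- propagate_relative(fas$f_a_star[match(long$group, fas$group)],
                                 long$f_C)
  long$f_a[is.na(long$chl_group)] <- NA_real_
  long$uncert_pct <- 100 * long$f_a
  dplyr::select(long, "lon", "lat", "group", "chl_group", "f_C", "aph",
                "f_a", "uncert_pct")
}

#' Per-pixel log uncertainties from an optical-water-type class map
#'
#' Emulates the workflow in which per-pixel product uncertainties come from a
#' classification of reflectance spectra: joins a pixel-to-class map with a
#' user-supplied per-class, per-group table of log10 error statistics. No
#' class table is packaged (the published per-class statistics are not
#' reproduced here).
#'
#' @param class_map a tibble with columns `lon`, `lat`, `owt` (class label).
#' @param class_table a tibble with columns `owt`, `group`, `sigma_log` and
#'   optionally `bias_log`.
#' @return A per-pixel tibble with columns `lon`, `lat`, `group`,
#'   `sigma_log`, `bias_log`, suitable for [map_uncertainty()].
#' @export
owt_uncertainty <- function(class_map, class_table) {
  stopifnot(all(c("lon", "lat", "owt") %in% names(class_map)),
            all(c("owt", "group", "sigma_log") %in% names(class_table)))
  if (!"bias_log" %in% names(class_table)) class_table$bias_log <- 0
  out <- dplyr::left_join(class_map, class_table, by = "owt",
                          relationship = "many-to-many")
  dplyr::select(out, "lon", "lat", "group", "sigma_log", "bias_log")
}
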