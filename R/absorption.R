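#' Group and total phytoplankton absorption spectra
#'
#' Composes spectral phytoplankton absorption as the sum over the four groups
#' of chlorophyll-specific absorption times group chlorophyll,
#' `aph(lambda) = sum_i a_i*(lambda) C_i`, with `C_i` from the SST-dependent
#' partition. Returns one row per observation, band and group, plus `total`
#' rows carrying the summed absorption and the total chlorophyll-specific
#' absorption `a*(lambda) = aph(lambda)/C` (reported as its analytic
#' low-chlorophyll limit when `chl = 0`, see [a_star_limits()]).
#'
#' @inheritParams group_chlorophyll
#' @param table a tidy a* table as returned by [astar_table()].
#' @param bands wavebands (nm) to evaluate; default all bands in `table`.
#'   Requesting a band absent from the table is an error.
#' @return A tibble with columns `.obs`, `chl`, `sst`, `wavelength`, `group`
#'   (`"pico"`, `"nano"`, `"dino"`, `"diatom"` or `"total"`), `aph` (m^-1)
#'   and `a_star` (m2 (mg chl-a)^-1).
#' @examples
#' aph_four_pop(0.5, sst = 15, bands = 443)
#' @export
aph_four_pop <- function(chl, sst, table = astar_table(),
                         params = community_params(), bands = NULL) {
  if (is.null(bands)) bands <- sort(unique(table$wavelength))
  am <- astar_matrix(table, bands) # groups x bands
  g <- group_chlorophyll(chl, sst, params)
  cg <- as.matrix(g[, fourpop_groups]) # n x 4
  n <- nrow(g)
  nb <- length(bands)
  per_group <- purrr::map(seq_along(fourpop_groups), function(i) {
    outer(cg[, i], am[i, ]) # n x bands
  })
  total <- Reduce(`+`, per_group)
  # total a*: aph/C, continued to its low-C limit at C = 0. a_star_limits
  # returns rows observation-major with bands nested, the same long order
  # used below.
  lim <- a_star_limits(g$sst, table = table, params = params, bands = bands)
  chl_long <- rep(g$chl, each = nb)
  total_long <- as.vector(t(total))
  astar_tot_long <- ifelse(chl_long > 0, total_long / chl_long, lim$low_chl)
  one <- function(mat, grp, astar) {
    tibble::tibble(
      .obs = rep(seq_len(n), each = nb),
      chl = rep(g$chl, each = nb),
      sst = rep(g$sst, each = nb),
      wavelength = rep(bands, times = n),
      group = grp,
      aph = unname(as.vector(t(mat))),
      a_star = unname(astar)
    )
  }
  out <- purrr::map2(per_group, fourpop_groups, function(mat, grp) {
    one(mat, grp, rep(am[grp, ], times = n))
  })
  out <- c(out, list(one(total, "total", astar_tot_long)))
  dplyr::arrange(dplyr::bind_rows(out), .data$.obs, .data$wavelength)
}

#' Bounding spectra of total chlorophyll-specific absorption
#'
#' The total chlorophyll-specific absorption `a*(lambda)` is bounded by the
#' group coefficients. As chlorophyll tends to zero the partition tends to the
#' fractions `D1`, `D12 - D1` and `1 - D12`, giving the low-chlorophyll limit
#' `D1 a1* + (D12 - D1) a2* + (1 - D12)(q a3* + (1 - q) a4*)` with `q` the
#' dinoflagellate fraction; at very high chlorophyll the saturated small-cell
#' terms vanish relative to the total and `a*` tends to
#' `q a3* + (1 - q) a4*`. Both limits depend on SST.
#'
#' @inheritParams aph_four_pop
#' @return A tibble with columns `sst`, `wavelength`, `low_chl` and
#'   `high_chl` (m2 (mg chl-a)^-1), one row per SST and band.
#' @examples
#' a_star_limits(c(10, 24), bands = 443)
#' @export
a_star_limits <- function(sst, table = astar_table(),
                          params = community_params(), bands = NULL) {
  if (is.null(bands)) bands <- sort(unique(table$wavelength))
  am <- astar_matrix(table, bands)
  sp <- size_params(sst, params)
  q <- dino_fraction(sst, params)
  micro <- outer(q, am["dino", ]) + outer(1 - q, am["diatom", ])
  low <- outer(sp$D1, am["pico", ]) + outer(sp$D12 - sp$D1, am["nano", ]) +
    micro * (1 - sp$D12)
  n <- length(sst)
  tibble::tibble(
    sst = rep(sst, each = length(bands)),
    wavelength = rep(bands, times = n),
    low_chl = as.vector(t(low)),
    high_chl = as.vector(t(micro))
  )
}

#' Linear spectral interpolation between model wavebands
#'
#' Interpolates a spectral quantity piecewise-linearly in wavelength between
#' the tabulated bands. Exact at band centres; requests outside the tabulated
#' range are an error (no spectral extrapolation).
#'
#' @param data a tibble with a `wavelength` column and one or more numeric
#'   spectral columns; extra non-numeric columns are treated as grouping keys
#'   and interpolation is performed within each group.
#' @param wavelengths target wavelengths (nm).
#' @return A tibble like `data` evaluated at `wavelengths`.
#' @examples
#' aph_four_pop(1, 15) |>
#'   dplyr::select(wavelength, group, aph) |>
#'   interpolate_spectrum(c(443, 552.5))
#' @export
interpolate_spectrum <- function(data, wavelengths) {
  stopifnot("wavelength" %in% names(data))
  rng <- range(data$wavelength)
  if (any(wavelengths < rng[1] | wavelengths > rng[2])) {
    stop(sprintf("target wavelengths must lie within [%g, %g] nm", rng[1],
                 rng[2]), call. = FALSE)
  }
  value_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        "wavelength")
  key_cols <- setdiff(names(data), c("wavelength", value_cols))
  interp_one <- function(df) {
    out <- tibble::tibble(wavelength = wavelengths)
    for (v in value_cols) {
      out[[v]] <- stats::approx(df$wavelength, df[[v]], xout = wavelengths,
                                ties = "ordered")$y
    }
    out
  }
  if (length(key_cols) == 0) {
    interp_one(dplyr::arrange(data, .data$wavelength))
  } else {
    data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
      dplyr::arrange(.data$wavelength, .by_group = TRUE) |>
      dplyr::group_modify(~ interp_one(.x)) |>
      dplyr::ungroup()
  }
}

#' Power-law absorption model
#'
#' The classical empirical alternative: `aph(lambda) = A(lambda) *
#' C^(1 - B(lambda))` with positive band-wise coefficients. No coefficients
#' are packaged; supply them (they belong to the antecedent literature).
#'
#' @param chl total chlorophyll-a (mg m^-3), scalar or vector.
#' @param coef a tibble with columns `wavelength`, `A`, `B` (A > 0, B > 0).
#' @return A tibble with columns `chl`, `wavelength`, `aph` (m^-1).
#' @examples
#' aph_power_law(2, tibble::tibble(wavelength = 443, A = 0.05, B = 0.3))
#' @export
aph_power_law <- function(chl, coef) {
  stopifnot(all(c("wavelength", "A", "B") %in% names(coef)))
  if (any(coef$A <= 0) || any(coef$B <= 0)) {
    stop("power-law coefficients A and B must be positive", call. = FALSE)
  }
  if (any(chl < 0, na.rm = TRUE)) stop("`chl` must be non-negative", call. = FALSE)
  if (any(chl == 0, na.rm = TRUE) && any(coef$B > 1)) {
    stop("aph is undefined at chl = 0 when B > 1", call. = FALSE)
  }
  n <- length(chl)
  out <- tidyr::expand_grid(chl = chl, coef)
  out$aph <- out$A * out$chl^(1 - out$B)
  dplyr::select(out, "chl", "wavelength", "aph")
}

#' Three-population absorption model
#'
#' The SST-independent predecessor of the four-population model: pico- and
#' nanophytoplankton saturate with fixed asymptotes and initial slopes, and a
#' single microphytoplankton class takes the remainder linearly. No
#' coefficients are packaged; supply them. The four-population model reduces
#' to this form when its community parameters are frozen to constants and
#' `a3* = a4*`.
#'
#' @inheritParams aph_power_law
#' @param coef a tibble with columns `wavelength`, `a1`, `a2`, `a34`
#'   (m2 (mg chl-a)^-1).
#' @param size a list with scalars `C1m`, `C12m` (mg m^-3) and `D1`, `D12`
#'   (dimensionless), all positive.
#' @return A tibble with columns `chl`, `wavelength`, `aph` (m^-1).
#' @export
aph_three_pop <- function(chl, coef, size) {
  stopifnot(all(c("wavelength", "a1", "a2", "a34") %in% names(coef)),
            all(c("C1m", "C12m", "D1", "D12") %in% names(size)))
  if (any(unlist(size[c("C1m", "C12m", "D1", "D12")]) <= 0)) {
    stop("three-population size parameters must be positive", call. = FALSE)
  }
  if (any(chl < 0, na.rm = TRUE)) stop("`chl` must be non-negative", call. = FALSE)
  c1 <- size$C1m * (1 - exp(-size$D1 * chl / size$C1m))
  c12 <- size$C12m * (1 - exp(-size$D12 * chl / size$C12m))
  out <- tidyr::expand_grid(i = seq_along(chl), coef)
  out$chl <- chl[out$i]
  out$aph <- out$a1 * c1[out$i] + out$a2 * (c12[out$i] - c1[out$i]) +
    out$a34 * (out$chl - c12[out$i])
  dplyr::select(out, "chl", "wavelength", "aph")
}
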