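# Synthetic observation sets and rasters carrying the model's own structure,
# so calibration and uncertainty propagation can be exercised closed-loop
# without external data.

#' Simulate an observation set
#'
#' Draws (chlorophyll, SST) pairs, computes noise-free spectral absorption
#' through the four-population model with the supplied (generating) parameter
#' tables, and applies independent multiplicative lognormal noise per band.
#' Defaults emulate the calibration data: chlorophyll log-uniform over
#' 0.01-30 mg m^-3, SST uniform over the 0-30.8 degC observed range. The
#' generating truth travels with the result (attribute `truth`), enabling
#' closed-loop parameter-recovery tests.
#'
#' @param n number of records (ignored when `chl` and `sst` are supplied).
#' @param c_range chlorophyll sampling range (mg m^-3), log-uniform.
#' @param sst_range SST sampling range (degrees C), uniform.
#' @param noise_log10_sd standard deviation of the multiplicative noise in
#'   log10 units (0 = noise-free).
#' @param bands wavebands to generate (default: all 12).
#' @param chl,sst optional explicit vectors (equal length) overriding the
#'   sampling laws, e.g. a designed calibration grid.
#' @param table,params generating specific-absorption table and community
#'   parameters.
#' @param seed integer seed; fixed seed gives an identical data set.
#' @return A tibble with columns `chl`, `sst` and `aph_<band>` for each band,
#'   with attribute `truth = list(table, params, noise_log10_sd, seed)`.
#' @examples
#' simulate_observations(5, bands = c(443, 550), seed = 1)
#' @export
simulate_observations <- function(n = 100, c_range = c(0.01, 30),
                                  sst_range = c(0, 30.8),
                                  noise_log10_sd = 0,
                                  bands = fourpop_bands,
                                  chl = NULL, sst = NULL,
                                  table = astar_table(),
                                  params = community_params(),
                                  seed = NULL) {
  stopifnot(noise_log10_sd >= 0, all(c_range > 0), diff(c_range) >= 0)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  withr::with_seed(seed, {
    if (is.null(chl) != is.null(sst)) {
      stop("supply both `chl` and `sst`, or neither", call. = FALSE)
    }
    if (is.null(chl)) {
      chl <- 10^stats::runif(n, log10(c_range[1]), log10(c_range[2]))
      sst <- stats::runif(n, sst_range[1], sst_range[2])
    } else {
      stopifnot(length(chl) == length(sst))
      n <- length(chl)
    }
    spec <- aph_four_pop(chl, sst, table = table, params = params,
                         bands = bands)
    tot <- spec[spec$group == "total", ]
    wide <- tidyr::pivot_wider(tot[, c(".obs", "wavelength", "aph")],
                               names_from = "wavelength",
                               values_from = "aph", names_prefix = "aph_")
    wide <- wide[order(wide$.obs), ]
    out <- dplyr::bind_cols(tibble::tibble(chl = chl, sst = sst),
                            wide[, -1, drop = FALSE])
    if (noise_log10_sd > 0) {
      for (col in grep("^aph_", names(out), value = TRUE)) {
        out[[col]] <- out[[col]] *
          10^stats::rnorm(n, mean = 0, sd = noise_log10_sd)
      }
    }
    attr(out, "truth") <- list(table = table, params = params,
                               noise_log10_sd = noise_log10_sd, seed = seed)
    out
  })
}

#' Noise-free calibration design grid
#'
#' Convenience constructor for the crossed design used in closed-loop
#' calibration checks: a log-spaced chlorophyll grid crossed with a set of
#' SST values, evaluated noise-free.
#'
#' @param n_chl number of chlorophyll grid points (log-spaced over `c_range`).
#' @param sst_values SST levels (degrees C) to cross with the grid.
#' @inheritParams simulate_observations
#' @return As [simulate_observations()], with `n_chl * length(sst_values)`
#'   rows.
#' @examples
#' observation_grid(n_chl = 10, sst_values = c(10, 20), bands = 443)
#' @export
observation_grid <- function(n_chl = 40, sst_values = c(5, 10, 15, 20, 25, 30),
                             c_range = c(0.01, 30), bands = fourpop_bands,
                             table = astar_table(),
                             params = community_params()) {
  grid <- tidyr::expand_grid(
    chl = 10^seq(log10(c_range[1]), log10(c_range[2]), length.out = n_chl),
    sst = sst_values
  )
  simulate_observations(chl = grid$chl, sst = grid$sst, bands = bands,
                        table = table, params = params, noise_log10_sd = 0,
                        seed = 1L)
}

#' Simulate a gridded chlorophyll/SST scene
#'
#' Builds a small raster with a smooth log-chlorophyll gradient along
#' longitude and an SST gradient along latitude, optional multiplicative
#' lognormal noise on chlorophyll and additive noise on SST, and a shared
#' random mask (masked pixels have `NA` in both fields).
#'
#' @param nx,ny grid dimensions.
#' @param chl_range chlorophyll gradient endpoints (mg m^-3).
#' @param sst_range SST gradient endpoints (degrees C).
#' @param chl_noise_log10_sd lognormal noise on chlorophyll (log10 sd).
#' @param sst_noise_sd additive Gaussian noise on SST (degrees C).
#' @param masked_fraction fraction of pixels masked at random.
#' @param lon_range,lat_range coordinate extents (degrees).
#' @param seed integer seed.
#' @return A long-format tibble with columns `lon`, `lat`, `chl`, `sst`
#'   (`NA` where masked), one row per pixel.
#' @examples
#' simulate_raster(4, 3, masked_fraction = 0.2, seed = 1)
#' @export
simulate_raster <- function(nx = 8, ny = 8, chl_range = c(0.05, 5),
                            sst_range = c(8, 22),
                            chl_noise_log10_sd = 0, sst_noise_sd = 0,
                            masked_fraction = 0,
                            lon_range = c(-30, -20), lat_range = c(45, 55),
                            seed = NULL) {
  stopifnot(nx >= 1, ny >= 1, masked_fraction >= 0, masked_fraction <= 1)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  withr::with_seed(seed, {
    lon <- seq(lon_range[1], lon_range[2], length.out = nx)
    lat <- seq(lat_range[1], lat_range[2], length.out = ny)
    grid <- tidyr::expand_grid(lat = lat, lon = lon)
    tx <- if (nx > 1) (match(grid$lon, lon) - 1) / (nx - 1) else rep(0, nrow(grid))
    ty <- if (ny > 1) (match(grid$lat, lat) - 1) / (ny - 1) else rep(0, nrow(grid))
    chl <- 10^(log10(chl_range[1]) + tx * diff(log10(chl_range)))
    sst <- sst_range[1] + ty * diff(sst_range)
    if (chl_noise_log10_sd > 0) {
      chl <- chl * 10^stats::rnorm(length(chl), 0, chl_noise_log10_sd)
    }
    if (sst_noise_sd > 0) {
      sst <- sst + stats::rnorm(length(sst), 0, sst_noise_sd)
    }
    n_mask <- round(masked_fraction * nrow(grid))
    if (n_mask > 0) {
      i <- sample.int(nrow(grid), n_mask)
      chl[i] <- NA_real_
      sst[i] <- NA_real_
    }
    tibble::tibble(lon = grid$lon, lat = grid$lat, chl = chl, sst = sst)
  })
}
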