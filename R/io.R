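# CSV and netCDF plumbing. All CSV writers emit plain comma-separated text
# with optional '#' provenance headers that the readers skip.

#' Read and write observation tables
#'
#' Observations are CSV with columns `chl` (mg m^-3), `sst` (degrees C) and
#' one `aph_<band>` column per waveband (m^-1). `col_map` renames arbitrary
#' input headers onto this convention, e.g.
#' `c(chl = "chlor_a", sst = "temp", aph_443 = "aph443")`.
#'
#' @param path file path.
#' @param col_map optional named character vector mapping required names to
#'   the file's column names.
#' @return `read_observations()` returns a tibble; missing required columns
#'   are an error listing them.
#' @export
read_observations <- function(path, col_map = NULL) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(out))
    if (length(missing_src) > 0) {
      stop("columns not found in file: ", paste(missing_src, collapse = ", "),
           call. = FALSE)
    }
    out <- dplyr::rename(out, !!!rlang::set_names(col_map, names(col_map)))
  }
  need <- c("chl", "sst")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0 || !any(grepl("^aph_", names(out)))) {
    stop("observations need columns ",
         paste(c(miss, if (!any(grepl("^aph_", names(out)))) "aph_<band>"),
               collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname read_observations
#' @param obs an observation tibble.
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(obs, path)
  invisible(path)
}

#' Write a calibrated coefficient table with provenance
#'
#' Writes a tidy `wavelength, group, a_star, sd` table as CSV plus a JSON
#' sidecar (`<path>.json`) recording seed, bootstrap size, convergence
#' failures and package version.
#'
#' @param fit a coefficient tibble from [fit_astar()].
#' @param path output CSV path.
#' @param provenance optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_astar_csv <- function(fit, path, provenance = list()) {
  readr::write_csv(fit, path)
  side <- c(list(
    seed = attr(fit, "seed"),
    n_boot = attr(fit, "n_boot"),
    n_fail = as.list(attr(fit, "n_fail")),
    package_version = as.character(utils::packageVersion("fourpop")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and write long-format rasters as CSV
#'
#' Rasters travel as long tibbles (`lon`, `lat`, one row per pixel, `NA` =
#' masked); the CSV form is the text interchange format used by the CLI.
#'
#' @param path file path.
#' @return A raster tibble.
#' @export
read_raster_csv <- function(path) {
  out <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("lon", "lat") %in% names(out))) {
    stop("raster CSV needs `lon` and `lat` columns", call. = FALSE)
  }
  out
}

#' @rdname read_raster_csv
#' @param raster a raster tibble.
#' @export
write_raster_csv <- function(raster, path) {
  readr::write_csv(raster, path)
  invisible(path)
}

#' Read and write rasters as CF-style netCDF
#'
#' One variable per non-coordinate column, on a `lon` x `lat` grid with
#' `_FillValue` marking masked pixels. Requires the `ncdf4` package.
#'
#' @param path file path.
#' @param raster a long-format raster tibble (`lon`, `lat`, value columns) on
#'   a complete rectangular grid.
#' @return `read_raster_nc()` returns a raster tibble; the writer returns
#'   `path` invisibly.
#' @export
write_raster_nc <- function(raster, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("writing netCDF requires the `ncdf4` package", call. = FALSE)
  }
  lon <- sort(unique(raster$lon))
  lat <- sort(unique(raster$lat))
  if (nrow(raster) != length(lon) * length(lat)) {
    stop("raster is not a complete lon x lat grid", call. = FALSE)
  }
  fill <- -9999.0
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lat)
  value_cols <- setdiff(names(raster), c("lon", "lat"))
  units <- vapply(value_cols, function(v) {
    if (grepl("pct", v)) "%" else if (v == "sst") "degC"
    else if (grepl("chl", v)) "mg m-3" else ""
  }, character(1))
  vars <- purrr::map2(value_cols, units, function(v, u) {
    ncdf4::ncvar_def(v, u, list(dim_lon, dim_lat), missval = fill,
                     prec = "double")
  })
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ord <- order(match(raster$lat, lat), match(raster$lon, lon))
  for (k in seq_along(value_cols)) {
    m <- matrix(raster[[value_cols[k]]][ord], nrow = length(lon))
    ncdf4::ncvar_put(nc, vars[[k]], m)
  }
  invisible(path)
}

#' @rdname write_raster_nc
#' @export
read_raster_nc <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("reading netCDF requires the `ncdf4` package", call. = FALSE)
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  lon <- as.vector(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.vector(ncdf4::ncvar_get(nc, "lat"))
  out <- tidyr::expand_grid(lat = lat, lon = lon)[, c("lon", "lat")]
  # expand_grid(lat, lon) is lat-major with lon fastest; ncvar_get returns
  # lon-fastest matrices, so a straight as.vector() aligns.
  for (v in names(nc$var)) {
    out[[v]] <- as.vector(ncdf4::ncvar_get(nc, v))
  }
  out
}

#' Serialise spectra to tidy CSV
#'
#' Writes the long spectra produced by [aph_four_pop()] using the column
#' conventions `wavelength_nm`, `group`, `aph_m-1`, `a_star_m2_per_mgC`.
#'
#' @param spectra output of [aph_four_pop()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  out <- dplyr::select(spectra, wavelength_nm = "wavelength", "group",
                       `aph_m-1` = "aph", a_star_m2_per_mgC = "a_star")
  readr::write_csv(out, path)
  invisible(path)
}
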