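# A deliberately simple, fully configurable case-1 reflectance closure used
# only to explore how SST-driven community shifts move the blue-to-green
# band ratio. It is not a radiative-transfer model.

#' Configuration of the case-1 forward reflectance model
#'
#' Bundles the water constants and covariation laws of the forward model:
#' pure-seawater absorption `aw` per band (m^-1; defaults follow standard
#' laboratory determinations for clear natural water), pure-seawater
#' backscattering `bbw(lambda) = bbw_ref * (lambda/500)^bbw_slope` (m^-1),
#' coloured dissolved organic matter tied to phytoplankton absorption at
#' 443 nm (`a_cdom(lambda) = cdom_frac * aph(443) * exp(-cdom_slope *
#' (lambda - 443))`), particulate backscattering as a power law in
#' chlorophyll with a spectral slope (`bbp(lambda) = bbp_ref * C^bbp_exp *
#' (lambda/555)^(-bbp_slope)`), and the proportionality factor `f_factor`
#' linking `bb/(a + bb)` to remote-sensing reflectance. Every element is
#' overridable and the whole configuration serialises to YAML.
#'
#' @param bands wavebands (nm); must include 443, 490, 510 and 555 for the
#'   maximum band ratio.
#' @param aw named numeric vector of pure-seawater absorption per band (m^-1).
#' @param bbw_ref,bbw_slope pure-seawater backscattering at 500 nm (m^-1) and
#'   its spectral exponent.
#' @param cdom_frac,cdom_slope CDOM-to-aph(443) ratio (dimensionless) and
#'   spectral slope (nm^-1).
#' @param bbp_ref,bbp_exp,bbp_slope particulate backscattering at 555 nm for
#'   C = 1 mg m^-3 (m^-1), its chlorophyll exponent, and its spectral slope.
#' @param f_factor reflectance proportionality factor (sr^-1).
#' @return An object of class `reflectance_config` (a named list).
#' @export
reflectance_config <- function(bands = fourpop_bands,
                               aw = c(`412` = 0.00455, `443` = 0.00707,
                                      `490` = 0.0150, `510` = 0.0325,
                                      `520` = 0.0417, `550` = 0.0565,
                                      `555` = 0.0596, `560` = 0.0619,
                                      `620` = 0.2755, `665` = 0.4295,
                                      `670` = 0.4390, `682` = 0.4700),
                               bbw_ref = 0.00144, bbw_slope = -4.32,
                               cdom_frac = 0.2, cdom_slope = 0.014,
                               bbp_ref = 0.0012, bbp_exp = 0.62,
                               bbp_slope = 1.0,
                               f_factor = 0.089) {
  missing_aw <- setdiff(as.character(bands), names(aw))
  if (length(missing_aw) > 0) {
    stop("`aw` lacks band(s): ", paste(missing_aw, collapse = ", "),
         call. = FALSE)
  }
  if (any(aw <= 0) || bbw_ref <= 0 || bbp_ref <= 0 || f_factor <= 0) {
    stop("water constants must be positive", call. = FALSE)
  }
  structure(
    list(bands = as.numeric(bands), aw = aw[as.character(bands)],
         bbw_ref = bbw_ref, bbw_slope = bbw_slope,
         cdom_frac = cdom_frac, cdom_slope = cdom_slope,
         bbp_ref = bbp_ref, bbp_exp = bbp_exp, bbp_slope = bbp_slope,
         f_factor = f_factor),
    class = "reflectance_config"
  )
}

#' @export
print.reflectance_config <- function(x, ...) {
  cat("Case-1 forward reflectance configuration\n")
  cat(" bands:", paste(x$bands, collapse = ", "), "nm\n")
  cat(sprintf(" bbw = %.3g*(lambda/500)^%.3g; cdom = %.3g*aph(443)*exp(-%.3g dl)\n",
              x$bbw_ref, x$bbw_slope, x$cdom_frac, x$cdom_slope))
  cat(sprintf(" bbp = %.3g*C^%.3g*(lambda/555)^-%.3g; f = %.3g sr^-1\n",
              x$bbp_ref, x$bbp_exp, x$bbp_slope, x$f_factor))
  invisible(x)
}

#' Read or write a reflectance configuration as YAML
#' @param path file path.
#' @return `read_reflectance_config()` returns a [reflectance_config()];
#'   the writer returns `path` invisibly.
#' @export
read_reflectance_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  aw <- unlist(cfg$aw)
  reflectance_config(bands = as.numeric(cfg$bands), aw = aw,
                     bbw_ref = cfg$bbw_ref, bbw_slope = cfg$bbw_slope,
                     cdom_frac = cfg$cdom_frac, cdom_slope = cfg$cdom_slope,
                     bbp_ref = cfg$bbp_ref, bbp_exp = cfg$bbp_exp,
                     bbp_slope = cfg$bbp_slope, f_factor = cfg$f_factor)
}

#' @rdname read_reflectance_config
#' @param cfg a [reflectance_config()] object.
#' @export
write_reflectance_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "reflectance_config"))
  out <- unclass(cfg)
  out$aw <- as.list(out$aw)
  out$bands <- as.list(out$bands)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Forward remote-sensing reflectance
#'
#' Evaluates the case-1 closure per band: total absorption is pure seawater
#' plus four-population phytoplankton absorption plus covarying CDOM; total
#' backscattering is pure seawater plus a chlorophyll power law; reflectance
#' is `f_factor * bb / (a + bb)`. Deterministic for a fixed configuration.
#'
#' @param chl total chlorophyll-a (mg m^-3), positive scalar or vector.
#' @param sst sea-surface temperature (degrees C), recycled against `chl`.
#' @param cfg a [reflectance_config()].
#' @inheritParams aph_four_pop
#' @return A tibble with columns `chl`, `sst`, `wavelength`, `rrs` (sr^-1).
#' @examples
#' forward_rrs(0.1, sst = 18)
#' @export
forward_rrs <- function(chl, sst, cfg = reflectance_config(),
                        table = astar_table(), params = community_params()) {
  if (any(chl <= 0, na.rm = TRUE)) stop("`chl` must be positive", call. = FALSE)
  bands <- cfg$bands
  if (!443 %in% bands) {
    stop("configuration must include the 443 nm band (CDOM anchor)",
         call. = FALSE)
  }
  n <- max(length(chl), length(sst))
  chl <- rep_len(chl, n)
  sst <- rep_len(sst, n)
  spec <- aph_four_pop(chl, sst, table = table, params = params, bands = bands)
  tot <- spec[spec$group == "total", ]
  aph <- matrix(tot$aph[order(tot$.obs, match(tot$wavelength, bands))],
                nrow = n, byrow = TRUE) # n x bands
  aph443 <- aph[, which(bands == 443)]
  acdom <- outer(cfg$cdom_frac * aph443, exp(-cfg$cdom_slope * (bands - 443)))
  a_tot <- matrix(cfg$aw, nrow = n, ncol = length(bands), byrow = TRUE) +
    aph + acdom
  bbw <- cfg$bbw_ref * (bands / 500)^cfg$bbw_slope
  bbp <- outer(cfg$bbp_ref * chl^cfg$bbp_exp, (bands / 555)^(-cfg$bbp_slope))
  bb <- matrix(bbw, nrow = n, ncol = length(bands), byrow = TRUE) + bbp
  rrs <- cfg$f_factor * bb / (a_tot + bb)
  tibble::tibble(
    chl = rep(chl, each = length(bands)),
    sst = rep(sst, each = length(bands)),
    wavelength = rep(bands, times = n),
    rrs = as.vector(t(rrs))
  )
}

#' Blue-to-green maximum band ratio
#'
#' `max(Rrs(443), Rrs(490), Rrs(510)) / Rrs(555)`, the quantity underlying
#' empirical band-ratio chlorophyll algorithms. Invariant to an overall
#' scaling of the spectrum.
#'
#' @param rrs a tibble with columns `wavelength` and `rrs` containing at
#'   least the 443, 490, 510 and 555 nm bands (a single spectrum).
#' @return A single positive number.
#' @examples
#' max_band_ratio(tibble::tibble(wavelength = c(443, 490, 510, 555),
#'                               rrs = c(0.008, 0.006, 0.004, 0.002)))
#' @export
max_band_ratio <- function(rrs) {
  need <- c(443, 490, 510, 555)
  v <- rrs$rrs[match(need, rrs$wavelength)]
  if (anyNA(v)) {
    stop("spectrum must include bands 443, 490, 510 and 555 nm",
         call. = FALSE)
  }
  max(v[1:3]) / v[4]
}

#' Maximum band ratio over a chlorophyll-SST grid
#'
#' Evaluates the forward model on a chlorophyll grid for each SST level and
#' returns the band-ratio curves, the simulation behind band-ratio-versus-
#' chlorophyll diagrams.
#'
#' @param chl chlorophyll grid (mg m^-3).
#' @param sst SST levels (degrees C); one curve per level.
#' @inheritParams forward_rrs
#' @return A tibble with columns `chl`, `sst`, `ratio`.
#' @examples
#' ratio_surface(c(0.05, 0.5, 5), sst = c(10, 24))
#' @export
ratio_surface <- function(chl, sst, cfg = reflectance_config(),
                          table = astar_table(),
                          params = community_params()) {
  grid <- tidyr::expand_grid(sst = sst, chl = chl)
  spec <- forward_rrs(grid$chl, grid$sst, cfg = cfg, table = table,
                      params = params)
  spec |>
    dplyr::group_by(.data$chl, .data$sst) |>
    dplyr::summarise(ratio = max_band_ratio(dplyr::pick(dplyr::everything())),
                     .groups = "drop") |>
    dplyr::arrange(.data$sst, .data$chl)
}

#' Polynomial band-ratio chlorophyll algorithm
#'
#' Fourth-order polynomial in the log10 maximum band ratio,
#' `10^(sum_k a_k log10(ratio)^k)`, the form of the operational OC4 family.
#' Coefficients are not packaged; supply the published set you wish to
#' compare against.
#'
#' @param ratio maximum band ratio (positive), vectorised.
#' @param coeffs numeric vector of 5 polynomial coefficients `a0..a4`.
#' @return Chlorophyll-a estimate (mg m^-3).
#' @export
oc4_reference <- function(ratio, coeffs) {
  stopifnot(length(coeffs) == 5)
  if (any(ratio <= 0, na.rm = TRUE)) {
    stop("`ratio` must be positive", call. = FALSE)
  }
  lr <- log10(ratio)
  10^(coeffs[1] + coeffs[2] * lr + coeffs[3] * lr^2 + coeffs[4] * lr^3 +
        coeffs[5] * lr^4)
}
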