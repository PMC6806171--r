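#' Four-parameter logistic in SST
#'
#' Evaluates `a / (1 + exp(-b * (sst - c))) + d`, the shared functional form of
#' all SST-dependent coefficients in the community-structure model. Monotone in
#' `sst` whenever `a * b != 0`; equals `a/2 + d` at the midpoint `sst = c`.
#'
#' @param sst sea-surface temperature (degrees C); scalar or vector. `NA`
#'   propagates.
#' @param a,b,c,d logistic coefficients (amplitude, slope, midpoint, offset).
#' @return Numeric vector the length of `sst`.
#' @examples
#' logistic_sst(14.89, a = 0.370, b = 1.13, c = 14.89, d = 0.569) # a/2 + d
#' @export
logistic_sst <- function(sst, a, b, c, d) {
  stopifnot(is.numeric(sst), is.numeric(a), is.numeric(b), is.numeric(c),
            is.numeric(d))
  if (any(is.infinite(sst))) {
    stop("`sst` must be finite (NA/NaN propagate, infinities do not)",
         call. = FALSE)
  }
  a / (1 + exp(-b * (sst - c))) + d
}

#' SST-dependent size-structure coefficients
#'
#' Computes, for each SST, the asymptotic maximum chlorophyll of cells <20 um
#' (`C12m`) and <2 um (`C1m`), and the low-chlorophyll fractions of the two
#' size classes (`D12`, `D1`). The asymptotes are `1 - logistic(sst)` with a
#' negative amplitude for `C12m`, so `C12m` can exceed 1 mg m^-3 in warm
#' water; the fractions are rising logistics of SST.
#'
#' @inheritParams group_chlorophyll
#' @param sst sea-surface temperature (degrees C), scalar or vector.
#' @return A tibble with columns `sst`, `C12m`, `C1m` (mg m^-3), `D12`, `D1`
#'   (dimensionless).
#' @examples
#' size_params(c(5, 15, 25))
#' @export
size_params <- function(sst, params = community_params()) {
  stopifnot(inherits(params, "community_params"))
  lg <- function(p) logistic_sst(sst, p[["a"]], p[["b"]], p[["c"]], p[["d"]])
  tibble::tibble(
    sst = sst,
    C12m = 1 - lg(params$G),
    C1m = 1 - lg(params$H),
    D12 = lg(params$J),
    D1 = lg(params$K)
  )
}

#' Dinoflagellate fraction of microphytoplankton
#'
#' The fraction of microphytoplankton chlorophyll (cells >20 um) held by
#' dinoflagellates rather than diatoms, a rising logistic of SST with slope
#' `alpha` and midpoint `beta`: 0.5 at `sst = beta`, approaching 1 in warm
#' water.
#'
#' @inheritParams size_params
#' @return Numeric vector in (0, 1), same length as `sst`.
#' @examples
#' dino_fraction(32.5) # midpoint: 0.5
#' @export
dino_fraction <- function(sst, params = community_params()) {
  stopifnot(inherits(params, "community_params"))
  logistic_sst(sst, a = 1, b = params$alpha, c = params$beta, d = 0)
}

# Vectorised core of the partition; returns a plain list of numeric vectors.
# Clamping guarantees 0 <= C1 <= C12 <= C for arbitrary parameter sets, and
# the differencing scheme conserves total chlorophyll to rounding error.
group_chl_core <- function(chl, sst, params) {
  sp <- size_params(sst, params)
  safe_exp_term <- function(m, d) {
    # m <= 0 would make the exponential saturation meaningless; treat the
    # size class as absent (clamped to zero below).
    out <- ifelse(m > 0, m * (1 - exp(-d * chl / m)), 0)
    out
  }
  c12 <- safe_exp_term(sp$C12m, sp$D12)
  c1 <- safe_exp_term(sp$C1m, sp$D1)
  c12 <- pmin(pmax(c12, 0), chl)
  c1 <- pmin(pmax(c1, 0), c12)
  c2 <- c12 - c1
  c34 <- chl - c12
  q <- dino_fraction(sst, params)
  c3 <- q * c34
  c4 <- c34 - c3
  list(pico = c1, nano = c2, dino = c3, diatom = c4)
}

#' Partition total chlorophyll-a into four phytoplankton groups
#'
#' Splits total chlorophyll-a between picophytoplankton, nanophytoplankton,
#' dinoflagellates and diatoms as a function of SST. Small-cell chlorophyll
#' saturates with total chlorophyll (exponential saturation with
#' SST-dependent asymptote and initial slope); the microphytoplankton
#' remainder is divided between dinoflagellates and diatoms by
#' [dino_fraction()]. The four concentrations are non-negative and sum to the
#' total by construction.
#'
#' @param chl total chlorophyll-a (mg m^-3), scalar or vector; must be
#'   non-negative (`NA` propagates).
#' @param sst sea-surface temperature (degrees C), recycled against `chl`.
#'   Values outside the 0-30.8 degC calibration range trigger a warning but
#'   are computed (extrapolation is a supported use).
#' @param params a [community_params()] object.
#' @return A tibble with columns `chl`, `sst`, `pico`, `nano`, `dino`,
#'   `diatom` (all mg m^-3).
#' @examples
#' group_chlorophyll(c(0.05, 1, 5), sst = 18)
#' @export
group_chlorophyll <- function(chl, sst, params = community_params()) {
  stopifnot(is.numeric(chl), is.numeric(sst))
  if (any(chl < 0, na.rm = TRUE)) {
    stop("`chl` must be non-negative", call. = FALSE)
  }
  n <- max(length(chl), length(sst))
  chl <- rep_len(chl, n)
  sst <- rep_len(sst, n)
  if (any(sst < 0 | sst > 30.8, na.rm = TRUE)) {
    warning("SST outside the 0-30.8 degC calibration range; extrapolating",
            call. = FALSE)
  }
  g <- group_chl_core(chl, sst, params)
  tibble::tibble(chl = chl, sst = sst,
                 pico = g$pico, nano = g$nano, dino = g$dino, diatom = g$diatom)
}

#' Add group chlorophylls and fractions to a data frame
#'
#' Data-frame-first wrapper around [group_chlorophyll()]: appends the four
#' group concentrations (`chl_pico`, ..., mg m^-3) and fractions (`f_pico`,
#' ..., dimensionless, `NA` where total chlorophyll is zero) to `data`.
#'
#' @param data a data frame with chlorophyll and SST columns.
#' @param chl,sst tidy-selected columns holding total chlorophyll-a (mg m^-3)
#'   and SST (degrees C).
#' @inheritParams group_chlorophyll
#' @return `data` as a tibble with eight added columns.
#' @examples
#' tibble::tibble(chl = c(0.05, 2), sst = c(25, 8)) |> partition_chlorophyll()
#' @export
partition_chlorophyll <- function(data, chl = chl, sst = sst,
                                  params = community_params()) {
  chl_v <- dplyr::pull(data, {{ chl }})
  sst_v <- dplyr::pull(data, {{ sst }})
  g <- group_chlorophyll(chl_v, sst_v, params)
  out <- tibble::as_tibble(data)
  for (grp in fourpop_groups) {
    out[[paste0("chl_", grp)]] <- g[[grp]]
    out[[paste0("f_", grp)]] <- ifelse(chl_v > 0, g[[grp]] / chl_v, NA_real_)
  }
  out
}
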