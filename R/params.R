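#' Model wavebands
#'
#' The 12 band centres (nm) at which the packaged chlorophyll-specific
#' absorption coefficients are defined, matching common multispectral
#' ocean-colour sensors.
#'
#' @export
fourpop_bands <- c(412, 443, 490, 510, 520, 550, 555, 560, 620, 665, 670, 682)

#' Phytoplankton group labels
#'
#' Group labels in fixed order: picophytoplankton (<2 um), nanophytoplankton
#' (2-20 um), dinoflagellates and diatoms (both >20 um, microphytoplankton).
#'
#' @export
fourpop_groups <- c("pico", "nano", "dino", "diatom")

#' Community-structure parameters
#'
#' The sixteen logistic coefficients governing the SST dependence of the
#' chlorophyll partition, plus the slope (`alpha`, per degree C) and midpoint
#' (`beta`, degrees C) of the dinoflagellate-to-microphytoplankton logistic.
#' Each of `G`, `H`, `J`, `K` is a named vector `(a, b, c, d)`:
#' `G` controls the asymptotic maximum chlorophyll of cells <20 um (`C12m`),
#' `H` that of cells <2 um (`C1m`), `J` the low-chlorophyll fraction of cells
#' <20 um (`D12`) and `K` that of cells <2 um (`D1`). Coefficients `c` are in
#' degrees C; the rest are dimensionless.
#'
#' Defaults are the published North Atlantic calibration. Supply any argument
#' to override; overrides are validated only for finiteness, and the partition
#' functions clamp defensively so chlorophyll conservation and non-negativity
#' hold for any parameter set.
#'
#' @param G,H,J,K named numeric vectors `(a, b, c, d)`.
#' @param alpha slope of the dinoflagellate fraction logistic (per degree C).
#' @param beta SST midpoint of the dinoflagellate fraction logistic (degrees C).
#'
#' @return An object of class `community_params` (a named list).
#' @examples
#' p <- community_params()
#' p$J["b"] # slope of the D12 logistic
#' @export
community_params <- function(G = c(a = -1.51, b = -1.25, c = 14.95, d = 0.25),
                             H = c(a = 0.29, b = 3.05, c = 16.24, d = 0.56),
                             J = c(a = 0.370, b = 1.13, c = 14.89, d = 0.569),
                             K = c(a = 0.503, b = 1.33, c = 17.31, d = 0.258),
                             alpha = 0.10,
                             beta = 32.5) {
  coefs <- list(G = G, H = H, J = J, K = K)
  for (nm in names(coefs)) {
    v <- coefs[[nm]]
    if (length(v) != 4 || !all(c("a", "b", "c", "d") %in% names(v))) {
      stop(sprintf("`%s` must be a named vector (a, b, c, d)", nm), call. = FALSE)
    }
    if (!all(is.finite(v))) {
      stop(sprintf("`%s` must be finite", nm), call. = FALSE)
    }
    coefs[[nm]] <- v[c("a", "b", "c", "d")]
  }
  if (!is.finite(alpha) || !is.finite(beta)) {
    stop("`alpha` and `beta` must be finite", call. = FALSE)
  }
  structure(c(coefs, list(alpha = alpha, beta = beta)),
            class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat("Community-structure parameters (logistic coefficients)\n")
  m <- rbind(G = x$G, H = x$H, J = x$J, K = x$K)
  print(m)
  cat(sprintf("alpha = %.3g per degC, beta = %.3g degC\n", x$alpha, x$beta))
  invisible(x)
}

# Packaged calibration: a* (m2 per mg chl-a) and robust sd, by band x group.
# Row order follows fourpop_bands; column order pico, nano, dino, diatom.
.astar_values <- matrix(c(
  0.124, 0.052, 0.039, 0.011,
  0.183, 0.039, 0.041, 0.016,
  0.118, 0.022, 0.035, 0.009,
  0.067, 0.018, 0.026, 0.008,
  0.053, 0.016, 0.022, 0.007,
  0.028, 0.011, 0.013, 0.004,
  0.023, 0.011, 0.012, 0.003,
  0.018, 0.011, 0.010, 0.003,
  0.016, 0.007, 0.008, 0.004,
  0.037, 0.009, 0.010, 0.013,
  0.052, 0.011, 0.011, 0.015,
  0.054, 0.012, 0.009, 0.012
), nrow = 12, byrow = TRUE)

.astar_sd <- matrix(c(
  0.054, 0.031, 0.014, 0.004,
  0.043, 0.027, 0.016, 0.005,
  0.025, 0.018, 0.008, 0.003,
  0.020, 0.015, 0.005, 0.003,
  0.016, 0.013, 0.004, 0.002,
  0.010, 0.008, 0.002, 0.001,
  0.009, 0.007, 0.002, 0.001,
  0.008, 0.006, 0.002, 0.001,
  0.007, 0.005, 0.001, 0.001,
  0.010, 0.008, 0.006, 0.002,
  0.013, 0.010, 0.008, 0.002,
  0.013, 0.009, 0.008, 0.002
), nrow = 12, byrow = TRUE)

#' Chlorophyll-specific absorption coefficients
#'
#' Packaged chlorophyll-specific absorption coefficients a_i*(lambda)
#' (m2 per mg chlorophyll-a) with their robust standard deviations, for the
#' four groups at the 12 model wavebands: the published North Atlantic
#' calibration of the four-population model. Picophytoplankton have the
#' highest, steepest spectra; diatoms the lowest and flattest (package
#' effect).
#'
#' @return A tibble with columns `wavelength` (nm), `group`, `a_star`
#'   (m2 (mg chl-a)^-1) and `sd` (same units).
#' @examples
#' astar_table() |> dplyr::filter(wavelength == 443)
#' @export
astar_table <- function() {
  tibble::tibble(
    wavelength = rep(fourpop_bands, times = length(fourpop_groups)),
    group = rep(fourpop_groups, each = length(fourpop_bands)),
    a_star = as.vector(.astar_values),
    sd = as.vector(.astar_sd)
  )
}

# 4 x n_band matrix (rows = groups) from a tidy a* table, checking bands.
astar_matrix <- function(table = astar_table(), bands = NULL) {
  if (is.null(bands)) bands <- sort(unique(table$wavelength))
  missing_b <- setdiff(bands, table$wavelength)
  if (length(missing_b) > 0) {
    stop("a* table lacks waveband(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = length(fourpop_groups), ncol = length(bands),
              dimnames = list(fourpop_groups, bands))
  for (g in fourpop_groups) {
    sub <- table[table$group == g, ]
    m[g, ] <- sub$a_star[match(bands, sub$wavelength)]
  }
  if (anyNA(m)) stop("a* table is incomplete for the requested bands", call. = FALSE)
  if (any(m < 0)) stop("a* coefficients must be non-negative", call. = FALSE)
  m
}

#' Read or write community parameters as a flat YAML config
#'
#' The file stores flat keys `Ga..Gd, Ha..Hd, Ja..Jd, Ka..Kd, alpha, beta`.
#' A packaged default file with the published calibration ships in
#' `system.file("extdata", "community_params.yml", package = "fourpop")`.
#'
#' @param path file path.
#' @return `read_community_params()` returns a [community_params()] object;
#'   `write_community_params()` returns `path` invisibly.
#' @export
read_community_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  pick <- function(letter) {
    v <- vapply(c("a", "b", "c", "d"),
                function(i) as.numeric(cfg[[paste0(letter, i)]]), numeric(1))
    names(v) <- c("a", "b", "c", "d")
    v
  }
  community_params(G = pick("G"), H = pick("H"), J = pick("J"), K = pick("K"),
                   alpha = as.numeric(cfg$alpha), beta = as.numeric(cfg$beta))
}

#' @rdname read_community_params
#' @param params a [community_params()] object.
#' @export
write_community_params <- function(params, path) {
  stopifnot(inherits(params, "community_params"))
  out <- list()
  for (letter in c("G", "H", "J", "K")) {
    for (i in c("a", "b", "c", "d")) {
      out[[paste0(letter, i)]] <- unname(params[[letter]][i])
    }
  }
  out$alpha <- params$alpha
  out$beta <- params$beta
  yaml::write_yaml(out, path)
  invisible(path)
}
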