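# ggplot2 views of the main result types. Colours follow the group order
# pico, nano, dino, diatom throughout.

group_palette <- c(pico = "#0072B2", nano = "#009E73", dino = "#D55E00",
                   diatom = "#CC79A7", total = "grey25")

#' Plot absorption spectra
#'
#' Group and total absorption (or specific absorption) against wavelength,
#' faceted by observation when several (chl, SST) pairs are present.
#'
#' @param spectra output of [aph_four_pop()].
#' @param what `"aph"` (m^-1) or `"a_star"` (m2 (mg chl-a)^-1).
#' @return A ggplot object.
#' @examples
#' plot_spectra(aph_four_pop(c(0.1, 1), sst = c(10, 24)))
#' @export
plot_spectra <- function(spectra, what = c("aph", "a_star")) {
  what <- match.arg(what)
  p <- ggplot2::ggplot(spectra,
                       ggplot2::aes(x = .data$wavelength,
                                    y = .data[[what]],
                                    colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = group_palette) +
    ggplot2::labs(
      x = "wavelength (nm)",
      y = if (what == "aph") expression(a[ph] ~ (m^-1))
          else expression(a^"*" ~ (m^2 ~ mg^-1)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (length(unique(spectra$.obs)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$.obs))
  }
  p
}

#' Plot community composition against SST
#'
#' Group fractions of total chlorophyll as a function of SST at fixed total
#' chlorophyll, showing the warm-water shift toward picophytoplankton and
#' dinoflagellates.
#'
#' @param chl total chlorophyll-a (mg m^-3), a single value.
#' @param sst SST grid (degrees C).
#' @inheritParams group_chlorophyll
#' @return A ggplot object.
#' @examples
#' plot_community(0.05)
#' @export
plot_community <- function(chl = 0.1, sst = seq(0, 30, by = 0.25),
                           params = community_params()) {
  stopifnot(length(chl) == 1)
  d <- group_chlorophyll(chl, sst, params) |>
    tidyr::pivot_longer(dplyr::all_of(fourpop_groups), names_to = "group",
                        values_to = "chl_group") |>
    dplyr::mutate(fraction = .data$chl_group / .data$chl)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sst, y = .data$fraction,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = group_palette) +
    ggplot2::labs(x = "SST (°C)", y = "fraction of total chlorophyll",
                  colour = NULL,
                  title = sprintf("C = %g mg m⁻³", chl)) +
    ggplot2::theme_minimal()
}

#' Plot band-ratio curves
#'
#' Maximum band ratio against chlorophyll, one curve per SST level, on
#' log-log axes.
#'
#' @param curve output of [ratio_surface()].
#' @return A ggplot object.
#' @export
plot_ratio_surface <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$chl, y = .data$ratio,
                                      colour = factor(.data$sst))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(C ~ (mg ~ m^-3)),
                  y = "max band ratio", colour = "SST (°C)") +
    ggplot2::theme_minimal()
}

#' Autoplot a bootstrap calibration
#'
#' Bootstrap distributions of the four coefficients at one band, with the
#' median marked.
#'
#' @param object a [bootstrap_fit()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fourpop_boot <- function(object, ...) {
  d <- tibble::as_tibble(object$boot) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "group",
                        values_to = "a_star") |>
    dplyr::filter(!is.na(.data$a_star))
  med <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$a_star,
                                  fill = .data$group)) +
    ggplot2::geom_violin(colour = NA, alpha = 0.6) +
    ggplot2::geom_point(data = med,
                        ggplot2::aes(y = .data$median), size = 2) +
    ggplot2::scale_fill_manual(values = group_palette, guide = "none") +
    ggplot2::labs(x = NULL,
                  y = expression(a^"*" ~ (m^2 ~ mg^-1)),
                  title = sprintf("Bootstrap calibration at %g nm",
                                  object$band)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
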