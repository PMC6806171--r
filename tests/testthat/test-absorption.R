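test_that("absorption is additive over groups at every band", {
  spec <- aph_four_pop(c(0.05, 0.7, 12), c(8, 17, 26))
  by_band <- spec |>
    dplyr::filter(group != "total") |>
    dplyr::group_by(.obs, wavelength) |>
    dplyr::summarise(s = sum(aph), .groups = "drop")
  tot <- dplyr::filter(spec, group == "total")
  expect_equal(by_band$s, tot$aph, tolerance = 1e-12)
})

test_that("zero chlorophyll gives zero absorption but a finite specific absorption", {
  spec <- aph_four_pop(0, 15)
  expect_true(all(spec$aph == 0))
  tot <- dplyr::filter(spec, group == "total")
  lim <- a_star_limits(15)
  expect_equal(tot$a_star, lim$low_chl, tolerance = 1e-12)
})

test_that("one-band composition matches an independent hand evaluation", {
  ci <- partition_by_hand(0.5, 15)
  a443 <- c(0.183, 0.039, 0.041, 0.016)
  spec <- aph_four_pop(0.5, 15, bands = 443)
  expect_equal(dplyr::filter(spec, group == "total")$aph,
               sum(a443 * ci), tolerance = 1e-12)
  expect_equal(dplyr::filter(spec, group != "total")$aph,
               unname(a443 * ci), tolerance = 1e-12)
})

test_that("dino/diatom absorption ratio equals the a* ratio at the midpoint SST", {
  spec <- suppressWarnings(aph_four_pop(2, 32.5))
  wide <- tidyr::pivot_wider(spec[, c("wavelength", "group", "aph")],
                             names_from = "group", values_from = "aph")
  am <- astar_table()
  a3 <- dplyr::filter(am, group == "dino")$a_star
  a4 <- dplyr::filter(am, group == "diatom")$a_star
  expect_equal(wide$dino / wide$diatom, a3 / a4, tolerance = 1e-12)
})

test_that("total specific absorption is bounded by the group coefficients", {
  set.seed(7)
  chl <- 10^runif(50, -4, 4)
  sst <- runif(50, 0, 30)
  spec <- aph_four_pop(chl, sst)
  tot <- dplyr::filter(spec, group == "total")
  rng <- astar_table() |>
    dplyr::group_by(wavelength) |>
    dplyr::summarise(lo = min(a_star), hi = max(a_star))
  j <- match(tot$wavelength, rng$wavelength)
  expect_true(all(tot$a_star >= rng$lo[j] - 1e-12))
  expect_true(all(tot$a_star <= rng$hi[j] + 1e-12))
})

test_that("specific absorption approaches its closed-form low- and high-chlorophyll limits", {
  lim <- a_star_limits(c(6, 21))
  lo <- dplyr::filter(aph_four_pop(1e-8, c(6, 21)), group == "total")
  hi <- dplyr::filter(aph_four_pop(1e4, c(6, 21)), group == "total")
  expect_equal(lo$a_star, lim$low_chl, tolerance = 1e-6)
  expect_equal(hi$a_star, lim$high_chl, tolerance = 0.01)
})

test_that("high-chlorophyll limit is the dino/diatom mean at the midpoint SST", {
  lim <- suppressWarnings(a_star_limits(32.5, bands = 443))
  expect_equal(lim$high_chl, (0.041 + 0.016) / 2)
})

test_that("warm low-chlorophyll water has higher a*(443) than cool water", {
  tot <- dplyr::filter(aph_four_pop(0.05, c(10, 24), bands = 443),
                       group == "total")
  expect_gt(tot$a_star[tot$sst == 24], tot$a_star[tot$sst == 10])
})

test_that("spectral interpolation is exact at knots, linear between, bounded by endpoints", {
  spec <- aph_four_pop(1, 15) |> dplyr::select(wavelength, group, aph)
  at_knot <- interpolate_spectrum(spec, 443)
  expect_equal(dplyr::arrange(at_knot, group)$aph,
               dplyr::arrange(dplyr::filter(spec, wavelength == 443), group)$aph)
  mid <- interpolate_spectrum(dplyr::filter(spec, group == "total"), 552.5)
  ends <- dplyr::filter(spec, group == "total", wavelength %in% c(550, 555))
  expect_equal(mid$aph, mean(ends$aph))
  expect_true(mid$aph >= min(ends$aph) && mid$aph <= max(ends$aph))
  expect_error(interpolate_spectrum(spec, 700), "within")
  expect_error(interpolate_spectrum(spec, 400), "within")
})

test_that("power-law model evaluates A * C^(1-B) with edge-case handling", {
  coef <- tibble::tibble(wavelength = c(443, 555), A = c(0.05, 0.02),
                         B = c(0.3, 1.0))
  expect_equal(dplyr::filter(aph_power_law(1, coef), wavelength == 443)$aph,
               0.05)
  expect_equal(aph_power_law(2, coef[1, ])$aph, 0.05 * 2^0.7)
  # B = 1: flat in chlorophyll
  flat <- aph_power_law(c(0.5, 5), coef[2, ])
  expect_equal(unique(flat$aph), 0.02)
  expect_error(aph_power_law(0, tibble::tibble(wavelength = 443, A = 1, B = 1.2)),
               "undefined")
  expect_error(aph_power_law(1, tibble::tibble(wavelength = 443, A = -1, B = 0.5)),
               "positive")
})

test_that("three-population model nests inside the four-population model", {
  # freeze community parameters to SST-independent constants: zero-slope
  # logistics pinned at the three-population values
  size <- list(C1m = 0.4, C12m = 1.1, D1 = 0.3, D12 = 0.7)
  frozen <- community_params(
    G = c(a = 0, b = 1, c = 15, d = 1 - size$C12m),
    H = c(a = 0, b = 1, c = 15, d = 1 - size$C1m),
    J = c(a = 0, b = 1, c = 15, d = size$D12),
    K = c(a = 0, b = 1, c = 15, d = size$D1)
  )
  a_micro <- c(0.030, 0.030) # dino = diatom so the split is irrelevant
  tab <- tibble::tibble(
    wavelength = 443,
    group = fourpop_groups,
    a_star = c(0.18, 0.04, a_micro),
    sd = 0
  )
  chl <- c(0.01, 0.3, 2, 40)
  four <- dplyr::filter(aph_four_pop(chl, 10, table = tab, params = frozen),
                        group == "total")
  three <- aph_three_pop(chl,
                         tibble::tibble(wavelength = 443, a1 = 0.18,
                                        a2 = 0.04, a34 = 0.030),
                         size)
  expect_equal(four$aph, three$aph, tolerance = 1e-12)
  # limiting slope: linear in chlorophyll with coefficient a34
  big <- aph_three_pop(c(1e4, 2e4),
                       tibble::tibble(wavelength = 443, a1 = 0.18, a2 = 0.04,
                                      a34 = 0.030), size)
  expect_equal(diff(big$aph) / 1e4, 0.030, tolerance = 1e-6)
  expect_equal(aph_three_pop(0, tibble::tibble(wavelength = 443, a1 = 0.18,
                                               a2 = 0.04, a34 = 0.03),
                             size)$aph, 0)
})

test_that("requesting a band missing from the a* table is a configuration error", {
  expect_error(aph_four_pop(1, 15, bands = c(443, 444)), "444")
})

test_that("spectra serialise to the tidy CSV convention", {
  path <- withr::local_tempfile(fileext = ".csv")
  spec <- aph_four_pop(0.5, 15, bands = c(443, 555))
  write_spectra_csv(spec, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("wavelength_nm", "group", "aph_m-1",
                       "a_star_m2_per_mgC"))
  expect_equal(back$`aph_m-1`, spec$aph)
})
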