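test_that("logistic form has midpoint symmetry and saturation limits", {
  # midpoint: a/2 + d, here with the packaged D12 coefficients
  expect_equal(logistic_sst(14.89, 0.370, 1.13, 14.89, 0.569), 0.754)
  # saturation: rising logistic tends to d (cold) and a + d (warm)
  expect_equal(logistic_sst(-1e3, 0.370, 1.13, 14.89, 0.569), 0.569)
  expect_equal(logistic_sst(1e3, 0.370, 1.13, 14.89, 0.569), 0.939)
  expect_error(logistic_sst(Inf, 1, 1, 0, 0), "finite")
  expect_true(is.na(logistic_sst(NA_real_, 1, 1, 0, 0)))
})

test_that("size-structure coefficients match direct evaluation of the logistics", {
  # at the C12m midpoint SST: 1 - (Ga/2 + Gd)
  expect_equal(size_params(14.95)$C12m, 1 - (-1.51 / 2 + 0.25))
  # cold and warm saturation; note the C12m logistic has a negative slope,
  # so its cold-water limit is 1 - (Ga + Gd) and its warm-water limit 1 - Gd
  cold <- size_params(-500)
  warm <- size_params(500)
  expect_equal(cold$C12m, 1 - (-1.51 + 0.25))
  expect_equal(warm$C12m, 0.75)
  expect_equal(cold$D1, 0.258)
  expect_equal(warm$D12, 0.939)
})

test_that("size fractions are ordered and bounded over a dense SST grid", {
  sst <- seq(-5, 40, by = 0.05)
  sp <- size_params(sst)
  expect_true(all(sp$D1 > 0))
  expect_true(all(sp$D1 <= sp$D12))
  expect_true(all(sp$D12 < 1))
  expect_true(all(sp$C1m <= sp$C12m))
})

test_that("dinoflagellate fraction is a rising logistic with midpoint 0.5", {
  expect_equal(dino_fraction(32.5), 0.5)
  expect_equal(dino_fraction(22.5), 1 / (1 + exp(1)), tolerance = 1e-10)
  expect_equal(dino_fraction(1e4), 1.0)
  sst <- seq(-2, 40, by = 0.5)
  q <- dino_fraction(sst)
  expect_true(all(q > 0 & q < 1))
  expect_true(all(diff(q) > 0))
})

test_that("partition conserves chlorophyll and stays non-negative", {
  set.seed(101)
  chl <- c(0, 10^runif(200, -2, 2))
  sst <- c(15, runif(200, -2, 35))
  g <- suppressWarnings(group_chlorophyll(chl, sst))
  tot <- g$pico + g$nano + g$dino + g$diatom
  expect_equal(tot, chl, tolerance = 1e-12)
  expect_true(all(as.matrix(g[, fourpop_groups]) >= 0))
  # saturation: size-class chlorophyll never exceeds its asymptote
  sp <- suppressWarnings(size_params(sst))
  expect_true(all(g$pico <= sp$C1m + 1e-12))
  expect_true(all(g$pico + g$nano <= sp$C12m + 1e-12))
})

test_that("partition matches an independent scalar transcription of the model", {
  for (case in list(c(0.1, 20), c(1.0, 5), c(8, 28), c(0.02, 12.3))) {
    got <- group_chlorophyll(case[1], case[2])
    expect_equal(unlist(got[1, fourpop_groups]),
                 partition_by_hand(case[1], case[2]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("group fractions approach the D-controlled limits as chlorophyll vanishes", {
  g <- group_chlorophyll(1e-8, 18)
  sp <- size_params(18)
  expect_equal(g$pico / g$chl, sp$D1, tolerance = 1e-6)
  expect_equal((g$pico + g$nano) / g$chl, sp$D12, tolerance = 1e-6)
})

test_that("dinoflagellates equal diatoms at the partition midpoint SST", {
  g <- suppressWarnings(group_chlorophyll(1.0, 32.5))
  expect_equal(g$dino, g$diatom)
})

test_that("picophytoplankton fraction is non-decreasing in SST at low chlorophyll", {
  d <- partition_chlorophyll(tibble::tibble(chl = 0.05, sst = seq(0, 30, 0.25)))
  expect_true(all(diff(d$f_pico) >= -1e-12))
})

test_that("clamping keeps invariants for pathological parameter sets", {
  # force D12 > 1 so the small-cell saturation would overshoot the total
  bad <- community_params(J = c(a = 2.0, b = 1.13, c = 14.89, d = 0.569))
  g <- group_chlorophyll(c(0.05, 1, 20), 25, params = bad)
  expect_true(all(as.matrix(g[, fourpop_groups]) >= 0))
  expect_equal(rowSums(as.matrix(g[, fourpop_groups])), g$chl,
               tolerance = 1e-12)
})

test_that("input validation: negative chlorophyll errors, out-of-range SST warns", {
  expect_error(group_chlorophyll(-0.1, 15), "non-negative")
  expect_warning(group_chlorophyll(1, 35), "calibration range")
  expect_silent(group_chlorophyll(1, 15))
  g <- group_chlorophyll(c(1, NA), c(NA, 10))
  expect_true(all(is.na(g$pico)))
})

test_that("community parameters validate and round-trip through YAML", {
  expect_error(community_params(G = c(1, 2, 3)), "named vector")
  expect_error(community_params(alpha = NaN), "finite")
  path <- withr::local_tempfile(fileext = ".yml")
  p <- community_params(alpha = 0.12)
  write_community_params(p, path)
  p2 <- read_community_params(path)
  expect_equal(p2$alpha, 0.12)
  expect_equal(p2$K, p$K)
})
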