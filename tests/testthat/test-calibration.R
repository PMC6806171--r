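test_that("robust sd is the 1.4826-scaled median absolute deviation", {
  expect_equal(robust_sd(rep(3, 10)), 0)
  expect_equal(robust_sd(c(-1, 0, 1)), 1.4826)
  set.seed(5)
  x <- rnorm(20000, sd = 2.5)
  expect_equal(robust_sd(x), 2.5, tolerance = 0.05)
  expect_error(robust_sd(1), "at least two")
})

test_that("noise-free calibration recovers the generating coefficients exactly", {
  obs <- make_grid_obs(bands = c(443, 550))
  truth <- astar_table()
  for (b in c(443, 550)) {
    fit <- fit_band(obs, b)
    want <- dplyr::filter(truth, wavelength == b)$a_star
    expect_equal(fit$estimate, want, tolerance = 1e-6)
    expect_true(all(fit$converged))
    expect_false(any(fit$at_bound))
  }
})

test_that("bounded LM fit equals the non-negative least-squares oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    X <- matrix(runif(n * 4), n, 4)
    beta <- pmax(rnorm(4, 0.05, 0.1), 0) * rbinom(4, 1, 0.7)
    y <- as.vector(X %*% beta + rnorm(n, 0, 0.02))
    imp <- fourpop:::lm_nnls(y, X)$estimate
    orc <- pracma::lsqnonneg(X, y)$x
    expect_lt(max(abs(unname(imp) - orc)), 1e-8)
  }
})

test_that("zero observed absorption yields all-zero coefficients, flagged at the bound", {
  obs <- make_grid_obs(bands = 443, n_chl = 10)
  obs$aph_443 <- 0
  fit <- fit_band(obs, 443)
  expect_equal(fit$estimate, rep(0, 4))
  expect_true(all(fit$at_bound))
})

test_that("coefficients are never negative even when the unconstrained fit would be", {
  obs <- make_grid_obs(bands = 443, n_chl = 15)
  # subtract a multiple of the nano contribution so its LS coefficient
  # would go negative
  g <- group_chlorophyll(obs$chl, obs$sst)
  obs$aph_443 <- pmax(obs$aph_443 - 0.06 * g$nano, 0)
  fit <- fit_band(obs, 443)
  expect_true(all(fit$estimate >= 0))
  expect_true(fit$at_bound[fit$group == "nano"])
})

test_that("a rank-deficient design raises a singular-fit error naming the problem", {
  obs <- simulate_observations(chl = rep(0.5, 12), sst = rep(15, 12),
                               bands = 443, seed = 1)
  expect_error(fit_band(obs, 443), "singular design")
})

test_that("too few records or missing columns are informative errors", {
  obs <- make_grid_obs(bands = 443, n_chl = 2, sst_values = 15)
  expect_error(fit_band(obs, 443), "at least 4")
  expect_error(fit_band(obs, 555), "aph_555")
})

test_that("bootstrap is deterministic for a fixed seed and degenerate without noise", {
  obs <- make_grid_obs(bands = 443, n_chl = 12, sst_values = c(5, 15, 25))
  b1 <- bootstrap_fit(obs, 443, n_boot = 30, seed = 99)
  b2 <- bootstrap_fit(obs, 443, n_boot = 30, seed = 99)
  expect_identical(b1$boot, b2$boot)
  expect_identical(tidy(b1), tidy(b2))
  # noise-free: every resample refit returns the generating coefficients
  truth <- dplyr::filter(astar_table(), wavelength == 443)$a_star
  expect_equal(unname(b1$median), truth, tolerance = 1e-6)
  expect_equal(unname(b1$robust_sd), rep(0, 4), tolerance = 1e-6)
  expect_equal(glance(b1)$n_fail, 0L)
})

test_that("bootstrap medians track the truth under lognormal noise", {
  design <- tidyr::expand_grid(
    chl = 10^seq(log10(0.01), log10(30), length.out = 40),
    sst = seq(2, 30, length.out = 10)
  )
  obs <- simulate_observations(chl = design$chl, sst = design$sst,
                               noise_log10_sd = 0.086, bands = 443,
                               seed = 2024)
  b <- bootstrap_fit(obs, 443, n_boot = 100, seed = 1)
  truth <- dplyr::filter(astar_table(), wavelength == 443)$a_star
  d <- tidy(b)
  # the bootstrap distribution centres on the point fit and has real spread
  expect_true(all(abs(d$median - d$estimate) <= d$robust_sd))
  expect_true(all(d$robust_sd > 0))
  # the tightly constrained microphytoplankton coefficients sit near truth
  micro <- d$group %in% c("dino", "diatom")
  expect_true(all(abs(d$median - truth)[micro] <= 3 * d$robust_sd[micro]))
})

test_that("full-table calibration mirrors the coefficient-table layout with provenance", {
  obs <- make_grid_obs(bands = c(443, 665), n_chl = 15,
                       sst_values = c(5, 15, 25))
  fit <- fit_astar(obs, n_boot = 10, seed = 5)
  expect_named(fit, c("wavelength", "group", "a_star", "sd"))
  expect_equal(nrow(fit), 8)
  expect_equal(attr(fit, "seed"), 5)
  truth <- astar_table()
  joined <- dplyr::inner_join(fit, truth, by = c("wavelength", "group"))
  expect_equal(joined$a_star.x, joined$a_star.y, tolerance = 1e-6)
})
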