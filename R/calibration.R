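#' Robust standard deviation
#'
#' Scaled median absolute deviation: `1.4826 * median(|x - median(x)|)`,
#' consistent for the standard deviation under normality.
#'
#' @param x numeric vector with at least two non-missing values.
#' @return A single non-negative number.
#' @examples
#' robust_sd(c(-1, 0, 1)) # 1.4826
#' @export
robust_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    stop("robust_sd() needs at least two non-missing values", call. = FALSE)
  }
  stats::mad(x, constant = 1.4826)
}

# Extract (y, X) for one band from an observation table: y = measured aph at
# the band, X = the four group chlorophylls. Rows with missing aph dropped.
band_design <- function(obs, band, params) {
  col <- paste0("aph_", format(band))
  if (!col %in% names(obs)) {
    stop(sprintf("observations lack column `%s`", col), call. = FALSE)
  }
  keep <- !is.na(obs[[col]]) & !is.na(obs$chl) & !is.na(obs$sst)
  obs <- obs[keep, ]
  if (nrow(obs) < 4) {
    stop(sprintf("need at least 4 observations with aph at %g nm", band),
         call. = FALSE)
  }
  if (any(obs[[col]] < 0)) {
    stop("measured aph must be non-negative", call. = FALSE)
  }
  g <- group_chlorophyll(obs$chl, obs$sst, params)
  X <- as.matrix(g[, fourpop_groups])
  list(y = obs[[col]], X = X)
}

# Diagnose a rank-deficient design: name near-zero and collinear columns.
check_design_rank <- function(X) {
  if (qr(X)$rank == ncol(X)) return(invisible(TRUE))
  norms <- sqrt(colSums(X^2))
  degenerate <- colnames(X)[norms < max(norms) * 1e-10]
  live <- X[, norms >= max(norms) * 1e-10, drop = FALSE]
  pairs <- character(0)
  if (ncol(live) >= 2) {
    cm <- suppressWarnings(stats::cor(live))
    idx <- which(abs(cm) > 1 - 1e-8 & upper.tri(cm), arr.ind = TRUE)
    pairs <- apply(idx, 1, function(i) {
      paste(colnames(live)[i], collapse = "~")
    })
  }
  stop("singular design: group chlorophyll columns are not independent (",
       paste(c(degenerate, pairs), collapse = ", "),
       "); broaden the (chl, sst) coverage", call. = FALSE)
}

# Bounded Levenberg-Marquardt solve of y ~ X %*% astar with astar >= 0.
# The model is linear in the coefficients, so the minimiser coincides with
# the non-negative least-squares solution. Projected LM loses accuracy in
# the remaining free coefficients when a bound is active, so the LM pass is
# polished by refitting the interior (free) coefficients, releasing a
# clamped coefficient if its gradient points back into the feasible region
# (KKT check).
lm_nnls <- function(y, X) {
  k <- ncol(X)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     gtol = 1e-15, maxiter = 1000)
  run_lm <- function(start, free) {
    minpack.lm::nls.lm(
      par = start[free],
      lower = rep(0, sum(free)),
      fn = function(p) {
        full <- numeric(k)
        full[free] <- p
        y - as.vector(X %*% full)
      },
      control = ctrl
    )
  }
  start <- stats::coef(stats::lm.fit(X, y))
  start[!is.finite(start) | start < 0] <- 0
  free <- rep(TRUE, k)
  fit <- run_lm(start, free)
  est <- numeric(k)
  est[free] <- fit$par
  for (pass in 1:8) {
    new_free <- est > 1e-9 * max(est, 1e-30)
    grad <- -as.vector(crossprod(X, y - X %*% est))
    release <- !new_free & grad < -1e-10 * max(abs(grad), 1e-30)
    new_free <- new_free | release
    if (!any(new_free)) break
    fit <- run_lm(est, new_free)
    est <- numeric(k)
    est[new_free] <- fit$par
    if (identical(new_free, free) && !any(release)) break
    free <- new_free
  }
  names(est) <- colnames(X)
  list(estimate = est, converged = fit$info %in% 1:4, info = fit$info,
       deviance = fit$deviance)
}

#' Calibrate specific-absorption coefficients at one waveband
#'
#' Fits the four chlorophyll-specific absorption coefficients at a single
#' waveband by bounded (non-negative) Levenberg-Marquardt least squares in
#' linear absorption space: the group chlorophylls are fixed functions of the
#' observed (chlorophyll, SST) through the packaged community parameters, so
#' the model is linear in the coefficients and the bounded fit coincides with
#' the non-negative linear least-squares solution. A coefficient held at the
#' zero bound is flagged, not silently clipped.
#'
#' @param obs an observation tibble with columns `chl` (mg m^-3), `sst`
#'   (degrees C) and per-band absorption columns named `aph_<band>` (m^-1),
#'   e.g. `aph_443`; see [simulate_observations()] and [read_observations()].
#' @param band waveband (nm) to fit.
#' @param params community parameters, held fixed during fitting.
#' @return A tibble with columns `wavelength`, `group`, `estimate`
#'   (m2 (mg chl-a)^-1), `at_bound` (logical) and `converged`.
#' @examples
#' obs <- simulate_observations(60, seed = 1)
#' fit_band(obs, 443)
#' @export
fit_band <- function(obs, band, params = community_params()) {
  d <- band_design(obs, band, params)
  check_design_rank(d$X)
  fit <- lm_nnls(d$y, d$X)
  tibble::tibble(
    wavelength = band,
    group = fourpop_groups,
    estimate = unname(fit$estimate),
    at_bound = unname(fit$estimate) == 0,
    converged = fit$converged
  )
}

#' Bootstrap calibration at one waveband
#'
#' Resamples whole observation records with replacement, refits the bounded
#' least-squares calibration on each resample, and summarises each
#' coefficient by the bootstrap median and robust standard deviation
#' ([robust_sd()]). Resamples that fail to fit are recorded and excluded; more
#' than 10% failures triggers a warning. Fully reproducible for a fixed seed.
#'
#' @inheritParams fit_band
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the resampling RNG.
#' @return An object of class `fourpop_boot`: a list with the point-fit
#'   tibble (`fit`), `median` and `robust_sd` named vectors, the
#'   `boot` sample matrix (`n_boot` x 4, failed rows `NA`), `n_fail`, `n_obs`,
#'   `band` and `seed`. Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' obs <- simulate_observations(80, noise_log10_sd = 0.05, seed = 2)
#' b <- bootstrap_fit(obs, 443, n_boot = 50, seed = 7)
#' tidy(b)
#' @export
bootstrap_fit <- function(obs, band, params = community_params(),
                          n_boot = 1000, seed = NULL) {
  d <- band_design(obs, band, params)
  check_design_rank(d$X)
  point <- lm_nnls(d$y, d$X)
  n <- length(d$y)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1) # recorded for provenance
  idx <- withr::with_seed(seed, {
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  })
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 4,
                 dimnames = list(NULL, fourpop_groups))
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    i <- idx[b, ]
    res <- tryCatch(lm_nnls(d$y[i], d$X[i, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      n_fail <- n_fail + 1L
    } else {
      boot[b, ] <- res$estimate
    }
  }
  if (n_fail > 0.1 * n_boot) {
    warning(sprintf("%d of %d bootstrap resamples failed to converge",
                    n_fail, n_boot), call. = FALSE)
  }
  med <- apply(boot, 2, stats::median, na.rm = TRUE)
  rsd <- apply(boot, 2, function(x) robust_sd(x))
  structure(
    list(
      band = band,
      fit = tibble::tibble(wavelength = band, group = fourpop_groups,
                           estimate = unname(point$estimate),
                           at_bound = unname(point$estimate) == 0,
                           converged = point$converged),
      median = med,
      robust_sd = rsd,
      boot = boot,
      n_fail = n_fail,
      n_obs = n,
      n_boot = n_boot,
      seed = seed
    ),
    class = "fourpop_boot"
  )
}

#' @export
print.fourpop_boot <- function(x, ...) {
  cat(sprintf("Bootstrap calibration at %g nm (%d obs, %d resamples, %d failed)\n",
              x$band, x$n_obs, x$n_boot, x$n_fail))
  print(tidy(x))
  invisible(x)
}

#' Calibrate the full specific-absorption table
#'
#' Runs the per-band bootstrap calibration across wavebands, resampling whole
#' records (all bands share each resample), and assembles a tidy coefficient
#' table in the same layout as [astar_table()]: bootstrap median as `a_star`,
#' robust standard deviation as `sd`.
#'
#' @inheritParams bootstrap_fit
#' @param bands wavebands to fit; defaults to every `aph_<band>` column
#'   present in `obs`.
#' @return A tibble with columns `wavelength`, `group`, `a_star`, `sd`, and
#'   attributes `seed`, `n_boot` and `n_fail` (per band).
#' @examples
#' obs <- simulate_observations(80, bands = c(443, 550), seed = 3)
#' fit_astar(obs, n_boot = 20, seed = 4)
#' @export
fit_astar <- function(obs, bands = NULL, params = community_params(),
                      n_boot = 1000, seed = NULL) {
  if (is.null(bands)) {
    bands <- as.numeric(sub("^aph_", "", grep("^aph_", names(obs), value = TRUE)))
    if (length(bands) == 0) stop("no `aph_<band>` columns found", call. = FALSE)
  }
  # one seed shared across bands so every band sees the same record resamples
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  fits <- purrr::map(bands, function(b) {
    bootstrap_fit(obs, b, params = params, n_boot = n_boot, seed = seed)
  })
  out <- purrr::map2(fits, bands, function(f, b) {
    tibble::tibble(wavelength = b, group = fourpop_groups,
                   a_star = unname(f$median), sd = unname(f$robust_sd))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "seed") <- seed
  attr(out, "n_boot") <- n_boot
  attr(out, "n_fail") <- stats::setNames(
    vapply(fits, function(f) f$n_fail, integer(1)), bands)
  out
}
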