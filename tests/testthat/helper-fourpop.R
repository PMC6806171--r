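# Shared fixtures, built in code.

# Well-conditioned noise-free calibration design: log-spaced chlorophyll
# crossed with a spread of SSTs, absorption generated from the packaged
# parameter tables.
make_grid_obs <- function(bands = fourpop_bands, n_chl = 40,
                          sst_values = c(5, 10, 15, 20, 25, 30)) {
  observation_grid(n_chl = n_chl, sst_values = sst_values, bands = bands)
}

# Independent straight-line evaluation of the chlorophyll partition,
# transcribing the model equations without the package's vectorised/clamped
# code path (scalar, no clamping; valid for the packaged parameter set).
partition_by_hand <- function(chl, sst, p = community_params()) {
  lg <- function(sst, v) v[["a"]] / (1 + exp(-v[["b"]] * (sst - v[["c"]]))) + v[["d"]]
  c12m <- 1 - lg(sst, p$G)
  c1m <- 1 - lg(sst, p$H)
  d12 <- lg(sst, p$J)
  d1 <- lg(sst, p$K)
  c12 <- c12m * (1 - exp(-d12 * chl / c12m))
  c1 <- c1m * (1 - exp(-d1 * chl / c1m))
  q <- 1 / (1 + exp(-p$alpha * (sst - p$beta)))
  c34 <- chl - c12
  c(pico = c1, nano = c12 - c1, dino = q * c34, diatom = (1 - q) * c34)
}
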