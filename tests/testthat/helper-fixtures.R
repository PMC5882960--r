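# collection of n series sharing a common standard-normal signal with
# pairwise correlation rbar; optionally staggered first years
make_common_signal_collection <- function(n, len, rbar = 1, first_year = 1950,
                                          stagger = 0, seed = 1,
                                          mean_level = 1, noise_scale = 0.1) {
  set.seed(seed)
  common <- rnorm(len + stagger)
  series_collection(lapply(seq_len(n), function(i) {
    fy <- first_year + if (stagger > 0) (i %% (stagger + 1)) else 0
    k <- fy - first_year
    sig <- sqrt(rbar) * common[(k + 1):(k + len)] +
      sqrt(1 - rbar) * rnorm(len)
    increment_series(sprintf("T%03d", i), fy,
                     pmax(mean_level + noise_scale * sig, 1e-3))
  }))
}

# detrended collection wrapping raw index values directly
as_detrended <- function(collection, mode = "ratio") {
  series_collection(lapply(collection, function(s)
    detrended_series(s$specimen_id, s$first_year, s$widths, mode = mode)))
}

# deterministic negative-exponential series
negexp_series <- function(id = "NEG", first_year = 1950, n = 40,
                          a = 2, b = 0.1, k = 0.5) {
  age <- seq_len(n)
  increment_series(id, first_year, a * exp(-b * age) + k)
}

default_scenario <- function(seed, ...) {
  sim_config(seed = seed, ...)
}
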