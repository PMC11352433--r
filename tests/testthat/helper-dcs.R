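# Shared fixtures: typical tissue optics, random photon-count series
# generators, and an independent direct-summation correlator check.

tissue_optics <- function() optical_config(mu_a = 0.1, mu_s_prime = 10, rho = 1)
tissue_constants <- function() derive_constants(tissue_optics())

phantom_optics <- function() {
  optical_config(mu_a = 0.23, mu_s_prime = 17.2, rho = 1)
}

# Poisson series at a constant rate (counts/bin)
rand_poisson_series <- function(n, rate = 2) {
  photon_count_series(rpois(n, rate), bin_width = 1e-6)
}

# bursty: blockwise alternation between a faint and a bright rate
rand_bursty_series <- function(n, lo = 0.2, hi = 20, block = 500) {
  rates <- rep(rep(c(lo, hi), length.out = ceiling(n / block)), each = block)
  photon_count_series(rpois(n, rates[seq_len(n)]), bin_width = 1e-6)
}

expect_curves_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$taus, b$taus)
  rel <- abs(a$g2 - b$g2) / pmax(abs(b$g2), .Machine$double.xmin)
  expect_lt(max(rel), tol)
}
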