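# Independent oracles and shared fixtures for the test suite.

# AUC by brute-force pair counting (ties count half).
auc_brute <- function(low, high) {
  wins <- 0
  for (h in high) for (l in low) {
    wins <- wins + (h > l) + 0.5 * (h == l)
  }
  wins / (length(low) * length(high))
}

# OLS slope via the closed covariance formula (independent of lm()).
slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Multiply two polynomials given as coefficient vectors (ascending powers).
poly_mult <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  }
  out
}

# Small standard volume fixture: 7 voids in one layer, one spheroid each.
make_small_sim <- function(dose = 0, hill = hill_params(18.92, 2.807),
                           noise = list(gauss_sd = 50, poisson_gain = 1),
                           seed = 42L, jitter_sd = 0, ...) {
  lat <- build_void_lattice(lattice_spec(250, 760), jitter_sd = jitter_sd,
                            seed = seed)
  sim <- simulate_volume(lat, dose = dose, hill = hill, noise = noise,
                         seed = seed + 1L, ...)
  sim$lattice <- lat
  sim
}

# Match detected records/ROIs to ground-truth spheroids by nearest centre.
match_truth <- function(records, truth, x = "x_um", y = "y_um") {
  vapply(seq_len(nrow(records)), function(i) {
    d2 <- (truth$x - records[[x]][i])^2 + (truth$y - records[[y]][i])^2
    which.min(d2)
  }, integer(1))
}
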