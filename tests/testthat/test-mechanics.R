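# Contact-mechanics model: modulus estimation, loading group, quartic solve,
# cap diameter, and their analytic invariants.

test_that("compressive modulus recovers the small-strain slope", {
  eps <- seq(1e-4, 1.1e-3, by = 1e-4)

  # exact line: slope recovered for any n_points
  curve <- stress_strain_curve(eps, 2156 * eps)
  expect_equal(estimate_compressive_modulus(curve), 2156, tolerance = 1e-12)
  expect_equal(estimate_compressive_modulus(curve, n_points = 5), 2156,
               tolerance = 1e-12)

  # weak quadratic term: slope within 0.1% of the analytic derivative at 0
  curve2 <- stress_strain_curve(eps, 477.4 * eps + 50 * eps^2)
  expect_equal(estimate_compressive_modulus(curve2), 477.4, tolerance = 1e-3)

  # noisy line against the independent least-squares oracle, and within the
  # analytic 3-sigma slope bound sd / sqrt(Sxx)
  set.seed(101)
  eps2 <- seq(0.01, 0.11, by = 0.01)
  y <- 1128.3 * eps2 + rnorm(length(eps2), 0, 0.5)
  curve3 <- stress_strain_curve(eps2, y)
  est <- estimate_compressive_modulus(curve3)
  expect_equal(est, slope_oracle(eps2, y), tolerance = 1e-10)
  se <- 0.5 / sqrt(sum((eps2 - mean(eps2))^2))
  expect_lt(abs(est - 1128.3), 3 * se)
})

test_that("stress-strain validation rejects malformed curves", {
  expect_error(stress_strain_curve(c(0.1, 0.1), c(1, 2)), "ascending")
  expect_error(stress_strain_curve(0.1, 1), "at least 2")
  expect_warning(
    estimate_compressive_modulus(stress_strain_curve(c(0, 1e-4), c(0, 0.2))),
    "using all"
  )
})

test_that("dimensionless load matches the printed SI groups and limits", {
  b1 <- microgel_batch(0.03, 2.156e6, 253.3)
  expect_equal(dimensionless_load(b1, "eq3"), 1000 * 0.03 * 9.81 / (3 * 2.156e6),
               tolerance = 1e-12)
  b2 <- microgel_batch(0.02, 4.774e5, 277.2)
  expect_equal(dimensionless_load(b2, "eq2"), 2 * 1000 * 0.02 * 9.81 / 4.774e5,
               tolerance = 1e-12)
  # stiff limit: lambda -> 0 as Ec -> Inf
  expect_lt(dimensionless_load(microgel_batch(0.03, 1e15, 250), "eq2"), 1e-12)
  expect_error(microgel_batch(0.03, -1, 250), "> 0")
  expect_error(microgel_batch(0.3, 1e6, 250), "fraction")
})

test_that("the lambda = 0 quartic factors as (x - a)^3 (x + 2a)", {
  for (a in c(0.5, 1, 126.65)) {
    # (x - a)^3 (x + 2a), ascending coefficients, via polynomial multiplication
    cube <- poly_mult(poly_mult(c(-a, 1), c(-a, 1)), c(-a, 1))
    expanded <- poly_mult(cube, c(2 * a, 1))
    expect_equal(expanded, c(-2 * a^4, 5 * a^3, -3 * a^2, -a, 1),
                 tolerance = 1e-12)
  }
})

test_that("contact solutions satisfy the quartic, Pythagoras, and asymptote", {
  # lambda = 0: exact tangency
  sol0 <- solve_contact_distance(253.3, 0)
  expect_identical(sol0$di, 253.3)
  expect_equal(sol0$rcap, 0)

  # derived reference roots (independent numeric root-finder agreement)
  expect_equal(solve_contact_distance(253.3, 4.55e-5)$di_over_r, 0.9688,
               tolerance = 2e-4)
  expect_equal(solve_contact_distance(277.2, 8.22e-4)$di_over_r, 0.918,
               tolerance = 1e-3)

  lams <- 10^seq(-7, -2, by = 0.5)
  prev_di <- Inf
  prev_rcap <- -Inf
  for (lam in lams) {
    sol <- solve_contact_distance(253.3, lam)
    a <- 253.3 / 2
    x <- sol$di / 2
    # residual contract
    expect_lt(abs(x^4 - a * x^3 - 3 * a^2 * x^2 + 5 * a^3 * x -
                    2 * a^4 * (1 - lam)), 1e-10 * a^4)
    # Pythagorean contract to 1e-9 relative
    expect_equal(sol$rcap^2 + sol$di^2, 253.3^2, tolerance = 1e-9)
    # cube-root asymptote at small load
    if (lam < 1e-4) {
      expect_lt(abs(sol$di_over_r - (1 - (2 * lam / 3)^(1 / 3))), 1e-3)
    }
    # monotone: Di decreases, Rcap increases with load
    expect_lt(sol$di, prev_di)
    expect_gt(sol$rcap, prev_rcap)
    prev_di <- sol$di
    prev_rcap <- sol$rcap
  }
})

test_that("cap diameter handles boundary geometry and bad input", {
  expect_equal(cap_diameter(250, 250), 0)
  expect_equal(cap_diameter(250, 0), 250)
  # derived example: near-rigid assembly
  expect_equal(cap_diameter(253.3, 0.983 * 253.3), 46.51, tolerance = 1e-2)
  expect_error(cap_diameter(250, 260), "exceeds")
})

test_that("predict_contact reproduces measured channel scale for stiff gels", {
  # 3.0% w/v batch: per-pair measured caps were 45.4 +/- 16.7 um; the
  # point-model value is expected only in that broad neighbourhood
  sol <- predict_contact(microgel_batch(0.03, 2.156e6, 253.3), "eq3")
  expect_gt(sol$rcap, 45.4 * 0.85)
  expect_lt(sol$rcap, 45.4 * 1.7)
})

test_that("stress-strain CSV round-trips through the reader", {
  eps <- seq(1e-4, 1.1e-3, by = 1e-4)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(strain = eps, stress_kpa = 2156 * eps), path)
  curve <- read_stress_strain(path)
  expect_equal(estimate_compressive_modulus(curve), 2156, tolerance = 1e-9)
})
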