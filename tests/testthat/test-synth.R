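# Generators: lattice geometry, volume ground truth, well-scans, histology
# pixels. Everything must be deterministic given its seed.

test_that("void lattice matches enumeration and HCP geometry", {
  # single layer, container = 3 d: the classic 7-circle arrangement
  lat <- build_void_lattice(lattice_spec(250, 750), seed = 1)
  expect_identical(nrow(lat), 7L)
  expect_identical(nrow(lat),
                   as.integer(count_circles_in_circle(lattice_spec(250, 750))))

  # default layer spacing is pitch * sqrt(2/3)
  spec <- lattice_spec(250, 750, layers = 3)
  lat3 <- build_void_lattice(spec, seed = 1)
  expect_equal(sort(unique(lat3$z)),
               (0:2) * 250 * sqrt(2 / 3), tolerance = 1e-12)

  # jitter-free nearest-neighbour distance equals the pitch
  d <- as.matrix(dist(lat[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(250, 7), tolerance = 1e-9)

  # determinism and jitter bound
  latj1 <- build_void_lattice(spec, jitter_sd = 3, seed = 7)
  latj2 <- build_void_lattice(spec, jitter_sd = 3, seed = 7)
  expect_identical(latj1, latj2)
  expect_lt(max(abs(latj1$x - lat3$x)), 3 * 5)  # well within 5 sd
})

test_that("volume ground truth obeys the Hill viability model", {
  hill <- hill_params(20, 2)

  # dose 0, no noise: no red voxels at all, viability exactly 1
  sim0 <- make_small_sim(dose = 0, hill = hill,
                         noise = list(gauss_sd = 0, poisson_gain = 0))
  expect_identical(sum(sim0$volume$red), 0)
  expect_true(all(sim0$truth$viability == 1))
  expect_true(all(sim0$truth$dead_fraction == 0))

  # dose = ic50: dead-voxel fraction ~ 0.5 within binomial error per spheroid
  sim50 <- make_small_sim(dose = 20, hill = hill,
                          noise = list(gauss_sd = 0, poisson_gain = 0))
  n_vox <- 4 / 3 * pi * (179.2 / 2)^3 / 125  # typical spheroid voxel count
  expect_true(all(abs(sim50$truth$dead_fraction - 0.5) < 4 / sqrt(n_vox)))

  # dead voxel counts are jointly binomial: pooled z-statistic is modest
  pooled_p <- mean(sim50$truth$dead_fraction)
  expect_lt(abs(pooled_p - 0.5), 0.02)

  # determinism
  sim50b <- make_small_sim(dose = 20, hill = hill,
                           noise = list(gauss_sd = 0, poisson_gain = 0))
  expect_identical(sim50$volume$red, sim50b$volume$red)
  expect_identical(sim50$truth, sim50b$truth)
})

test_that("scaffold intensity is periodic in z across layers", {
  # container wide enough that A and B layers carry comparable void counts,
  # so the autocorrelation fundamental sits at one layer spacing
  spec <- lattice_spec(250, 1300, layers = 3)
  lat <- build_void_lattice(spec, seed = 3)
  sim <- simulate_volume(lat, dose = 0, seed = 4)
  profile <- apply(sim$volume$green, 3, mean)
  ac <- stats::acf(profile, lag.max = length(profile) - 1, plot = FALSE)$acf[, 1, 1]
  # first positive-lag local maximum of the autocorrelation sits at the
  # layer spacing (in voxels)
  lag_expect <- spec$layer_spacing / sim$volume$voxel_size[3]
  local_max <- which(diff(sign(diff(ac))) == -2) + 1
  expect_true(any(abs(local_max - 1 - lag_expect) <= 0.1 * lag_expect))
})

test_that("well-scan grids have the documented shape and monotone response", {
  doses <- c(0, 10, 20, 50, 100, 200)
  scan <- simulate_wellscan(doses, hill_params(25, 1.2), seed = 5)
  # 4 wells x 36 points per dose
  expect_identical(nrow(scan), length(doses) * 4L * 36L)
  counts <- dplyr::count(scan, dose_um)
  expect_true(all(counts$n == 144L))

  # noiseless single dose: all in-framework points identical
  s1 <- simulate_wellscan(10, hill_params(25, 1.2),
                          noise = list(gauss_sd = 0), seed = 5)
  infw <- s1[s1$in_framework, ]
  expect_identical(length(unique(infw$fi_red)), 1L)
  expect_identical(sum(!s1$in_framework), 4L * 4L)  # the four grid corners

  # monotone dose -> monotone mean red/blue ratio
  ratio <- scan |>
    dplyr::filter(in_framework) |>
    dplyr::group_by(dose_um) |>
    dplyr::summarise(r = mean(fi_red / pmax(fi_blue, 1)), .groups = "drop") |>
    dplyr::arrange(dose_um)
  expect_true(all(diff(ratio$r) > 0))
})

test_that("histology generator hits its target correlation", {
  # rho = 1: affinely identical channels
  h1 <- simulate_histology(1, 1000, seed = 8)
  expect_equal(cor(h1$red, h1$blue), 1, tolerance = 1e-12)

  # rho = 0 at n = 1e5: |R| below the CLT bound
  h0 <- simulate_histology(0, 1e5, seed = 9)
  expect_lt(abs(cor(h0$red, h0$blue)), 0.01)

  # strongly correlated case near the generator setting
  h9 <- simulate_histology(0.933, 1e5, seed = 10)
  expect_equal(cor(h9$red, h9$blue), 0.933, tolerance = 0.006)

  expect_error(simulate_histology(1.2, 10), "\\[-1, 1\\]")
})

test_that("per-spheroid viability draws follow the Hill curve", {
  hill <- hill_params(18.92, 2.807)
  v <- simulate_spheroid_viabilities(c(0, 10, 20, 50, 100, 200), hill,
                                     n_per_dose = 400, noise_sd = 0.05,
                                     seed = 11)
  means <- v |>
    dplyr::group_by(dose_um) |>
    dplyr::summarise(m = mean(viability), .groups = "drop")
  expected <- hill_response(means$dose_um, hill)
  expect_true(all(abs(means$m - expected) < 4 * 0.05 / sqrt(400)))
})
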