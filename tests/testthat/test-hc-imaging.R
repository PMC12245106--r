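# High-content pipeline: void detection, OR-gate segmentation, viability
# scoring, diameter measurement, lattice metrics. The primary test surface
# is closure against the generator's ground truth.

test_that("void detection recovers lattice centres and rejects flat images", {
  sim <- make_small_sim(noise = list(gauss_sd = 0, poisson_gain = 0))
  rois <- detect_voids(sim$volume, 250)
  expect_identical(nrow(rois), nrow(sim$lattice))
  m <- match_truth(rois, sim$truth, x = "x", y = "y")
  err <- sqrt((rois$x - sim$truth$x[m])^2 + (rois$y - sim$truth$y[m])^2 +
                (rois$z - sim$truth$z[m])^2)
  # within one coarse detection voxel of ground truth
  expect_lt(max(err), 3 * sim$volume$voxel_size[1])

  # solid scaffold: no voids
  flat <- volume_image(array(3000, c(24, 24, 24)), array(0, c(24, 24, 24)),
                       array(0, c(24, 24, 24)), voxel_size = 5)
  expect_warning(r0 <- detect_voids(flat, 60), "uniform|no void")
  expect_identical(nrow(r0), 0L)
})

test_that("void detection stays precise at default noise", {
  lat <- build_void_lattice(lattice_spec(250, 2150), seed = 21)
  expect_gte(nrow(lat), 50)
  sim <- simulate_volume(lat, dose = 20, seed = 22)
  rois <- detect_voids(sim$volume, 250)
  dd <- as.matrix(dist(rbind(as.matrix(rois[, c("x", "y", "z")]),
                             as.matrix(lat[, c("x", "y", "z")]))))
  cross <- dd[seq_len(nrow(rois)), nrow(rois) + seq_len(nrow(lat)), drop = FALSE]
  tol <- 125  # expected_diameter / 2
  recall <- mean(apply(cross, 2, min) < tol)
  precision <- mean(apply(cross, 1, min) < tol)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("segmentation is an OR gate, independent of live/dead split", {
  hill <- hill_params(20, 2)
  base <- list(diam_mean = 180, diam_sd = 0,
               noise = list(gauss_sd = 0, poisson_gain = 0))
  sim_live <- do.call(make_small_sim, c(list(dose = 0, hill = hill), base))
  sim_half <- do.call(make_small_sim, c(list(dose = 20, hill = hill), base))
  roi <- detect_voids(sim_live$volume, 250)[1, ]

  seg_live <- segment_spheroid(sim_live$volume, roi)
  seg_half <- segment_spheroid(sim_half$volume, roi)
  expect_identical(seg_live$mask, seg_half$mask)

  # mask volume ~ sphere volume within 5%
  vol_meas <- sum(seg_live$mask) * prod(sim_live$volume$voxel_size)
  vol_true <- 4 / 3 * pi * (180 / 2)^3
  expect_equal(vol_meas, vol_true, tolerance = 0.05)

  # an empty void is flagged, not thrown
  empty <- make_small_sim(n_spheroids = 3,
                          noise = list(gauss_sd = 0, poisson_gain = 0))
  rois <- detect_voids(empty$volume, 250)
  occupied <- match_truth(rois, empty$truth, x = "x", y = "y")
  d2 <- sqrt((rois$x - empty$truth$x[occupied])^2 +
               (rois$y - empty$truth$y[occupied])^2)
  empty_roi <- rois[which.max(d2), ]
  seg_empty <- segment_spheroid(empty$volume, empty_roi)
  expect_identical(seg_empty$flag, "no spheroid")
})

test_that("viability scoring matches the realised dead fraction", {
  # analytic cases on a hand-built mask
  mask <- array(TRUE, c(5, 5, 5))
  expect_equal(score_viability(array(0, c(5, 5, 5)), mask), 1)
  expect_equal(score_viability(array(3000, c(5, 5, 5)), mask), 0)
  expect_warning(v <- score_viability(array(0, c(5, 5, 5)),
                                      array(FALSE, c(5, 5, 5))), "empty")
  expect_true(is.na(v))

  # binomial closure at ~30% dead, noiseless
  hill <- hill_params(10, 1)         # viability 0.7 at dose 30/7
  dose <- 10 * (0.3 / 0.7)           # solve hill for viability 0.7
  sim <- make_small_sim(dose = dose, hill = hill,
                        noise = list(gauss_sd = 0, poisson_gain = 0))
  res <- process_volume(sim$volume, 250)
  m <- match_truth(res$records, sim$truth)
  expect_true(all(abs(res$records$viability -
                        (1 - sim$truth$dead_fraction[m])) < 0.02))
  expect_true(all(abs(res$records$viability - 0.7) < 0.05))
})

test_that("diameter is the maximal equivalent-circle diameter over z", {
  vox <- c(5, 5, 5)
  mk_ellipsoid <- function(axes, n = 48) {
    ctr <- n / 2 * 5
    xs <- (seq_len(n) - 0.5) * 5
    arr <- array(0, c(n, n, n))
    for (k in seq_len(n)) {
      inz <- ((xs[k] - ctr) / (axes[3] / 2))^2
      if (inz > 1) next
      sl <- outer(((xs - ctr) / (axes[1] / 2))^2,
                  ((xs - ctr) / (axes[2] / 2))^2, `+`) + inz <= 1
      arr[, , k] <- sl
    }
    arr > 0
  }
  # digital sphere of 180 um: equator recovered within a voxel pitch
  expect_equal(measure_spheroid_diameter(mk_ellipsoid(c(180, 180, 180)), vox),
               180, tolerance = 5 / 180)
  # oblate ellipsoid (200, 200, 100): reports the 200 um equator
  expect_equal(measure_spheroid_diameter(mk_ellipsoid(c(200, 200, 100)), vox),
               200, tolerance = 5 / 200)
  # degenerate single voxel
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(measure_spheroid_diameter(single, vox), 2 * sqrt(25 / pi))
  expect_error(measure_spheroid_diameter(array(FALSE, c(2, 2, 2)), vox), "empty")
})

test_that("full pipeline closes on ground truth at default noise", {
  sim <- make_small_sim(dose = 20, seed = 77)
  res <- process_volume(sim$volume, 250)
  ok <- res$records[res$records$flags == "ok", ]
  expect_identical(nrow(ok), nrow(sim$truth))
  m <- match_truth(ok, sim$truth)
  viab_err <- abs(ok$viability - (1 - sim$truth$dead_fraction[m]))
  expect_lte(mean(viab_err), 0.05)
  diam_err <- abs(ok$diameter_um - sim$truth$diameter_um[m])
  expect_lt(max(diam_err), 2 * 5)  # two voxels

  # circle map carries one entry per scored spheroid and round-trips
  expect_identical(nrow(res$circle_map), nrow(ok))
  expect_true(all(res$circle_map$viability >= 0 & res$circle_map$viability <= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(res$circle_map), path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  for (col in names(res$circle_map)) {
    expect_equal(back[[col]], res$circle_map[[col]], tolerance = 1e-12)
  }
})

test_that("mean viability is non-increasing along a dose series", {
  doses <- c(0, 20, 50, 200)
  mv <- vapply(seq_along(doses), function(i) {
    sim <- make_small_sim(dose = doses[i], seed = 30)
    res <- process_volume(sim$volume, 250)
    mean(res$records$viability[res$records$flags == "ok"])
  }, numeric(1))
  expect_true(all(diff(mv) <= 0))
})

test_that("lattice metrics recover pitch, spread, and the Jensen gap", {
  # perfect lattice at pitch = r: Di/R exactly 1, zero spread
  lat <- build_void_lattice(lattice_spec(250, 1300), seed = 1)
  met <- hcp_lattice_metrics(lat[, c("x", "y")], r = 250)
  expect_equal(met$summary$di_over_r_mean, 1, tolerance = 1e-12)
  expect_equal(met$summary$di_over_r_sd, 0, tolerance = 1e-12)

  # lattice generated at Di/R = 0.932 recovers the generator setting
  met2 <- hcp_lattice_metrics(lat[, c("x", "y")] * 0.932, r = 250)
  expect_equal(met2$summary$di_over_r_mean, 0.932, tolerance = 0.005)

  # jittered lattice: mean per-pair Rcap differs from Rcap of the mean Di
  # (brute-force over pairs), since the cap transform is concave there
  latj <- build_void_lattice(lattice_spec(250, 1300), jitter_sd = 6, seed = 5)
  metj <- hcp_lattice_metrics(latj[, c("x", "y")] * 0.95, r = 250)
  brute <- mean(sqrt(250^2 - metj$pairs$di[metj$pairs$di <= 250]^2))
  expect_equal(metj$summary$rcap_mean, brute, tolerance = 1e-9)
  expect_gt(abs(metj$summary$rcap_mean - metj$summary$rcap_of_mean_di), 0.5)

  expect_error(hcp_lattice_metrics(matrix(1, 1, 2), 250), "at least 2")
})
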