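# Synthetic data with the statistical structure the analyses assume: HCP void
# lattices, three-channel two-photon-like volumes (scaffold / live / dead)
# with Hill-governed per-voxel death, plate-reader well-scan grids, histology
# pixel pairs, and per-spheroid viability draws. Every generator is
# deterministic given (parameters, seed) and returns its ground truth, so the
# analysis pipeline can be tested by closure: generate -> analyse -> compare.

#' Hill dose-response parameters
#'
#' @param ic50 Half-maximal dose, uM (> 0).
#' @param n Hill coefficient (> 0); cooperativity/steepness.
#' @param top Response at dose 0 (default 1).
#' @param bottom Response as dose -> Inf (default 0); must be < `top`.
#' @return A one-row tibble.
#' @export
hill_params <- function(ic50, n, top = 1, bottom = 0) {
  check_number(ic50, "ic50", positive = TRUE)
  check_number(n, "n", positive = TRUE)
  check_number(top, "top")
  check_number(bottom, "bottom")
  if (top <= bottom) abort_input("`top` must exceed `bottom`")
  tibble(ic50 = ic50, n = n, top = top, bottom = bottom)
}

#' Build a (possibly jittered) HCP void lattice
#'
#' Places hexagonal-lattice centres layer by layer (alternating A/B in-plane
#' registration, layer k at z = (k-1) * layer_spacing) inside the container
#' circle, then adds isotropic Gaussian positional jitter.
#'
#' @param spec A [lattice_spec()].
#' @param jitter_sd Positional jitter SD in um (applied per axis).
#' @param seed Integer seed; the lattice is bit-reproducible given it.
#' @return A tibble with columns `void_id`, `x`, `y`, `z` (um, z up through
#'   layers), `layer`. The spec and seed travel as attributes.
#' @export
build_void_lattice <- function(spec, jitter_sd = 0, seed = 1L) {
  spec <- as_tibble(spec)
  check_number(jitter_sd, "jitter_sd", nonneg = TRUE)
  rmax <- (spec$container_diameter - spec$void_diameter) / 2
  b_off <- c(spec$pitch / 2, spec$pitch / (2 * sqrt(3)))
  layers <- vector("list", spec$layers)
  for (k in seq_len(spec$layers)) {
    off <- if (k %% 2L == 1L) c(0, 0) else b_off
    ctr <- if (rmax < 0) matrix(numeric(0), ncol = 2) else hex_centers(spec$pitch, rmax, off)
    if (nrow(ctr) == 0 && k == 1L) warning("container too small for a single void")
    if (nrow(ctr)) {
      layers[[k]] <- tibble(
        x = ctr[, 1], y = ctr[, 2],
        z = (k - 1) * spec$layer_spacing, layer = k
      )
    }
  }
  out <- bind_rows(layers)
  if (nrow(out)) {
    set.seed(seed)
    out$x <- out$x + rnorm(nrow(out), 0, jitter_sd)
    out$y <- out$y + rnorm(nrow(out), 0, jitter_sd)
    out$z <- out$z + rnorm(nrow(out), 0, jitter_sd)
  }
  out <- mutate(out, void_id = seq_len(nrow(out)), .before = 1)
  attr(out, "spec") <- spec
  attr(out, "jitter_sd") <- jitter_sd
  attr(out, "seed") <- seed
  out
}

#' Volume image constructor
#'
#' A three-channel 3D intensity stack. Channels: `green` = scaffold label,
#' `blue` = live-cell tracker, `red` = dead-cell stain. Arrays are indexed
#' (x, y, z); voxel (i, j, k) is centred at `origin + (c(i,j,k) - 0.5) *
#' voxel_size` in um.
#'
#' @param green,blue,red Nonnegative numeric arrays of identical dimension.
#' @param voxel_size Length-3 voxel size (dx, dy, dz) in um.
#' @param origin Physical coordinate of the corner of voxel (1,1,1), um.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(green, blue, red, voxel_size, origin = c(0, 0, 0)) {
  if (!identical(dim(green), dim(blue)) || !identical(dim(green), dim(red))) {
    abort_input("all channels must share one dimension")
  }
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  if (any(voxel_size <= 0)) abort_input("voxel_size must be positive")
  structure(
    list(green = green, blue = blue, red = red,
         voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, voxel %.3g x %.3g x %.3g um\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

# Burn a spherical region into linear indices of a volume grid.
sphere_indices <- function(dims, voxel, origin, center, radius) {
  lo <- pmax(1L, floor((center - radius - origin) / voxel) - 1L)
  hi <- pmin(dims, ceiling((center + radius - origin) / voxel) + 1L)
  if (any(lo > hi)) return(integer(0))
  xs <- origin[1] + (lo[1]:hi[1] - 0.5) * voxel[1]
  ys <- origin[2] + (lo[2]:hi[2] - 0.5) * voxel[2]
  zs <- origin[3] + (lo[3]:hi[3] - 0.5) * voxel[3]
  dx2 <- (xs - center[1])^2
  dy2 <- (ys - center[2])^2
  dz2 <- (zs - center[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  ii <- which(inside, arr.ind = TRUE)
  if (!nrow(ii)) return(integer(0))
  (lo[1] + ii[, 1] - 1L) +
    (lo[2] + ii[, 2] - 2L) * dims[1] +
    (lo[3] + ii[, 3] - 2L) * dims[1] * dims[2]
}

# Burn a finite cylinder (axis p1 -> p2, given radius) into linear indices.
cylinder_indices <- function(dims, voxel, origin, p1, p2, radius) {
  lo <- pmax(1L, floor((pmin(p1, p2) - radius - origin) / voxel) - 1L)
  hi <- pmin(dims, ceiling((pmax(p1, p2) + radius - origin) / voxel) + 1L)
  if (any(lo > hi)) return(integer(0))
  xs <- origin[1] + (lo[1]:hi[1] - 0.5) * voxel[1]
  ys <- origin[2] + (lo[2]:hi[2] - 0.5) * voxel[2]
  zs <- origin[3] + (lo[3]:hi[3] - 0.5) * voxel[3]
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  ax <- p2 - p1
  len2 <- sum(ax^2)
  px <- g$x - p1[1]; py <- g$y - p1[2]; pz <- g$z - p1[3]
  t <- (px * ax[1] + py * ax[2] + pz * ax[3]) / len2
  d2 <- (px - t * ax[1])^2 + (py - t * ax[2])^2 + (pz - t * ax[3])^2
  inside <- t >= 0 & t <= 1 & d2 <= radius^2
  if (!any(inside)) return(integer(0))
  ii <- which(array(inside, dim = c(length(xs), length(ys), length(zs))), arr.ind = TRUE)
  (lo[1] + ii[, 1] - 1L) +
    (lo[2] + ii[, 2] - 2L) * dims[1] +
    (lo[3] + ii[, 3] - 2L) * dims[1] * dims[2]
}

#' Simulate a three-channel spheroid-array volume
#'
#' Renders a scaffold (green) plateau with dark spherical voids at the
#' lattice positions and dark cylindrical channels (diameter `cap_diameter`)
#' between neighbouring voids; drops one spheroid of drawn diameter into each
#' occupied void; labels each spheroid voxel dead with probability
#' `1 - hill_response(dose)/top` (red) and live otherwise (blue); then adds
#' Poisson shot noise and additive Gaussian read noise to every channel.
#' Intensities are 12-bit-like (plateau ~3000 on a 0-4095 scale) so that the
#' conventional ">2000 a.u." scaffold gate is meaningful.
#'
#' @param lattice A [build_void_lattice()] result.
#' @param diam_mean,diam_sd Spheroid diameter distribution, um (normal).
#' @param dose Drug dose in uM applied to the whole volume.
#' @param hill A [hill_params()] row governing expected viability vs dose.
#' @param cap_um Channel (cap) diameter in um; 0 suppresses channels.
#' @param n_spheroids Number of voids to occupy (closest to the container
#'   centre first); `NULL` occupies all voids.
#' @param noise List with `gauss_sd` (additive SD, a.u.) and `poisson_gain`
#'   (0 disables shot noise). Defaults `list(gauss_sd = 50, poisson_gain = 1)`.
#' @param voxel_size Voxel edge(s) in um (default 5).
#' @param seed Integer seed.
#' @param intensity Signal plateau, a.u. (default 3000).
#' @return A list with `volume` (a [volume_image()]) and `truth`, a tibble of
#'   one row per spheroid: void centre, `diameter_um`, expected `viability`,
#'   realised `dead_fraction`, `dose_um`; generator settings as attributes.
#' @export
simulate_volume <- function(lattice, diam_mean = 179.2, diam_sd = 9.76,
                            dose = 0, hill = hill_params(18.92, 2.807),
                            cap_um = 45, n_spheroids = NULL,
                            noise = list(gauss_sd = 50, poisson_gain = 1),
                            voxel_size = 5, seed = 1L, intensity = 3000) {
  spec <- attr(lattice, "spec")
  if (is.null(spec)) abort_input("`lattice` must come from build_void_lattice()")
  if (diam_mean > spec$void_diameter) {
    abort_input("`diam_mean` exceeds the void diameter")
  }
  voxel <- rep(as.numeric(voxel_size), length.out = 3L)
  margin <- spec$void_diameter * 0.12
  r_void <- spec$void_diameter / 2
  origin <- c(min(lattice$x) - r_void - margin,
              min(lattice$y) - r_void - margin,
              min(lattice$z) - r_void - margin)
  top_corner <- c(max(lattice$x) + r_void + margin,
                  max(lattice$y) + r_void + margin,
                  max(lattice$z) + r_void + margin)
  dims <- pmax(ceiling((top_corner - origin) / voxel), 4L)
  dims <- as.integer(dims)

  green <- array(intensity, dim = dims)
  blue <- array(0, dim = dims)
  red <- array(0, dim = dims)
  low <- intensity / 10

  centers <- as.matrix(lattice[, c("x", "y", "z")])
  for (i in seq_len(nrow(centers))) {
    idx <- sphere_indices(dims, voxel, origin, centers[i, ], r_void)
    green[idx] <- low
  }
  if (cap_um > 0 && nrow(centers) > 1) {
    dmat <- as.matrix(dist(centers))
    cutoff <- 1.2 * spec$pitch
    pairs <- which(dmat > 0 & dmat <= cutoff, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    for (p in seq_len(nrow(pairs))) {
      idx <- cylinder_indices(dims, voxel, origin,
                              centers[pairs[p, 1], ], centers[pairs[p, 2], ],
                              cap_um / 2)
      green[idx] <- low
    }
  }

  # occupy voids (nearest the centroid first when capped)
  occ <- seq_len(nrow(lattice))
  if (!is.null(n_spheroids)) {
    if (n_spheroids > nrow(lattice)) abort_input("more spheroids requested than voids")
    d0 <- sqrt((lattice$x - mean(lattice$x))^2 + (lattice$y - mean(lattice$y))^2)
    occ <- order(d0)[seq_len(n_spheroids)]
  }

  set.seed(seed)
  viab <- hill_response(dose, hill) / hill$top
  truth <- vector("list", length(occ))
  for (j in seq_along(occ)) {
    i <- occ[j]
    diam <- min(rnorm(1, diam_mean, diam_sd), spec$void_diameter - 2 * voxel[1])
    idx <- sphere_indices(dims, voxel, origin, centers[i, ], diam / 2)
    dead <- runif(length(idx)) > viab
    red[idx[dead]] <- intensity
    blue[idx[!dead]] <- intensity
    truth[[j]] <- tibble(
      void_id = lattice$void_id[i],
      x = lattice$x[i], y = lattice$y[i], z = lattice$z[i],
      diameter_um = diam,
      viability = viab,
      dead_fraction = mean(dead),
      dose_um = dose
    )
  }
  truth <- bind_rows(truth)

  gauss_sd <- noise$gauss_sd %||% 0
  pois_gain <- noise$poisson_gain %||% 0
  add_noise <- function(a) {
    if (pois_gain > 0) {
      a <- array(pois_gain * rpois(length(a), a / pois_gain), dim = dim(a))
    }
    if (gauss_sd > 0) a <- a + array(rnorm(length(a), 0, gauss_sd), dim = dim(a))
    a[a < 0] <- 0
    a
  }
  green <- add_noise(green); blue <- add_noise(blue); red <- add_noise(red)

  vol <- volume_image(green, blue, red, voxel, origin)
  attr(truth, "hill") <- hill
  attr(truth, "noise") <- list(gauss_sd = gauss_sd, poisson_gain = pois_gain)
  attr(truth, "seed") <- seed
  attr(truth, "cap_um") <- cap_um
  list(volume = vol, truth = truth)
}

#' Simulate a plate-reader well-scan table
#'
#' Emulates the 6x6 filled-circle well-scan mode: each well yields a grid of
#' `points_per_well` read points; points whose grid position falls outside
#' the circular scaffold punch report a scaffold (green) intensity below the
#' gate. In-framework points report `fi_blue` proportional to the live volume
#' fraction and `fi_red` to the dead fraction, so `fi_red / fi_blue` encodes
#' the local dead/live volume ratio implied by the Hill ground truth.
#'
#' @param doses Dose series, uM (nonempty).
#' @param hill A [hill_params()] row (viability vs dose; `top` at dose 0).
#' @param points_per_well Read points per well; must be a perfect square
#'   (default 36, the 6x6 grid).
#' @param wells_per_dose Replicate wells per dose (default 4).
#' @param noise List with `gauss_sd` additive intensity noise (default 50).
#' @param framework_radius Radius of the scaffold punch in units of the
#'   half-span of the scan grid (default 1.2: the four grid corners fall
#'   outside, 32/36 points in-framework).
#' @param seed Integer seed.
#' @param intensity Full-scale signal, a.u. (default 3000).
#' @return A tibble with columns `well`, `dose_um`, `point`, `fi_green`,
#'   `fi_blue`, `fi_red`, plus ground-truth columns `in_framework` and
#'   `true_viability`.
#' @export
simulate_wellscan <- function(doses, hill = hill_params(25.69, 1.310),
                              points_per_well = 36L, wells_per_dose = 4L,
                              noise = list(gauss_sd = 50),
                              framework_radius = 1.2, seed = 1L,
                              intensity = 3000) {
  if (!length(doses)) abort_input("`doses` must be nonempty")
  side <- sqrt(points_per_well)
  if (side != round(side)) abort_input("`points_per_well` must be a perfect square")
  side <- as.integer(side)
  g <- (2 * seq_len(side) - side - 1) / (side - 1)  # grid coords in [-1, 1]
  grid <- expand.grid(gx = g, gy = g)
  in_fw <- grid$gx^2 + grid$gy^2 <= framework_radius^2
  gauss_sd <- noise$gauss_sd %||% 0

  set.seed(seed)
  rows <- vector("list", length(doses) * wells_per_dose)
  well_i <- 0L
  for (d in doses) {
    v <- hill_response(d, hill) / hill$top
    for (w in seq_len(wells_per_dose)) {
      well_i <- well_i + 1L
      fi_green <- ifelse(in_fw, intensity, intensity / 6)
      fi_blue <- ifelse(in_fw, intensity * v, intensity / 30)
      fi_red <- ifelse(in_fw, intensity * (1 - v), intensity / 30)
      if (gauss_sd > 0) {
        np <- length(fi_green)
        fi_green <- fi_green + rnorm(np, 0, gauss_sd)
        fi_blue <- fi_blue + rnorm(np, 0, gauss_sd)
        fi_red <- fi_red + rnorm(np, 0, gauss_sd)
      }
      rows[[well_i]] <- tibble(
        well = sprintf("W%03d", well_i),
        dose_um = d,
        point = seq_len(points_per_well),
        fi_green = pmax(fi_green, 0),
        fi_blue = pmax(fi_blue, 0),
        fi_red = pmax(fi_red, 0),
        in_framework = in_fw,
        true_viability = v
      )
    }
  }
  out <- bind_rows(rows)
  attr(out, "hill") <- hill
  attr(out, "seed") <- seed
  out
}

#' Simulate correlated two-channel histology pixels
#'
#' Draws `n_pixels` pixel pairs from a bivariate normal with the requested
#' Pearson correlation (the sample correlation converges to `rho` as n grows).
#'
#' @param rho Target correlation in \[-1, 1\].
#' @param n_pixels Number of pixels.
#' @param seed Integer seed.
#' @param mean,sd Marginal intensity mean and SD (shared by both channels).
#' @return A tibble with columns `red`, `blue`.
#' @export
simulate_histology <- function(rho, n_pixels = 1e5, seed = 1L,
                               mean = 120, sd = 30) {
  check_number(rho, "rho")
  if (abs(rho) > 1) abort_input("`rho` must lie in [-1, 1]")
  set.seed(seed)
  z1 <- rnorm(n_pixels)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_pixels)
  tibble(red = mean + sd * z1, blue = mean + sd * z2)
}

#' Simulate per-spheroid viability measurements over a dose series
#'
#' Draws `n_per_dose` spheroid viabilities per dose as the Hill-expected
#' viability plus Gaussian measurement noise. This is the compact generator
#' behind the high-content parameter-recovery experiments, where the full
#' volumetric pipeline would be redundant.
#'
#' @param doses Dose series, uM.
#' @param hill A [hill_params()] row.
#' @param n_per_dose Spheroids per dose (default 300).
#' @param noise_sd Measurement noise SD on viability (default 0.05).
#' @param seed Integer seed.
#' @return A tibble with columns `dose_um`, `viability`.
#' @export
simulate_spheroid_viabilities <- function(doses, hill, n_per_dose = 300L,
                                          noise_sd = 0.05, seed = 1L) {
  if (!length(doses)) abort_input("`doses` must be nonempty")
  set.seed(seed)
  bind_rows(lapply(doses, function(d) {
    tibble(
      dose_um = d,
      viability = hill_response(d, hill) + rnorm(n_per_dose, 0, noise_sd)
    )
  }))
}
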