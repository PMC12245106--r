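# Automated high-content image processing: find the dark voids in the
# scaffold (green) channel, delineate each spheroid from the OR-merged
# live/dead channels, score per-voxel viability, measure diameters, and
# summarise everything as a per-spheroid table plus a circle map.

# Convert a linear voxel index to (i, j, k).
vox_ijk <- function(lin, dims) {
  k <- (lin - 1L) %/% (dims[1] * dims[2]) + 1L
  rem <- (lin - 1L) %% (dims[1] * dims[2])
  j <- rem %/% dims[1] + 1L
  i <- rem %% dims[1] + 1L
  cbind(i, j, k)
}

#' Detect void centres in the scaffold channel
#'
#' Voids are dark, quasi-periodic spheres of known diameter in the green
#' channel, so detection is smoothed-minimum peak finding rather than
#' Hough-style sphere search: the channel is (optionally) block-downsampled,
#' Gaussian-smoothed, and local minima within a box of roughly one void
#' radius are kept if they are darker than the Otsu split between scaffold
#' and void intensities, then greedily deduplicated at half the expected
#' diameter.
#'
#' @param volume A [volume_image()], or a bare 3D green-channel array (then
#'   `voxel_size` must be given).
#' @param expected_diameter Void diameter in um (>= 4 voxels).
#' @param voxel_size Voxel size in um (taken from `volume` when omitted).
#' @return A tibble of ROIs: `roi_id`, `x`, `y`, `z` (um), `radius` (um,
#'   `expected_diameter / 2`). Empty (with a warning) for a uniform image.
#' @export
detect_voids <- function(volume, expected_diameter, voxel_size = NULL) {
  if (inherits(volume, "volume_image")) {
    green <- volume$green
    voxel <- volume$voxel_size
    origin <- volume$origin
  } else {
    green <- volume
    if (is.null(voxel_size)) abort_input("`voxel_size` required for a bare array")
    voxel <- rep(as.numeric(voxel_size), length.out = 3L)
    origin <- c(0, 0, 0)
  }
  d_vox <- expected_diameter / voxel[1]
  if (d_vox < 4) abort_input("`expected_diameter` must span at least 4 voxels")
  if (diff(range(green)) == 0) {
    warning("uniform image: no voids detected")
    return(tibble(roi_id = integer(), x = numeric(), y = numeric(),
                  z = numeric(), radius = numeric()))
  }

  # stride-subsample so a void spans ~16 voxels: the Gaussian smoothing that
  # follows absorbs voxel noise, and centre precision of a few (coarse)
  # voxels is ample against the expected_diameter/2 dedup/matching scale
  f <- max(1L, floor(d_vox / 16))
  if (f > 1L) {
    dims <- dim(green)
    g <- green[seq(1L, dims[1], by = f),
               seq(1L, dims[2], by = f),
               seq(1L, dims[3], by = f), drop = FALSE]
  } else {
    g <- green
  }
  voxel_ds <- voxel * f
  d_ds <- expected_diameter / voxel_ds[1]

  sm <- gaussian_smooth3d(g, d_ds / 10)
  r_min <- max(1L, floor(d_ds * 0.35))
  eroded <- min_filter3d(sm, r_min)
  thr <- otsu_threshold(sm)
  cand <- which(sm <= eroded + 1e-9 & sm < thr)
  if (!length(cand)) {
    warning("no void-like minima found")
    return(tibble(roi_id = integer(), x = numeric(), y = numeric(),
                  z = numeric(), radius = numeric()))
  }
  ijk <- vox_ijk(cand, dim(g))
  # coarse voxel m sits at fine voxel 1 + (m-1) f; report its centre
  pos <- sweep(sweep((ijk - 1) * f + 0.5, 2, voxel, `*`), 2, origin, `+`)
  o <- order(sm[cand])
  pos <- pos[o, , drop = FALSE]

  # greedy dedup: keep darkest minima at least expected_diameter/2 apart
  kept <- matrix(numeric(0), ncol = 3)
  min_sep2 <- (expected_diameter / 2)^2
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    if (!nrow(kept) ||
        min(colSums((t(kept) - p)^2)) > min_sep2) {
      kept <- rbind(kept, p)
    }
  }
  tibble(
    roi_id = seq_len(nrow(kept)),
    x = kept[, 1], y = kept[, 2], z = kept[, 3],
    radius = expected_diameter / 2
  )
}

# Extract the subvolume of half-width `r_um` around a physical point.
# Returns channel subarrays plus the voxel offset (0-based) of the box.
extract_box <- function(volume, center, r_um) {
  dims <- dim(volume$green)
  voxel <- volume$voxel_size
  lo <- pmax(1L, floor((center - r_um - volume$origin) / voxel))
  hi <- pmin(dims, ceiling((center + r_um - volume$origin) / voxel))
  list(
    green = volume$green[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    blue = volume$blue[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    red = volume$red[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
    lo = lo
  )
}

#' Segment the spheroid within one ROI
#'
#' Merges the red and blue channels with a voxelwise OR (their maximum),
#' thresholds the merged subvolume inside the spherical ROI, and keeps the
#' largest 6-connected component. The contour is therefore independent of
#' how the signal splits between live and dead — a half-dead spheroid yields
#' the same mask as an all-live one.
#'
#' @param volume A [volume_image()].
#' @param roi One ROI row from [detect_voids()] (`x`, `y`, `z`, `radius`).
#' @param threshold_method `"otsu"` (default) or a fixed numeric threshold.
#' @param min_voxels Masks smaller than this are flagged `"no spheroid"`
#'   (default 33, a sphere of ~4 voxel diameter).
#' @return A list: `mask` (logical subarray), `offset` (1-based voxel index
#'   of the subarray corner), `threshold`, `flag` (`"ok"` or `"no spheroid"`).
#' @export
segment_spheroid <- function(volume, roi, threshold_method = "otsu",
                             min_voxels = 33L) {
  center <- c(roi$x, roi$y, roi$z)
  box <- extract_box(volume, center, roi$radius + volume$voxel_size[1])
  merged <- pmax(box$red, box$blue)
  dim(merged) <- dim(box$red)
  thr <- resolve_threshold(merged, threshold_method)
  if (diff(range(merged)) == 0) thr <- merged[1] / 2  # constant subvolume
  mask <- merged > thr

  # restrict to the spherical ROI
  dims <- dim(mask)
  voxel <- volume$voxel_size
  xs <- volume$origin[1] + (box$lo[1] + seq_len(dims[1]) - 1.5) * voxel[1]
  ys <- volume$origin[2] + (box$lo[2] + seq_len(dims[2]) - 1.5) * voxel[2]
  zs <- volume$origin[3] + (box$lo[3] + seq_len(dims[3]) - 1.5) * voxel[3]
  inside <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
                  (zs - center[3])^2, `+`) <= (roi$radius + voxel[1])^2
  mask <- mask & inside

  if (sum(mask) >= min_voxels) mask <- largest_component(mask)
  flag <- if (sum(mask) < min_voxels) "no spheroid" else "ok"
  list(mask = mask, offset = box$lo, threshold = thr, flag = flag)
}

#' Score viability from the red (dead) channel
#'
#' Thresholds the red channel and counts dead voxels within the contour
#' mask: `viability = 1 - dead / contour`. In the composed pipeline the
#' threshold found on the OR-merged channel is reused here, which keeps the
#' dead call stable when a spheroid contains no (or only) dead voxels.
#'
#' @param red Red-channel subarray matching `mask`.
#' @param mask Logical contour mask (nonempty).
#' @param threshold_method `"otsu"` (computed on red within the mask) or a
#'   fixed numeric threshold.
#' @return Viability in \[0, 1\]; `NA` with a warning for an empty mask.
#' @export
score_viability <- function(red, mask, threshold_method = "otsu") {
  if (!any(mask)) {
    warning("empty mask: viability undefined")
    return(NA_real_)
  }
  vals <- red[mask]
  thr <- if (is.numeric(threshold_method)) {
    threshold_method
  } else if (diff(range(vals)) == 0) {
    vals[1] / 2
  } else {
    otsu_threshold(vals)
  }
  1 - sum(vals > thr) / length(vals)
}

#' Spheroid diameter from a contour mask
#'
#' For each z-slice of the mask the equivalent-circle diameter
#' `2 * sqrt(area / pi)` is computed from the slice area; the maximum over z
#' is the recorded spheroid diameter (the equatorial slice of a sphere).
#'
#' @param mask Logical 3D mask (nonempty).
#' @param voxel_size Length-3 voxel size in um.
#' @return Diameter in um.
#' @export
measure_spheroid_diameter <- function(mask, voxel_size) {
  if (!any(mask)) abort_input("empty mask has no diameter")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3L)
  areas <- apply(mask, 3, sum) * voxel_size[1] * voxel_size[2]
  2 * sqrt(max(areas) / pi)
}

#' Run the full high-content pipeline on a volume
#'
#' Composes [detect_voids()], [segment_spheroid()], [score_viability()] and
#' [measure_spheroid_diameter()] over every detected ROI. Per-ROI failures
#' are recorded in the `flag` column and never abort the run. Viability is
#' scored against the contour threshold found on the OR-merged channel.
#'
#' @param volume A [volume_image()].
#' @param expected_diameter Void diameter in um.
#' @param threshold_method `"otsu"` (default: a single Otsu threshold
#'   computed on the OR-merged channel of the whole volume, so that empty
#'   voids are not segmented against their own noise floor) or a fixed
#'   numeric threshold for the contour segmentation.
#' @return An object of class `hc_result`: a list with `records` (tibble:
#'   `roi_id`, `x_um`, `y_um`, `z_um`, `diameter_um`, `contour_voxels`,
#'   `dead_voxels`, `viability`, `flags`) and `circle_map`
#'   (class `circle_map`; see [circle_map()]).
#' @export
process_volume <- function(volume, expected_diameter,
                           threshold_method = "otsu") {
  if (!inherits(volume, "volume_image")) abort_input("`volume` must be a volume_image")
  rois <- detect_voids(volume, expected_diameter)
  voxel <- volume$voxel_size
  if (identical(threshold_method, "otsu")) {
    # one global contour threshold from the merged channel: the whole-volume
    # histogram is genuinely bimodal (background vs cell signal), whereas an
    # empty void's subvolume is not, and an Otsu split of pure noise marks
    # ~half its voxels as foreground
    stride <- seq(1L, length(volume$red), by = 4L)
    threshold_method <- otsu_threshold(pmax(volume$red[stride], volume$blue[stride]))
  }
  records <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    rec <- tibble(
      roi_id = roi$roi_id, x_um = roi$x, y_um = roi$y, z_um = roi$z,
      diameter_um = NA_real_, contour_voxels = 0L, dead_voxels = 0L,
      viability = NA_real_, flags = "ok"
    )
    seg <- tryCatch(segment_spheroid(volume, roi, threshold_method),
                    error = function(e) NULL)
    if (is.null(seg) || seg$flag != "ok") {
      rec$flags <- if (is.null(seg)) "segmentation error" else seg$flag
      records[[i]] <- rec
      next
    }
    box <- extract_box(volume, c(roi$x, roi$y, roi$z), roi$radius + voxel[1])
    dead <- sum(box$red[seg$mask] > seg$threshold)
    rec$contour_voxels <- sum(seg$mask)
    rec$dead_voxels <- as.integer(dead)
    rec$viability <- 1 - dead / rec$contour_voxels
    rec$diameter_um <- measure_spheroid_diameter(seg$mask, voxel)
    # refine the reported centre to the mask centroid
    ijk <- which(seg$mask, arr.ind = TRUE)
    cen <- unname((colMeans(ijk) + seg$offset - 1.5) * voxel + volume$origin)
    rec$x_um <- cen[1]; rec$y_um <- cen[2]; rec$z_um <- cen[3]
    records[[i]] <- rec
  }
  records <- bind_rows(records)
  structure(
    list(records = records, circle_map = circle_map(records)),
    class = "hc_result"
  )
}

#' @export
print.hc_result <- function(x, ...) {
  ok <- sum(x$records$flags == "ok")
  cat(sprintf("<hc_result> %d ROIs, %d spheroids scored\n", nrow(x$records), ok))
  if (ok) {
    cat(sprintf("  viability: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$records$viability[x$records$flags == "ok"]),
                min(x$records$viability, na.rm = TRUE),
                max(x$records$viability, na.rm = TRUE)))
  }
  invisible(x)
}

#' Circle map of a spheroid record table
#'
#' The 2D screening summary: each spheroid drawn at its (x, y) location,
#' with circle diameter equal to the measured spheroid diameter and colour
#' encoding viability.
#'
#' @param records A record tibble from [process_volume()] (or equivalent with
#'   `x_um`, `y_um`, `diameter_um`, `viability`).
#' @return A tibble of class `circle_map` with columns `x`, `y`, `diameter`,
#'   `viability`, `color` (hex, from a blue-to-red viability scale).
#' @export
circle_map <- function(records) {
  records <- as_tibble(records)
  ok <- records[records$flags %in% "ok", , drop = FALSE]
  ramp <- grDevices::colorRamp(c("#b2182b", "#f7f7f7", "#2166ac"))
  col <- function(v) {
    rgb <- ramp(pmin(pmax(v, 0), 1))
    grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  out <- tibble(
    x = ok$x_um, y = ok$y_um,
    diameter = ok$diameter_um,
    viability = ok$viability,
    color = if (nrow(ok)) col(ok$viability) else character(0)
  )
  class(out) <- c("circle_map", class(out))
  attr(out, "scale") <- "viability 0 (red) -> 1 (blue), diverging at 0.5"
  out
}

#' @rdname circle_map
#' @param object A `circle_map`.
#' @param ... Unused.
#' @export
autoplot.circle_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$diameter,
                                     colour = .data$viability)) +
    ggplot2::scale_colour_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                    high = "#2166ac", midpoint = 0.5,
                                    limits = c(0, 1)) +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "viability",
                  size = "diameter (um)") +
    ggplot2::theme_minimal()
}

#' Lattice metrics from detected 2D centres
#'
#' Recovers the centre-to-centre distance distribution of a (possibly
#' imperfect) hexagonal assembly: every pair closer than `1.3 *` the median
#' nearest-neighbour distance counts as a contact (deduplicated, i < j), the
#' relative distance Di/R is reported per pair, and each pair's cap diameter
#' follows from [cap_diameter()] (pairs with Di > R carry `NA`: no overlap,
#' no channel). Because the cap transform is nonlinear, the mean of per-pair
#' caps differs from the cap of the mean distance; both are reported.
#'
#' @param centers A matrix or data frame of (x, y) centres in um (>= 2 rows).
#' @param r Nominal microgel diameter in um.
#' @return A list: `pairs` (tibble `i`, `j`, `di`, `di_over_r`, `rcap`) and
#'   `summary` (one-row tibble with means/SDs and `rcap_of_mean_di`).
#' @export
hcp_lattice_metrics <- function(centers, r) {
  centers <- as.matrix(as.data.frame(centers)[, 1:2])
  if (nrow(centers) < 2L) abort_input("need at least 2 centres")
  check_number(r, "r", positive = TRUE)
  dmat <- as.matrix(dist(centers))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1, min)
  cutoff <- 1.3 * median(nn)
  pr <- which(dmat <= cutoff, arr.ind = TRUE)
  pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE]
  di <- dmat[pr]
  rcap <- ifelse(di <= r, suppressWarnings(sqrt(pmax(r^2 - di^2, 0))), NA_real_)
  pairs <- tibble(i = pr[, 1], j = pr[, 2], di = di,
                  di_over_r = di / r, rcap = rcap)
  summary <- tibble(
    n_pairs = nrow(pairs),
    di_over_r_mean = mean(pairs$di_over_r),
    di_over_r_sd = sd(pairs$di_over_r),
    rcap_mean = mean(pairs$rcap, na.rm = TRUE),
    rcap_sd = sd(pairs$rcap, na.rm = TRUE),
    rcap_of_mean_di = if (mean(di) <= r) cap_diameter(r, mean(di)) else NA_real_
  )
  list(pairs = pairs, summary = summary)
}
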