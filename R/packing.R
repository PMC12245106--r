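# Packing geometry: how many ~250 um voids fit in a dish layer, and how many
# spheroid-bearing voids a multi-layer HCP scaffold holds. These counts back
# the throughput arithmetic of the platform (thousands of voids per dish
# layer, >1000 per 5 mm well punch).

#' Lattice specification for a void array
#'
#' @param void_diameter Void (microgel) diameter, um.
#' @param container_diameter Inner diameter of the dish/punch, um.
#' @param layers Number of HCP layers (>= 1).
#' @param pitch Lattice pitch, um (defaults to `void_diameter`: touching voids).
#' @param layer_spacing Vertical spacing between layers, um (defaults to
#'   `pitch * sqrt(2/3)`, the HCP value).
#' @param registration `"centered"` (one void at the container centre, rows
#'   along x) or `"best-of-translations"` (maximise the count over a grid of
#'   lattice offsets).
#' @return A one-row tibble carrying the validated specification.
#' @export
lattice_spec <- function(void_diameter, container_diameter, layers = 1L,
                         pitch = void_diameter,
                         layer_spacing = pitch * sqrt(2 / 3),
                         registration = c("centered", "best-of-translations")) {
  registration <- match.arg(registration)
  check_number(void_diameter, "void_diameter", positive = TRUE)
  check_number(container_diameter, "container_diameter", positive = TRUE)
  check_number(pitch, "pitch", positive = TRUE)
  check_number(layer_spacing, "layer_spacing", positive = TRUE)
  if (layers < 1L) abort_input("`layers` must be >= 1")
  tibble(
    void_diameter = void_diameter, container_diameter = container_diameter,
    layers = as.integer(layers), pitch = pitch, layer_spacing = layer_spacing,
    registration = registration
  )
}

# Hexagonal-lattice centres (rows along x) with the given pitch and offset,
# restricted to |c| <= rmax. Layer parity "B" shifts by the in-plane HCP
# offset (pitch/2, pitch/(2 sqrt(3))).
hex_centers <- function(pitch, rmax, offset = c(0, 0)) {
  if (rmax < 0) return(matrix(numeric(0), ncol = 2))
  row_h <- pitch * sqrt(3) / 2
  jmax <- ceiling((rmax + abs(offset[2])) / row_h) + 2L
  imax <- ceiling((rmax + abs(offset[1])) / pitch) + 2L
  out <- vector("list", 2L * jmax + 1L)
  for (j in -jmax:jmax) {
    y <- j * row_h + offset[2]
    x <- (-imax:imax) * pitch + (abs(j) %% 2L) * pitch / 2 + offset[1]
    keep <- x * x + y * y <= rmax * rmax * (1 + 1e-12)
    out[[j + jmax + 1L]] <- cbind(x[keep], rep(y, sum(keep)))
  }
  do.call(rbind, out)
}

#' Count lattice circles fully inside a circular container
#'
#' Enumerates hexagonal-lattice positions (pitch = `spec$pitch`) whose circles
#' of diameter `void_diameter` lie entirely within the container circle, i.e.
#' centres within radius `(container_diameter - void_diameter) / 2`. Under
#' `"centered"` registration one circle sits at the container centre; under
#' `"best-of-translations"` the lattice offset is chosen to maximise the
#' count over a grid of translations spanning one unit cell.
#'
#' @param spec A [lattice_spec()].
#' @param n_offsets Grid resolution per axis for best-of-translations.
#' @return Integer count of circles in a single layer.
#' @examples
#' count_circles_in_circle(lattice_spec(250, 15000))
#' @export
count_circles_in_circle <- function(spec, n_offsets = 15L) {
  spec <- as_tibble(spec)
  rmax <- (spec$container_diameter - spec$void_diameter) / 2
  if (rmax < 0) {
    warning("void larger than container: count is 0")
    return(0L)
  }
  if (spec$registration == "centered") {
    return(nrow(hex_centers(spec$pitch, rmax)))
  }
  offs_x <- seq(0, spec$pitch, length.out = n_offsets + 1L)[-(n_offsets + 1L)]
  offs_y <- seq(0, spec$pitch * sqrt(3) / 2, length.out = n_offsets + 1L)[-(n_offsets + 1L)]
  best <- 0L
  for (ox in offs_x) for (oy in offs_y) {
    best <- max(best, nrow(hex_centers(spec$pitch, rmax, c(ox, oy))))
  }
  best
}

#' HCP capacity of a multi-layer scaffold
#'
#' Counts voids layer by layer (alternating A/B in-plane registration for
#' successive layers) and reports the ideal HCP packing fraction
#' `pi / (3 sqrt(2))` (~0.7405, the 74% maximum porosity once inverted) and
#' the HCP number density `sqrt(2) / d^3` expressed per uL.
#'
#' @param spec A [lattice_spec()].
#' @return A one-row tibble: `per_layer` (list-column of per-layer counts),
#'   `total`, `packing_fraction`, `number_density_per_ul`.
#' @examples
#' hcp_capacity(lattice_spec(250, 5000, layers = 5))
#' @export
hcp_capacity <- function(spec) {
  spec <- as_tibble(spec)
  rmax <- (spec$container_diameter - spec$void_diameter) / 2
  b_off <- c(spec$pitch / 2, spec$pitch / (2 * sqrt(3)))
  counts <- integer(spec$layers)
  for (k in seq_len(spec$layers)) {
    off <- if (k %% 2L == 1L) c(0, 0) else b_off
    counts[k] <- if (rmax < 0) 0L else nrow(hex_centers(spec$pitch, rmax, off))
  }
  d <- spec$void_diameter
  tibble(
    per_layer = list(counts),
    total = sum(counts),
    packing_fraction = pi / (3 * sqrt(2)),
    number_density_per_ul = sqrt(2) / d^3 * 1e9
  )
}
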