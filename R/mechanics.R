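# Contact mechanics of elastic alginate microgels in a close-packed template.
#
# Soft microgels settling into a hexagonal close packing deform at their
# contacts; the flattened contact discs become the interconnecting channels of
# the inverted colloidal crystal once the template is degraded. The model
# balances gravity, buoyancy and the elastic contact stress, which reduces to
# a quartic in the half centre-to-centre distance x = Di/2 with a = R/2:
#
#   x^4 - a x^3 - 3 a^2 x^2 + 5 a^3 x - 2 a^4 (1 - lambda) = 0
#
# where lambda collects the loading group rho_w * C_alg * g / E_c (with a
# variant-dependent prefactor). At lambda = 0 the quartic factors exactly as
# (x - a)^3 (x + 2a): rigid spheres touch at Di = R. The physical root is the
# perturbation of the triple root x = a.

#' Stress-strain curve constructor
#'
#' @param strain Fractional compressive strain (dimensionless, ascending, >= 0).
#' @param stress Compressive stress in kPa, same length as `strain`.
#' @return A tibble with columns `strain` and `stress_kpa`.
#' @export
stress_strain_curve <- function(strain, stress) {
  if (length(strain) != length(stress)) abort_input("strain and stress lengths differ")
  if (length(strain) < 2L) abort_input("a stress-strain curve needs at least 2 points")
  if (any(!is.finite(strain)) || any(!is.finite(stress))) abort_input("non-finite values in curve")
  if (any(diff(strain) <= 0)) abort_input("strain must be strictly ascending")
  tibble(strain = as.numeric(strain), stress_kpa = as.numeric(stress))
}

#' Compressive modulus from the small-strain slope
#'
#' Estimates the compressive modulus E_c as the ordinary-least-squares slope
#' of stress against strain over the first `n_points` samples of the curve
#' (the small-strain linear regime). The fit includes an intercept; only the
#' slope is reported.
#'
#' @param curve A data frame with columns `strain` and `stress_kpa`
#'   (see [stress_strain_curve()]).
#' @param n_points Number of leading points used for the linear fit (default 11).
#' @return Modulus in kPa (a single number).
#' @examples
#' eps <- seq(1e-4, 1.1e-3, by = 1e-4)
#' estimate_compressive_modulus(stress_strain_curve(eps, 2156 * eps))
#' @export
estimate_compressive_modulus <- function(curve, n_points = 11L) {
  curve <- as_tibble(curve)
  if (!all(c("strain", "stress_kpa") %in% names(curve))) {
    abort_input("`curve` needs columns strain, stress_kpa")
  }
  if (nrow(curve) < 2L) abort_input("fewer than 2 samples in curve")
  if (nrow(curve) < n_points) {
    warning(sprintf("curve has %d < %d samples; using all of them", nrow(curve), n_points))
    n_points <- nrow(curve)
  }
  d <- head(curve, n_points)
  unname(coef(lm(stress_kpa ~ strain, data = d))[2])
}

#' Microgel batch descriptor
#'
#' @param calg Alginate mass-per-volume fraction (dimensionless; 0.030 means
#'   3.0% w/v). Must lie in (0, 0.1].
#' @param ec Compressive modulus in Pa.
#' @param radius_mean,radius_sd Microgel diameter mean and SD in um.
#' @return A tibble with one row.
#' @export
microgel_batch <- function(calg, ec, radius_mean, radius_sd = 0) {
  check_number(calg, "calg", positive = TRUE)
  if (calg > 0.1) abort_input("`calg` must be in (0, 0.1] (a fraction, not a percent)")
  check_number(ec, "ec", positive = TRUE)
  check_number(radius_mean, "radius_mean", positive = TRUE)
  check_number(radius_sd, "radius_sd", nonneg = TRUE)
  tibble(calg = calg, ec = ec, radius_mean = radius_mean, radius_sd = radius_sd)
}

#' Dimensionless contact load
#'
#' Evaluates the loading group of the force-balance model with SI base units
#' inserted literally: variant `"eq2"` gives `2 * rho_w * calg * g / ec`,
#' variant `"eq3"` gives `rho_w * calg * g / (3 * ec)`. The printed group is
#' not strictly dimensionless (it carries units of 1/m in SI); the package
#' treats its SI numeric value as the load `lambda`, and
#' [solve_contact_distance()] also accepts a user-supplied `lambda` directly
#' so any alternative nondimensionalisation can be applied upstream.
#'
#' @param batch A one-row data frame from [microgel_batch()] (`ec` in Pa).
#' @param variant `"eq2"` or `"eq3"`, the two printed prefactors.
#' @param rho_w Water density in kg m^-3 (default 1000).
#' @param g Gravitational acceleration in m s^-2 (default 9.81).
#' @return `lambda`, a nonnegative scalar; tends to 0 as `ec` grows.
#' @examples
#' dimensionless_load(microgel_batch(0.03, 2.156e6, 253.3), variant = "eq3")
#' @export
dimensionless_load <- function(batch, variant = c("eq3", "eq2"),
                               rho_w = 1000, g = 9.81) {
  variant <- match.arg(variant)
  check_number(rho_w, "rho_w", positive = TRUE)
  check_number(g, "g", positive = TRUE)
  if (!is.data.frame(batch) || !all(c("calg", "ec") %in% names(batch))) {
    abort_input("`batch` must come from microgel_batch()")
  }
  if (any(batch$ec <= 0)) abort_input("`ec` must be > 0")
  base <- rho_w * batch$calg * g / batch$ec
  switch(variant, eq2 = 2 * base, eq3 = base / 3)
}

quartic_contact <- function(x, a, lambda) {
  x^4 - a * x^3 - 3 * a^2 * x^2 + 5 * a^3 * x - 2 * a^4 * (1 - lambda)
}

#' Solve the contact-distance quartic
#'
#' Finds the physical centre-to-centre distance Di between two identical
#' compressed microgels of diameter `r` under dimensionless load `lambda`.
#' The quartic in x = Di/2 has a triple root at x = a = R/2 when lambda = 0
#' and an unphysical root at -2a; the physical root is the largest real root
#' in (0, a], located by bracketed root-finding on
#' `[a * (1 - 2 * (2 lambda)^(1/3)), a]`, the bracket suggested by the
#' perturbation expansion Di/R ~ 1 - (2 lambda / 3)^(1/3).
#'
#' @param r Microgel diameter in um.
#' @param lambda Dimensionless load, e.g. from [dimensionless_load()].
#' @param variant Label recorded in the result (`"eq2"` or `"eq3"`).
#' @return A one-row tibble: `di` (um), `di_over_r`, `rcap` (um, channel
#'   diameter via [cap_diameter()]), `lam`, `variant`.
#' @examples
#' solve_contact_distance(253.3, 4.55e-5)
#' @export
solve_contact_distance <- function(r, lambda, variant = "eq3") {
  check_number(r, "r", positive = TRUE)
  check_number(lambda, "lambda", nonneg = TRUE)
  a <- r / 2
  if (lambda == 0) {
    di <- r
  } else {
    lo <- a * (1 - 2 * (2 * lambda)^(1 / 3))
    if (lo <= 0) lo <- .Machine$double.eps * a
    flo <- quartic_contact(lo, a, lambda)
    fhi <- quartic_contact(a, a, lambda)  # = 2 a^4 lambda > 0
    if (!is.finite(flo) || flo >= 0) {
      abort_input("no physical contact solution: load too large for a root in (0, a]")
    }
    root <- uniroot(quartic_contact, c(lo, a), a = a, lambda = lambda,
                    tol = 1e-13 * a, f.lower = flo, f.upper = fhi)$root
    # polish by one Newton step for the residual contract |q| < 1e-10 a^4
    dq <- 4 * root^3 - 3 * a * root^2 - 6 * a^2 * root + 5 * a^3
    root <- root - quartic_contact(root, a, lambda) / dq
    di <- 2 * root
  }
  tibble(
    di = di,
    di_over_r = di / r,
    rcap = cap_diameter(r, di),
    lam = lambda,
    variant = variant
  )
}

#' Contact cap (channel) diameter
#'
#' Diameter of the circular contact disc between two spheres of diameter `r`
#' whose centres sit `di` apart: `Rcap = 2 * sqrt((r/2)^2 - (di/2)^2)`, i.e.
#' `sqrt(r^2 - di^2)`. After template degradation this disc is the
#' interconnecting channel between neighbouring voids. `Rcap` is a diameter;
#' the identity `rcap^2 + di^2 = r^2` always holds.
#'
#' @param r Sphere diameter, um.
#' @param di Centre-to-centre distance, um, with `0 <= di <= r`.
#' @return Cap diameter in um (vectorised over `di`).
#' @export
cap_diameter <- function(r, di) {
  check_number(r, "r", positive = TRUE)
  if (any(!is.finite(di)) || any(di < 0)) abort_input("`di` must be finite and >= 0")
  if (any(di > r * (1 + 1e-12))) abort_input("`di` exceeds the sphere diameter `r`")
  di <- pmin(di, r)
  sqrt(pmax(r^2 - di^2, 0))
}

#' Predict channel diameter from batch mechanics
#'
#' Convenience composition: loading group, quartic solve, cap diameter.
#'
#' @inheritParams dimensionless_load
#' @return A one-row tibble as [solve_contact_distance()].
#' @export
predict_contact <- function(batch, variant = c("eq3", "eq2"),
                            rho_w = 1000, g = 9.81) {
  variant <- match.arg(variant)
  lam <- dimensionless_load(batch, variant, rho_w = rho_w, g = g)
  solve_contact_distance(batch$radius_mean, lam, variant = variant)
}

#' Read a stress-strain CSV
#'
#' Expects a header row and two columns: `strain`, `stress_kpa`.
#'
#' @param path CSV file path.
#' @return A validated tibble (see [stress_strain_curve()]).
#' @export
read_stress_strain <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("strain", "stress_kpa") %in% names(d))) {
    abort_input("CSV must have columns strain, stress_kpa")
  }
  stress_strain_curve(d$strain, d$stress_kpa)
}
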