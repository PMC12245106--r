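# High-throughput plate-reader path: gate scan points on the scaffold
# channel, convert the volume-proportional dead/live intensity ratio to its
# area-proportional (pixel) equivalent, fit a Gaussian to the per-dose
# histogram of corrected ratios, and assemble the dose table that feeds the
# Hill fit.

#' Gate well-scan points on the scaffold channel
#'
#' Retains rows whose green (scaffold) intensity is strictly greater than the
#' gate — read points that actually overlap the scaffold punch. The strict
#' inequality is the documented boundary convention.
#'
#' @param scan A well-scan tibble with at least `fi_green`.
#' @param green_threshold Gate in a.u. (default 2000).
#' @return The retained rows; warns if everything is gated out.
#' @export
gate_by_scaffold <- function(scan, green_threshold = 2000) {
  scan <- as_tibble(scan)
  if (!nrow(scan)) abort_input("`scan` is empty")
  if (!"fi_green" %in% names(scan)) abort_input("`scan` needs an fi_green column")
  out <- filter(scan, .data$fi_green > green_threshold)
  if (!nrow(out)) warning("all scan points gated out by the scaffold threshold")
  out
}

#' Voxel-to-pixel ratio correction
#'
#' Converts a volume-proportional intensity ratio to the corresponding
#' area-proportional one: a sphere of volume V has great-circle area
#' `pi * (3V / (4 pi))^(2/3)`. Applied to raw `FIred/FIblue` readings, whose
#' signal accumulates over the scanned volume, before histogramming.
#' Monotone increasing, concave, and exactly `pi` at `4 pi / 3`.
#'
#' @param raw_ratio Nonnegative raw ratio(s).
#' @return Corrected ratio(s).
#' @examples
#' voxel_to_pixel_correct(4 * pi / 3)  # pi
#' @export
voxel_to_pixel_correct <- function(raw_ratio) {
  if (any(!is.finite(raw_ratio)) || any(raw_ratio < 0)) {
    abort_input("`raw_ratio` must be finite and >= 0")
  }
  pi * (3 * raw_ratio / (4 * pi))^(2 / 3)
}

#' Inverse of the voxel-to-pixel correction
#'
#' @param corrected Corrected ratio(s) >= 0.
#' @return The raw (volume-proportional) ratio.
#' @export
pixel_to_voxel_ratio <- function(corrected) {
  if (any(!is.finite(corrected)) || any(corrected < 0)) {
    abort_input("`corrected` must be finite and >= 0")
  }
  (4 * pi / 3) * (corrected / pi)^(3 / 2)
}

#' Least-squares Gaussian fit to a value histogram
#'
#' Bins the values (Freedman-Diaconis width, minimum 10 bins) and fits
#' `A * exp(-(x - mean)^2 / (2 sd^2))` to the bin counts by nonlinear least
#' squares. Falls back to sample moments (flag `"moments"`) if the fit does
#' not converge; identical values short-circuit to a degenerate summary
#' (flag `"degenerate"`); a converged fit explaining less than 90% of the
#' count variance is flagged `"poor-fit"` (e.g. clearly bimodal input).
#'
#' @param values Numeric vector, length >= 3.
#' @return A one-row tibble: `mean`, `sd`, `amplitude`, `r_squared`, `n`,
#'   `flag` (`"ok"`, `"poor-fit"`, `"moments"` or `"degenerate"`).
#' @export
fit_gaussian <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) abort_input("need >= 3 values for a Gaussian fit")
  n <- length(values)
  if (diff(range(values)) == 0) {
    return(tibble(mean = values[1], sd = 0, amplitude = n,
                  r_squared = NA_real_, n = n, flag = "degenerate"))
  }
  bw <- 2 * IQR(values) / n^(1 / 3)
  n_bins <- if (bw > 0) max(10L, ceiling(diff(range(values)) / bw)) else 10L
  breaks <- seq(min(values), max(values), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  m0 <- mean(values); s0 <- sd(values)
  dat <- data.frame(x = mids, y = counts)
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
    data = dat,
    start = list(A = max(counts), mu = m0, s = s0),
    lower = c(A = 0, mu = -Inf, s = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble(mean = m0, sd = s0, amplitude = NA_real_,
                  r_squared = NA_real_, n = n, flag = "moments"))
  }
  cf <- coef(fit)
  r2 <- 1 - sum(residuals(fit)^2) / sum((counts - mean(counts))^2)
  tibble(
    mean = cf[["mu"]], sd = cf[["s"]], amplitude = cf[["A"]],
    r_squared = r2, n = n,
    flag = if (is.finite(r2) && r2 < 0.9) "poor-fit" else "ok"
  )
}

#' Build the per-dose corrected-ratio summary table
#'
#' For each dose: gate on the scaffold channel, form the corrected
#' `fi_red / fi_blue` ratio per retained point ([voxel_to_pixel_correct()]),
#' and fit a Gaussian to the histogram. Doses whose points are all gated out
#' are dropped with a warning.
#'
#' @param scan A well-scan tibble (`dose_um`, `fi_green`, `fi_blue`,
#'   `fi_red`; see [simulate_wellscan()] or [read_wellscan()]).
#' @param green_threshold Scaffold gate, a.u. (default 2000).
#' @return A tibble ordered by dose: `dose_um`, `mean`, `sd`, `amplitude`,
#'   `r_squared`, `n`, `flag`.
#' @export
build_dose_response <- function(scan, green_threshold = 2000) {
  scan <- as_tibble(scan)
  req <- c("dose_um", "fi_green", "fi_blue", "fi_red")
  if (!all(req %in% names(scan))) {
    abort_input(paste("`scan` needs columns", paste(req, collapse = ", ")))
  }
  doses <- sort(unique(scan$dose_um))
  if (length(doses) < 2L) abort_input("need >= 2 distinct doses")
  out <- vector("list", length(doses))
  for (i in seq_along(doses)) {
    rows <- suppressWarnings(
      gate_by_scaffold(filter(scan, .data$dose_um == doses[i]), green_threshold)
    )
    if (!nrow(rows)) {
      warning(sprintf("dose %g uM: all points gated out; dropped", doses[i]))
      next
    }
    ratio <- rows$fi_red / pmax(rows$fi_blue, 1e-9)
    corrected <- voxel_to_pixel_correct(pmax(ratio, 0))
    out[[i]] <- mutate(fit_gaussian(corrected), dose_um = doses[i], .before = 1)
  }
  arrange(bind_rows(out), .data$dose_um)
}

#' Hill fit from a plate-reader dose summary
#'
#' Maps each per-dose corrected-ratio mean back to a viability estimate —
#' inverse voxel-to-pixel transform, then `v = 1 / (1 + dead/live)` —
#' normalises to the zero-dose level, and fits the two-parameter Hill model
#' (top = 1, bottom = 0). Set `normalize = FALSE` to fit the four-parameter
#' model to the corrected-ratio means directly.
#'
#' @param summaries Output of [build_dose_response()].
#' @param normalize Use the normalised-viability mode (default TRUE).
#' @return A `hill_fit` (see [fit_hill()]).
#' @export
fit_hill_ht <- function(summaries, normalize = TRUE) {
  summaries <- as_tibble(summaries)
  if (!all(c("dose_um", "mean") %in% names(summaries))) {
    abort_input("`summaries` must come from build_dose_response()")
  }
  if (!normalize) {
    return(fit_hill(summaries$dose_um, summaries$mean, free_asymptotes = TRUE))
  }
  raw <- pixel_to_voxel_ratio(pmax(summaries$mean, 0))
  viab <- 1 / (1 + raw)
  v0 <- viab[which.min(summaries$dose_um)]
  if (v0 <= 0) abort_input("zero-dose viability estimate is nonpositive")
  fit_hill(summaries$dose_um, viab / v0, free_asymptotes = FALSE)
}

#' Read a well-scan CSV export
#'
#' Expects a header with columns `well`, `dose_um`, `point`, `fi_green`,
#' `fi_blue`, `fi_red` (dose in uM, intensities in a.u.).
#'
#' @param path CSV file path.
#' @return A well-scan tibble.
#' @export
read_wellscan <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("well", "dose_um", "point", "fi_green", "fi_blue", "fi_red")
  missing <- setdiff(req, names(d))
  if (length(missing)) {
    abort_input(paste("well-scan CSV missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(d$fi_green < 0 | d$fi_blue < 0 | d$fi_red < 0)) {
    abort_input("negative intensities in well-scan CSV")
  }
  d
}
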