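# Hill dose-response model: response = bottom + (top - bottom) /
# (1 + (dose/ic50)^n). Dose 0 is handled by the power form directly
# (response = top exactly), so no log-dose transform is needed. Fitting is
# bounded nonlinear least squares with multi-start over log-spaced IC50 and a
# small grid of Hill coefficients, because Hill likelihoods are multimodal at
# small n.

#' Hill response
#'
#' @param dose Dose(s), uM, >= 0.
#' @param p A [hill_params()] row.
#' @return Response at each dose; `top` at dose 0, midpoint at `ic50`.
#' @examples
#' hill_response(20, hill_params(20, 1))  # 0.5
#' @export
hill_response <- function(dose, p) {
  if (any(dose < 0)) abort_input("`dose` must be >= 0")
  p$bottom + (p$top - p$bottom) / (1 + (dose / p$ic50)^p$n)
}

#' Fit the Hill equation
#'
#' Nonlinear least squares over (ic50, n, top, bottom), with bounds
#' `ic50 > 0`, `n > 0`, multi-started from a geometric grid of IC50 seeds
#' spanning `[min positive dose / 3, max dose * 3]` crossed with
#' n in {0.5, 1, 2, 4}. With `free_asymptotes = FALSE` the two-parameter
#' model (top = 1, bottom = 0) is fitted instead — the appropriate mode for
#' responses already normalised to the zero-dose level.
#'
#' @param doses Doses, uM (>= 4 distinct values, including 0 or near 0).
#' @param responses Observed responses, same length.
#' @param weights Optional nonnegative fit weights.
#' @param free_asymptotes Fit `top`/`bottom` (default TRUE)?
#' @return An object of class `hill_fit`: access parameters via `tidy()`,
#'   fit quality via `glance()`, the curve via `autoplot()`.
#' @examples
#' d <- c(0, 10, 20, 50, 100, 200)
#' fit <- fit_hill(d, hill_response(d, hill_params(20, 1)))
#' tidy(fit)
#' @export
fit_hill <- function(doses, responses, weights = NULL, free_asymptotes = TRUE) {
  if (length(doses) != length(responses)) abort_input("doses/responses lengths differ")
  if (is.null(weights)) weights <- rep(1, length(doses))
  if (length(weights) != length(doses)) abort_input("weights length mismatch")
  keep <- is.finite(doses) & is.finite(responses)
  doses <- doses[keep]; responses <- responses[keep]; weights <- weights[keep]
  if (length(unique(doses)) < 4L) abort_input("need >= 4 distinct doses")
  if (min(doses) > 0.05 * max(doses)) {
    warning("no dose at or near 0; top asymptote is poorly constrained")
  }

  if (var(responses) == 0) {
    abort_input("constant responses: Hill fit is degenerate (top = bottom)")
  }

  pos <- doses[doses > 0]
  ic50_grid <- exp(seq(log(min(pos) / 3), log(max(pos) * 3), length.out = 7))
  n_grid <- c(0.5, 1, 2, 4)
  dat <- data.frame(dose = doses, resp = responses)
  top0 <- max(responses); bot0 <- min(responses)

  best <- NULL
  best_sse <- Inf
  for (ic in ic50_grid) for (nn in n_grid) {
    fit <- if (free_asymptotes) {
      tryCatch(minpack.lm::nlsLM(
        resp ~ bottom + (top - bottom) / (1 + (dose / ic50)^n),
        data = dat, weights = weights,
        start = list(ic50 = ic, n = nn, top = top0, bottom = bot0),
        lower = c(ic50 = 1e-9, n = 1e-3, top = -Inf, bottom = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), error = function(e) NULL)
    } else {
      tryCatch(minpack.lm::nlsLM(
        resp ~ 1 / (1 + (dose / ic50)^n),
        data = dat, weights = weights,
        start = list(ic50 = ic, n = nn),
        lower = c(ic50 = 1e-9, n = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ), error = function(e) NULL)
    }
    if (is.null(fit)) next
    sse <- sum(weights * residuals(fit)^2)
    if (is.finite(sse) && sse < best_sse) {
      best <- fit
      best_sse <- sse
    }
  }
  if (is.null(best)) abort_input("Hill fit failed to converge from all starts")

  cf <- coef(best)
  params <- if (free_asymptotes) {
    tibble(ic50 = cf[["ic50"]], n = cf[["n"]], top = cf[["top"]], bottom = cf[["bottom"]])
  } else {
    tibble(ic50 = cf[["ic50"]], n = cf[["n"]], top = 1, bottom = 0)
  }
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  sst <- sum(weights * (responses - weighted.mean(responses, weights))^2)
  r2 <- 1 - best_sse / sst
  extrapolated <- params$ic50 < min(pos) || params$ic50 > max(doses)

  structure(
    list(
      params = params,
      std_errors = se,
      r_squared = r2,
      n_obs = length(doses),
      free_asymptotes = free_asymptotes,
      extrapolated = extrapolated,
      data = tibble(dose_um = doses, response = responses, weight = weights)
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<hill_fit> IC50 = %.4g uM, n = %.4g, top = %.4g, bottom = %.4g\n  R^2 = %.4f on %d observations%s\n",
    p$ic50, p$n, p$top, p$bottom, x$r_squared, x$n_obs,
    if (x$extrapolated) " (IC50 outside dose range)" else ""
  ))
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  terms <- names(x$params)
  tibble(
    term = terms,
    estimate = as.numeric(x$params[1, ]),
    std.error = as.numeric(x$std_errors[match(terms, names(x$std_errors))])
  )
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    n.obs = x$n_obs,
    ic50.extrapolated = x$extrapolated
  )
}

#' @rdname fit_hill
#' @param object A `hill_fit` object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble(dose_um = seq(0, max(object$data$dose_um), length.out = 200))
  grid$response <- hill_response(grid$dose_um, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dose_um, .data$response)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "dose (uM)", y = "response",
      title = sprintf("Hill fit: IC50 = %.3g uM, n = %.3g",
                      object$params$ic50, object$params$n)
    ) +
    ggplot2::theme_minimal()
}

#' ROC area under the curve for two viability groups
#'
#' Probability that a value from `group_high` exceeds one from `group_low`,
#' with ties counted half: the rank (Mann-Whitney) formulation of AUC.
#'
#' @param group_low,group_high Numeric vectors (nonempty).
#' @return AUC in \[0, 1\]; 0.5 for identical distributions, 1 for complete
#'   separation with `group_high` above.
#' @examples
#' roc_auc(c(0.1, 0.2, 0.3), c(0.25, 0.4, 0.5))  # 8/9
#' @export
roc_auc <- function(group_low, group_high) {
  if (!length(group_low) || !length(group_high)) abort_input("both groups must be nonempty")
  n1 <- length(group_low); n2 <- length(group_high)
  r <- rank(c(group_low, group_high))
  u <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  u / (n1 * n2)
}
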