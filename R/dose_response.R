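#' Percentage viability from raw plate signals
#'
#' `100 * (signal - background) / (dmso_signal - background)`. Values are not
#' clipped: viability may exceed 100% or fall below 0% (clip at reporting
#' time if desired). The result is invariant to adding a constant to all
#' three signals.
#'
#' @param signal Signal of the treated well (fluorescence/luminescence).
#' @param background Background signal.
#' @param dmso_signal Signal of the vehicle (DMSO) control.
#' @return Viability in percent (vectorized).
#' @export
normalize_viability <- function(signal, background, dmso_signal) {
  if (any(dmso_signal <= background, na.rm = TRUE)) {
    abort("degenerate control: dmso_signal must exceed background")
  }
  100 * (signal - background) / (dmso_signal - background)
}

#' Fit a logistic dose-response model
#'
#' Least-squares fit of
#' `V(x) = bottom + (top - bottom) / (1 + (x / ic50)^hill)`. The
#' `"two_param"` model (screen stage) fixes `top = 100`, `bottom = 0` and
#' fits `ic50` and `hill`; `"four_param"` (confirmation/organoid stage) fits
#' all four. Optimization is bounded Levenberg-Marquardt on `log10(ic50)`,
#' initialized at the geometric mean of the positive doses with `hill = 1`,
#' with 3 jittered restarts before declaring non-convergence. Fits whose
#' IC50 falls outside the dose range times `[1e-2, 1e2]`, or data with no
#' measurable response (all viabilities >= 80%), are flagged
#' `converged = FALSE`.
#'
#' @param dose_um Concentrations in µM (may include 0).
#' @param viability Normalized viabilities in percent.
#' @param model `"two_param"` or `"four_param"`.
#' @return A `dose_response_fit` object with elements `ic50`, `hill`, `top`,
#'   `bottom`, `model`, `converged`, `reason`, `rss`, `data`.
#' @export
fit_dose_response <- function(dose_um, viability,
                              model = c("two_param", "four_param")) {
  model <- match.arg(model)
  ok <- !is.na(dose_um) & !is.na(viability)
  dose_um <- dose_um[ok]; viability <- viability[ok]
  pos <- unique(dose_um[dose_um > 0])
  need <- if (model == "two_param") 3L else 5L
  if (length(pos) < need) {
    abort(sprintf("%s model requires >= %d distinct positive doses", model, need))
  }
  out <- structure(list(ic50 = NA_real_, hill = NA_real_,
                        top = if (model == "two_param") 100 else NA_real_,
                        bottom = if (model == "two_param") 0 else NA_real_,
                        model = model, converged = FALSE, reason = NA_character_,
                        rss = NA_real_,
                        data = tibble(dose_um = dose_um, viability = viability)),
                   class = "dose_response_fit")
  if (all(viability >= 80)) {
    out$reason <- "no response"
    return(out)
  }
  df <- data.frame(x = dose_um, v = viability)
  l0 <- mean(log10(pos))
  lower_l <- log10(min(pos)) - 4; upper_l <- log10(max(pos)) + 4
  fits <- list()
  for (r in 0:2) {
    jit <- if (r == 0) c(0, 0) else c(runif(1, -1, 1), runif(1, -0.3, 0.3))
    fit <- tryCatch({
      if (model == "two_param") {
        minpack.lm::nlsLM(
          v ~ 100 / (1 + (x / 10^l)^h), data = df,
          start = list(l = l0 + jit[1], h = 1 + jit[2]),
          lower = c(l = lower_l, h = 0.05), upper = c(l = upper_l, h = 10),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          v ~ b + (t - b) / (1 + (x / 10^l)^h), data = df,
          start = list(l = l0 + jit[1], h = 1 + jit[2],
                       t = max(viability), b = min(viability)),
          lower = c(l = lower_l, h = 0.05, t = 50, b = -20),
          upper = c(l = upper_l, h = 10, t = 200, b = 80),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
  }
  if (length(fits) == 0) {
    out$reason <- "optimizer failed"
    return(out)
  }
  best <- fits[[which.min(purrr::map_dbl(fits, stats::deviance))]]
  cf <- coef(best)
  out$ic50 <- 10^cf[["l"]]
  out$hill <- cf[["h"]]
  if (model == "four_param") { out$top <- cf[["t"]]; out$bottom <- cf[["b"]] }
  out$rss <- stats::deviance(best)
  in_range <- out$ic50 >= min(pos) * 1e-2 && out$ic50 <= max(pos) * 1e2
  out$converged <- in_range
  if (!in_range) out$reason <- "ic50 outside dose range"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> %s: ic50 = %.4g uM, hill = %.3g%s\n",
              x$model, x$ic50, x$hill,
              if (x$converged) "" else sprintf(" [not converged: %s]", x$reason)))
  invisible(x)
}

#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(term = c("ic50", "hill", "top", "bottom"),
         estimate = c(x$ic50, x$hill, x$top, x$bottom))
}

#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
         model = x$model, converged = x$converged, rss = x$rss,
         n = nrow(x$data))
}

#' @export
autoplot.dose_response_fit <- function(object, ...) {
  dat <- filter(object$data, .data$dose_um > 0)
  p <- ggplot(dat, aes(x = .data$dose_um, y = .data$viability)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "viability (%)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(dose_um = 10^seq(log10(min(dat$dose_um)),
                                    log10(max(dat$dose_um)), length.out = 100))
    grid$viability <- object$bottom + (object$top - object$bottom) /
      (1 + (grid$dose_um / object$ic50)^object$hill)
    p <- p + ggplot2::geom_line(data = grid, color = "steelblue") +
      ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed")
  }
  p
}

#' Spheroid volume from its radius
#'
#' `V = (4/3) * pi * r^3`.
#'
#' @param r Radius (any length unit); must be non-negative.
#' @return Volume in the cubed unit of `r` (vectorized).
#' @export
spheroid_volume <- function(r) {
  if (any(r < 0, na.rm = TRUE)) abort("spheroid radius must be non-negative")
  (4 / 3) * pi * r^3
}
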