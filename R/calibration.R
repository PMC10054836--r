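#' Printed calibration-line coefficients for each ion
#'
#' The published log-linear sensor response lines, peak current (A)
#' against log10 of molar concentration: slope 1.64e-7 and intercept
#' 1.97e-6 for copper, slope 5.36e-7 and intercept 6.07e-6 for zinc.
#' Used as generator defaults and as reference values in examples.
#'
#' @param ion `"Cu"` or `"Zn"`.
#' @return A list with `slope` (A per decade) and `intercept` (A).
#' @examples
#' calibration_line("Cu")
#' @export
calibration_line <- function(ion = c("Cu", "Zn")) {
  ion <- match.arg(ion)
  if (ion == "Cu") list(slope = 1.64e-7, intercept = 1.97e-6)
  else list(slope = 5.36e-7, intercept = 6.07e-6)
}

#' Concentration panel used for sensor calibration
#'
#' @return The five calibration concentrations in mol/L.
#' @examples
#' calibration_concentrations()
#' @export
calibration_concentrations <- function() {
  c(1e-11, 1e-10, 1e-9, 1e-7, 1e-6)
}

#' Fit a log-linear ion calibration curve
#'
#' Ordinary least squares of the mean replicate peak current on
#' log10(concentration), the standard stripping-voltammetry calibration.
#' Replicates at each concentration are averaged before regression;
#' their scatter feeds the per-point relative standard deviation, of
#' which the maximum is reported (`rsd_max_pct`).
#'
#' @param data A data frame with columns `concentration_m` (mol/L, > 0)
#'   and `peak_current_a` (A); an optional `replicate_id` column marks
#'   replicate measurements. At least 3 distinct concentrations.
#' @param ion Optional ion label (`"Cu"`/`"Zn"`) carried into the model.
#'
#' @return An object of class `swasv_calibration`: a list with `ion`,
#'   `slope` (A per decade), `intercept` (A), `r` (Pearson correlation of
#'   mean current with log10 concentration), `rsd_max_pct`, `n_points`,
#'   `range_m` (calibrated concentration range) and `points` (the
#'   per-concentration summary tibble). Supports [tidy()], [glance()],
#'   [predict_concentration()] and [ggplot2::autoplot()].
#'
#' @examples
#' cal <- gen_calibration_set("Cu", noise = noise_model("none")) |>
#'   fit_calibration(ion = "Cu")
#' glance(cal)
#' @export
fit_calibration <- function(data, ion = NULL) {
  req <- c("concentration_m", "peak_current_a")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort_invalid("calibration data needs columns concentration_m, peak_current_a")
  }
  if (any(!is.finite(data$peak_current_a))) {
    abort_invalid("peak currents must be finite")
  }
  if (any(data$concentration_m <= 0)) {
    abort_invalid("concentrations must be positive (log10 is taken)")
  }
  pts <- data |>
    dplyr::group_by(concentration_m = .data$concentration_m) |>
    dplyr::summarise(
      mean_current_a = mean(.data$peak_current_a),
      sd_current_a = ifelse(dplyr::n() > 1, stats::sd(.data$peak_current_a), 0),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$concentration_m) |>
    dplyr::mutate(
      log10_concentration = log10(.data$concentration_m),
      rsd_pct = ifelse(.data$mean_current_a != 0,
                       100 * .data$sd_current_a / abs(.data$mean_current_a),
                       NA_real_)
    )
  if (nrow(pts) < 3) {
    abort_invalid("at least 3 distinct concentrations are required")
  }
  if (stats::sd(pts$log10_concentration) == 0) {
    abort_invalid("zero variance in log10(concentration)")
  }
  fit <- stats::lm(mean_current_a ~ log10_concentration, data = pts)
  coefs <- stats::coef(fit)
  r <- if (stats::sd(pts$mean_current_a) == 0) {
    warn("all mean currents are equal; correlation undefined, reported as 0")
    0
  } else {
    stats::cor(pts$log10_concentration, pts$mean_current_a)
  }
  structure(
    list(
      ion = ion,
      slope = unname(coefs["log10_concentration"]),
      intercept = unname(coefs["(Intercept)"]),
      r = r,
      rsd_max_pct = max(pts$rsd_pct, na.rm = TRUE),
      n_points = nrow(pts),
      range_m = range(pts$concentration_m),
      points = pts
    ),
    class = "swasv_calibration"
  )
}

#' @export
print.swasv_calibration <- function(x, ...) {
  cat("<swasv_calibration>", x$ion %||% "", "\n")
  cat(sprintf("  i_peak = %.3g * log10(C) + %.3g   (A; C in mol/L)\n",
              x$slope, x$intercept))
  cat(sprintf("  r = %.4f, max RSD = %.2f%%, %d concentrations in [%.1e, %.1e] M\n",
              x$r, x$rsd_max_pct, x$n_points, x$range_m[1], x$range_m[2]))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x,object A `swasv_calibration` object.
#' @param ... Unused.
#' @export
tidy.swasv_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("log10_concentration", "(Intercept)"),
    estimate = c(x$slope, x$intercept),
    unit = c("A per decade", "A")
  )
}

#' @rdname fit_calibration
#' @export
glance.swasv_calibration <- function(x, ...) {
  tibble::tibble(
    ion = x$ion %||% NA_character_,
    slope = x$slope,
    intercept = x$intercept,
    r = x$r,
    rsd_max_pct = x$rsd_max_pct,
    n_points = x$n_points
  )
}

#' @rdname fit_calibration
#' @export
autoplot.swasv_calibration <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(.data$log10_concentration,
                                    .data$mean_current_a * 1e6)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = (.data$mean_current_a - .data$sd_current_a) * 1e6,
                   ymax = (.data$mean_current_a + .data$sd_current_a) * 1e6),
      width = 0.1
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope * 1e6,
                         intercept = object$intercept * 1e6,
                         colour = "red") +
    ggplot2::labs(
      x = "log10( concentration / M )",
      y = expression(Peak ~ current ~ (mu * A)),
      title = sprintf("%s calibration: r = %.4f",
                      object$ion %||% "", object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Limit of detection from blank noise and calibration slope
#'
#' The conventional stripping-voltammetry detection limit
#' \eqn{LOD = 3\sigma / m}, where \eqn{\sigma} is the standard deviation
#' of the blank peak current and \eqn{m} the calibration slope.
#'
#' Note on units: with the slope in A per decade of molar concentration,
#' the ratio is formally in decades of concentration; the field
#' conventionally quotes the resulting number on the mol/L scale. The
#' value is returned as the literal `3 * sigma_blank / slope` and the
#' interpretation is left to the caller.
#'
#' @param model A `swasv_calibration` with positive slope.
#' @param sigma_blank Standard deviation of the blank peak current, A.
#' @return The detection limit (scalar).
#' @examples
#' cal <- fit_calibration(gen_calibration_set("Cu", noise = noise_model("none")))
#' lod(cal, sigma_blank = 1.4e-19)
#' @export
lod <- function(model, sigma_blank) {
  stopifnot(inherits(model, "swasv_calibration"))
  if (!is.numeric(sigma_blank) || sigma_blank < 0) {
    abort_invalid("sigma_blank must be a nonnegative number")
  }
  if (model$slope <= 0) abort_invalid("LOD requires a positive slope")
  3 * sigma_blank / model$slope
}

#' Invert a calibration curve to estimate concentration
#'
#' Applies the inverse of the fitted line,
#' \eqn{C = 10^{(i_{peak} - b)/m}}, to one or more peak currents.
#' Estimates falling outside the calibrated concentration range are
#' flagged as extrapolation rather than refused.
#'
#' @param model A `swasv_calibration`.
#' @param i_peak Peak current(s), A.
#' @return A tibble with `i_peak_a`, `concentration_m`, `extrapolated`.
#' @examples
#' cal <- fit_calibration(gen_calibration_set("Cu", noise = noise_model("none")))
#' predict_concentration(cal, 9.86e-7)
#' @export
predict_concentration <- function(model, i_peak) {
  stopifnot(inherits(model, "swasv_calibration"))
  if (model$slope == 0) abort_invalid("cannot invert a zero-slope calibration")
  conc <- 10^((i_peak - model$intercept) / model$slope)
  # small relative slack so round-tripped boundary points are in range
  tibble::tibble(
    i_peak_a = i_peak,
    concentration_m = conc,
    extrapolated = conc < model$range_m[1] * (1 - 1e-9) |
      conc > model$range_m[2] * (1 + 1e-9)
  )
}
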