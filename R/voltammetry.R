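#' Square-wave anodic stripping voltammetry protocol
#'
#' Describes one SWASV run: the cathodic pre-concentration step that
#' deposits the metal on the ion-selective membrane, the square-wave
#' anodic scan that strips it (producing the oxidation peak), and the
#' final cleaning step. The built-in presets are the instrument settings
#' used for copper and zinc detection:
#'
#' * Cu: precondition -1.0 V / 30 s; scan -0.2 to +0.5 V, 4 mV step,
#'   20 mV amplitude, 25 Hz; cleaning +0.3 V / 90 s.
#' * Zn: precondition -1.2 V / 30 s; scan -1.0 to -0.2 V, 8 mV step,
#'   50 mV amplitude, 50 Hz; cleaning +0.3 V / 90 s.
#'
#' Pre-concentration and cleaning parameters are carried as metadata;
#' they have no numeric role in the phenomenological trace model.
#'
#' @param ion `"Cu"` or `"Zn"`; selects the preset defaults.
#' @param precondition_potential_v,precondition_time_s Deposition step.
#' @param e_start_v,e_end_v,step_v Anodic scan window and increment (V).
#' @param amplitude_v,frequency_hz Square-wave pulse amplitude and rate.
#' @param cleaning_potential_v,cleaning_time_s Post-scan stripping step.
#'
#' @return An object of class `swv_protocol` (named list).
#' @examples
#' swv_protocol("Cu")
#' swv_protocol("Zn", frequency_hz = 25)
#' @export
swv_protocol <- function(ion = c("Cu", "Zn"),
                         precondition_potential_v = NULL,
                         precondition_time_s = 30,
                         e_start_v = NULL, e_end_v = NULL, step_v = NULL,
                         amplitude_v = NULL, frequency_hz = NULL,
                         cleaning_potential_v = 0.3,
                         cleaning_time_s = 90) {
  ion <- match.arg(ion)
  preset <- if (ion == "Cu") {
    list(precondition_potential_v = -1.0, e_start_v = -0.2, e_end_v = 0.5,
         step_v = 0.004, amplitude_v = 0.020, frequency_hz = 25)
  } else {
    list(precondition_potential_v = -1.2, e_start_v = -1.0, e_end_v = -0.2,
         step_v = 0.008, amplitude_v = 0.050, frequency_hz = 50)
  }
  p <- list(
    ion = ion,
    precondition_potential_v =
      precondition_potential_v %||% preset$precondition_potential_v,
    precondition_time_s = precondition_time_s,
    e_start_v = e_start_v %||% preset$e_start_v,
    e_end_v = e_end_v %||% preset$e_end_v,
    step_v = step_v %||% preset$step_v,
    amplitude_v = amplitude_v %||% preset$amplitude_v,
    frequency_hz = frequency_hz %||% preset$frequency_hz,
    cleaning_potential_v = cleaning_potential_v,
    cleaning_time_s = cleaning_time_s
  )
  if (p$e_start_v == p$e_end_v) abort_invalid("e_start_v must differ from e_end_v")
  if (p$step_v <= 0) abort_invalid("step_v must be positive")
  if (p$frequency_hz <= 0) abort_invalid("frequency_hz must be positive")
  structure(p, class = "swv_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.swv_protocol <- function(x, ...) {
  cat(sprintf(
    "<swv_protocol> %s: precondition %.1f V / %g s; scan %.3f -> %.3f V, step %g mV, amplitude %g mV, %g Hz; cleaning %.1f V / %g s\n",
    x$ion, x$precondition_potential_v, x$precondition_time_s,
    x$e_start_v, x$e_end_v, 1e3 * x$step_v, 1e3 * x$amplitude_v,
    x$frequency_hz, x$cleaning_potential_v, x$cleaning_time_s
  ))
  invisible(x)
}

#' Potential grid of a square-wave scan
#'
#' The arithmetic sequence of staircase potentials, from `e_start_v`
#' towards `e_end_v` in increments of `step_v` (start inclusive). For the
#' Cu preset this is 176 points from -0.200 to +0.500 V; for Zn, 101
#' points from -1.0 to -0.2 V.
#'
#' @param protocol A [swv_protocol()] object.
#' @return Numeric vector of potentials, V.
#' @examples
#' length(potential_grid(swv_protocol("Cu")))
#' @export
potential_grid <- function(protocol) {
  stopifnot(inherits(protocol, "swv_protocol"))
  span <- abs(protocol$e_end_v - protocol$e_start_v)
  if (protocol$step_v > span) {
    abort_invalid("step_v exceeds the scan range")
  }
  n_steps <- floor(span / protocol$step_v + 1e-9)
  dir <- sign(protocol$e_end_v - protocol$e_start_v)
  protocol$e_start_v + (0:n_steps) * protocol$step_v * dir
}

#' Build a voltammogram from a current trace
#'
#' @param protocol A [swv_protocol()] object.
#' @param currents Currents in A, one per point of
#'   [potential_grid()] of the protocol.
#' @return A tibble of class `swasv_voltammogram` with columns
#'   `potential_v`, `current_a`; the protocol travels as an attribute.
#' @examples
#' pr <- swv_protocol("Cu")
#' voltammogram(pr, rep(0, length(potential_grid(pr))))
#' @export
voltammogram <- function(protocol, currents) {
  grid <- potential_grid(protocol)
  if (length(currents) != length(grid)) {
    abort_invalid(sprintf(
      "currents has %d values but the protocol grid has %d points",
      length(currents), length(grid)
    ))
  }
  if (any(!is.finite(currents))) abort_invalid("currents must be finite")
  new_voltammogram(grid, currents, protocol)
}

new_voltammogram <- function(potential_v, current_a, protocol = NULL) {
  out <- tibble::tibble(
    potential_v = as.numeric(potential_v),
    current_a = as.numeric(current_a)
  )
  attr(out, "protocol") <- protocol
  class(out) <- c("swasv_voltammogram", class(out))
  out
}

vg_protocol <- function(v) attr(v, "protocol", exact = TRUE)

as_voltammogram <- function(data, protocol = NULL) {
  req <- c("potential_v", "current_a")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort_invalid("a voltammogram needs columns potential_v, current_a")
  }
  if (nrow(data) < 2) abort_invalid("voltammogram has fewer than 2 points")
  new_voltammogram(data$potential_v, data$current_a,
                   protocol %||% vg_protocol(data))
}

# Linear baseline from the outer flanks: least-squares line through the
# outer `flank_fraction` of points at each end of the scan.
flank_baseline <- function(v, flank_fraction) {
  if (!is.numeric(flank_fraction) || flank_fraction <= 0 ||
      flank_fraction > 0.4) {
    abort_invalid("flank_fraction must be in (0, 0.4]")
  }
  n <- nrow(v)
  k <- floor(flank_fraction * n)
  idx <- c(seq_len(k), seq(n - k + 1, n))
  idx <- unique(idx[idx >= 1 & idx <= n])
  if (length(idx) < 4) abort_invalid("fewer than 4 flank points")
  fit <- stats::lm(current_a ~ potential_v, data = v[idx, ])
  list(
    predict = unname(stats::predict(fit, newdata = v)),
    residual_sd = stats::mad(stats::residuals(fit))
  )
}

#' Subtract a linear flank baseline from a voltammogram
#'
#' Fits a straight line to the outer `flank_fraction` of points at each
#' end of the scan (where no stripping peak is expected) and subtracts it
#' from the whole trace. The potential grid is unchanged.
#'
#' @param v A voltammogram (tibble with `potential_v`, `current_a`).
#' @param flank_fraction Fraction of points per flank used for the line,
#'   in (0, 0.4]. Default 0.15.
#' @return The baseline-corrected voltammogram; the fitted baseline is
#'   attached as attribute `"baseline"` and the robust flank noise
#'   estimate as `"flank_noise_a"`.
#' @examples
#' pr <- swv_protocol("Cu")
#' v <- gen_voltammogram(pr, peak_height = 1e-6)
#' baseline_correct(v)
#' @export
baseline_correct <- function(v, flank_fraction = 0.15) {
  v <- as_voltammogram(v)
  bl <- flank_baseline(v, flank_fraction)
  out <- new_voltammogram(v$potential_v, v$current_a - bl$predict,
                          vg_protocol(v))
  attr(out, "baseline") <- bl$predict
  attr(out, "flank_noise_a") <- bl$residual_sd
  out
}

default_peak_window <- function(ion) {
  switch(ion,
    Cu = c(0.0, 0.2),
    Zn = c(-0.55, -0.35),
    abort_invalid("no default peak window for this ion")
  )
}

#' Locate the oxidation peak of a stripping voltammogram
#'
#' Baseline-corrects the trace ([baseline_correct()]) and returns the
#' maximum corrected current inside the search window, provided its
#' height exceeds a prominence threshold; otherwise the peak is reported
#' as not found (the blank / pre-transport case).
#'
#' Default windows follow the observed oxidation potentials:
#' Cu `[0.0, 0.2]` V, Zn `[-0.55, -0.35]` V. The default prominence
#' threshold is 3x the robust noise estimate from the flank residuals
#' (median absolute deviation, scaled), so a flat blank trace yields
#' `found = FALSE`.
#'
#' @param v A voltammogram.
#' @param window Length-2 numeric search window in V; defaults from the
#'   protocol ion if the trace carries one.
#' @param min_prominence Minimum baseline-corrected height (A) for a
#'   peak to count as found; default 3x flank noise.
#' @param flank_fraction Passed to [baseline_correct()].
#' @return A one-row tibble: `e_peak_v`, `i_peak_a`, `window_lo_v`,
#'   `window_hi_v`, `found`. When not found, `e_peak_v` and `i_peak_a`
#'   are `NA`.
#' @examples
#' v <- gen_voltammogram(swv_protocol("Cu"), peak_height = 1e-6)
#' find_peak(v)
#' @export
find_peak <- function(v, window = NULL, min_prominence = NULL,
                      flank_fraction = 0.15) {
  v <- as_voltammogram(v)
  if (is.null(window)) {
    proto <- vg_protocol(v)
    if (is.null(proto)) {
      abort_invalid("no window given and the trace carries no protocol")
    }
    window <- default_peak_window(proto$ion)
  }
  window <- sort(as.numeric(window))
  corrected <- baseline_correct(v, flank_fraction)
  in_win <- which(v$potential_v >= window[1] & v$potential_v <= window[2])
  if (length(in_win) == 0) {
    abort_invalid("search window does not overlap the potential grid")
  }
  if (is.null(min_prominence)) {
    min_prominence <- 3 * attr(corrected, "flank_noise_a")
  }
  i_best <- in_win[which.max(corrected$current_a[in_win])]
  height <- corrected$current_a[i_best]
  found <- is.finite(height) && height > min_prominence
  tibble::tibble(
    e_peak_v = if (found) v$potential_v[i_best] else NA_real_,
    i_peak_a = if (found) height else NA_real_,
    window_lo_v = window[1],
    window_hi_v = window[2],
    found = found
  )
}

#' @rdname voltammogram
#' @param object A `swasv_voltammogram`.
#' @param ... Unused.
#' @export
autoplot.swasv_voltammogram <- function(object, ...) {
  proto <- vg_protocol(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$potential_v,
                                       .data$current_a * 1e6)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Potential (V)", y = expression(Current ~ (mu * A)),
      title = if (!is.null(proto)) paste0(proto$ion, " square-wave scan")
    ) +
    ggplot2::theme_minimal()
}
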