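#' Apical/basolateral peak-current time series
#'
#' Time-stamped peak currents measured in the two Transwell compartments
#' for one ion, starting at the pre-treatment timepoint T0 (time 0). A
#' basolateral peak that was not detected is recorded as 0 (the blank /
#' "no peak" case).
#'
#' @param ion `"Cu"` or `"Zn"`.
#' @param timepoint_h Strictly increasing times in hours; the first must
#'   be 0.
#' @param apical_a Apical peak currents, A; `apical_a[1]` must be > 0
#'   (a detectable apical dose at T0).
#' @param basolateral_a Basolateral peak currents, A (0 when no peak).
#' @return A tibble of class `transport_series` with the three columns;
#'   the ion travels as an attribute.
#' @examples
#' transport_series("Cu", c(0, 1, 2), c(1, 0.6, 0.3) * 1e-6,
#'                  c(0, 0.4, 0.7) * 1e-6)
#' @export
transport_series <- function(ion, timepoint_h, apical_a, basolateral_a) {
  ion <- match.arg(ion, c("Cu", "Zn"))
  n <- length(timepoint_h)
  if (length(apical_a) != n || length(basolateral_a) != n) {
    abort_invalid("timepoint_h, apical_a and basolateral_a must have equal length")
  }
  if (n < 1 || timepoint_h[1] != 0) {
    abort_invalid("the first timepoint must be 0 (pre-treatment T0)")
  }
  if (is.unsorted(timepoint_h, strictly = TRUE)) {
    abort_invalid("timepoints must be strictly increasing")
  }
  if (!is.finite(apical_a[1]) || apical_a[1] <= 0) {
    abort_invalid("apical peak current at T0 must be positive")
  }
  out <- tibble::tibble(
    timepoint_h = as.numeric(timepoint_h),
    apical_a = as.numeric(apical_a),
    basolateral_a = as.numeric(basolateral_a)
  )
  attr(out, "ion") <- ion
  class(out) <- c("transport_series", class(out))
  out
}

#' Percent decrease of the apical peak current since T0
#'
#' \eqn{100 (i_{apical}(0) - i_{apical}(t)) / i_{apical}(0)}; positive
#' when the apical signal fell (ion left the apical compartment),
#' negative if it rose. Invariant under scaling the whole series.
#'
#' @param series A [transport_series()].
#' @param t A timepoint present in the series, > 0 (hours).
#' @return The percent decrease (scalar).
#' @examples
#' s <- transport_series("Cu", c(0, 1), c(1e-6, 6e-7), c(0, 4e-7))
#' percent_decrease(s, 1)
#' @export
percent_decrease <- function(series, t) {
  stopifnot(inherits(series, "transport_series"))
  i <- match(t, series$timepoint_h)
  if (is.na(i)) abort_invalid(sprintf("timepoint %g h is not in the series", t))
  if (t <= 0) abort_invalid("t must be a post-treatment timepoint (> 0)")
  100 * (series$apical_a[1] - series$apical_a[i]) / series$apical_a[1]
}

#' Per-timepoint transport report for one Transwell
#'
#' Tabulates the apical percent decrease and the basolateral change at
#' every timepoint. Because a tight barrier gives no basolateral peak at
#' T0, a basolateral fold-change relative to T0 is only defined when the
#' T0 basolateral signal itself exceeds the detection floor; otherwise
#' the report marks the timepoint at which a basolateral peak first
#' appeared.
#'
#' The report is flagged `consistent_with_disruption` when the apical
#' signal is strictly decreasing and the basolateral signal strictly
#' increasing over time — the signature of ions crossing a compromised
#' barrier.
#'
#' @param series A [transport_series()].
#' @param detection_floor Peak currents at or below this value (A) count
#'   as "no peak"; propagate the [find_peak()] prominence threshold here.
#' @return A tibble of class `transport_report` with columns
#'   `timepoint_h`, `apical_a`, `apical_decrease_pct`, `basolateral_a`,
#'   `basolateral_fold`, `basolateral_detected`; attributes
#'   `appeared_at_h` (first post-T0 basolateral detection, `NA` if
#'   never), `monotone_basolateral_increase` and
#'   `consistent_with_disruption`.
#' @examples
#' s <- transport_series("Cu", c(0, 1, 2), c(1, 0.6, 0.3) * 1e-6,
#'                      c(0, 0.4, 0.7) * 1e-6)
#' transport_report(s)
#' @export
transport_report <- function(series, detection_floor = 0) {
  stopifnot(inherits(series, "transport_series"))
  a0 <- series$apical_a[1]
  b0 <- series$basolateral_a[1]
  detected <- series$basolateral_a > detection_floor
  fold <- if (b0 > detection_floor) series$basolateral_a / b0 else
    rep(NA_real_, nrow(series))
  out <- tibble::tibble(
    timepoint_h = series$timepoint_h,
    apical_a = series$apical_a,
    apical_decrease_pct = 100 * (a0 - series$apical_a) / a0,
    basolateral_a = series$basolateral_a,
    basolateral_fold = fold,
    basolateral_detected = detected
  )
  appeared_at <- if (b0 > detection_floor) NA_real_ else {
    first <- which(detected)[1]
    if (is.na(first)) NA_real_ else series$timepoint_h[first]
  }
  post_baso <- series$basolateral_a
  monotone_up <- length(post_baso) > 1 && all(diff(post_baso) > 0)
  apical_down <- nrow(series) > 1 && all(diff(series$apical_a) < 0)
  attr(out, "ion") <- attr(series, "ion", exact = TRUE)
  attr(out, "appeared_at_h") <- appeared_at
  attr(out, "monotone_basolateral_increase") <- monotone_up
  attr(out, "consistent_with_disruption") <- apical_down && monotone_up
  class(out) <- c("transport_report", class(out))
  out
}

#' @export
print.transport_report <- function(x, ...) {
  ion <- attr(x, "ion", exact = TRUE)
  cat("<transport_report>", if (!is.null(ion)) ion, "\n")
  NextMethod()
  ap <- attr(x, "appeared_at_h", exact = TRUE)
  if (!is.null(ap) && !is.na(ap)) {
    cat(sprintf("basolateral peak appeared at %g h\n", ap))
  }
  if (isTRUE(attr(x, "consistent_with_disruption", exact = TRUE))) {
    cat("pattern consistent with barrier disruption",
        "(apical falling, basolateral rising)\n")
  }
  invisible(x)
}

#' @rdname transport_report
#' @param object A `transport_report`.
#' @param ... Unused.
#' @export
autoplot.transport_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("timepoint_h", "apical_a", "basolateral_a")],
    -"timepoint_h", names_to = "compartment", values_to = "current_a"
  ) |>
    dplyr::mutate(compartment = sub("_a$", "", .data$compartment))
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint_h,
                                     .data$current_a * 1e6,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time after treatment (h)",
                  y = expression(Peak ~ current ~ (mu * A)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Extract a transport series from per-trace voltammograms
#'
#' Runs [find_peak()] on every trace of an EGTA-style experiment table
#' (as produced by [gen_egta_experiment()] or assembled from a manifest
#' via [read_manifest()]) and assembles the apical/basolateral
#' [transport_series()]. Undetected peaks enter as 0.
#'
#' @param experiment A data frame with columns `timepoint_h`,
#'   `compartment` (`"apical"`/`"basolateral"`) and a list-column
#'   `trace` of voltammograms.
#' @param ion Ion label; defaults to the protocol ion of the first trace.
#' @inheritParams find_peak
#' @return A [transport_series()].
#' @examples
#' exp <- gen_egta_experiment("Cu", noise = noise_model("none"))
#' extract_transport(exp)
#' @export
extract_transport <- function(experiment, ion = NULL, window = NULL,
                              min_prominence = NULL) {
  req <- c("timepoint_h", "compartment", "trace")
  if (!is.data.frame(experiment) || !all(req %in% names(experiment))) {
    abort_invalid("experiment needs columns timepoint_h, compartment, trace")
  }
  if (is.null(ion)) {
    proto <- vg_protocol(experiment$trace[[1]])
    if (is.null(proto)) abort_invalid("no ion given and traces carry no protocol")
    ion <- proto$ion
  }
  peaks <- experiment |>
    dplyr::mutate(peak = purrr::map(
      .data$trace, find_peak,
      window = window, min_prominence = min_prominence
    )) |>
    tidyr::unnest("peak") |>
    dplyr::mutate(i_peak_a = ifelse(.data$found, .data$i_peak_a, 0)) |>
    dplyr::select("timepoint_h", "compartment", "i_peak_a")
  wide <- tidyr::pivot_wider(peaks, names_from = "compartment",
                             values_from = "i_peak_a") |>
    dplyr::arrange(.data$timepoint_h)
  transport_series(ion, wide$timepoint_h, wide$apical, wide$basolateral)
}
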