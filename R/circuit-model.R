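#' Equivalent-circuit parameters of a polarized epithelial monolayer
#'
#' Constructs the five-parameter description of the epithelial equivalent
#' circuit: the medium resistance in series with two parallel RC elements,
#' one per membrane face of the polarized cell layer. All values are
#' area-normalized.
#'
#' The two RC elements are interchangeable in the model (swapping the
#' labels of element 1 and element 2 leaves the impedance unchanged), so
#' the constructor enforces a canonical ordering: element 1 always carries
#' the smaller time constant \eqn{\tau = R C}. Inputs violating this are
#' silently relabelled.
#'
#' @param r_media Medium (solution + filter) resistance, ohm cm^2.
#' @param r1,r2 Membrane resistances, ohm cm^2.
#' @param c1,c2 Membrane capacitances, uF/cm^2.
#'
#' @return An object of class `circuit_params`: a named list with fields
#'   `r_media`, `r1`, `c1`, `r2`, `c2`.
#'
#' @examples
#' circuit_params(r_media = 20, r1 = 300, c1 = 2.4, r2 = 446, c2 = 7.2)
#' @export
circuit_params <- function(r_media, r1, c1, r2, c2) {
  vals <- c(r_media = r_media, r1 = r1, c1 = c1, r2 = r2, c2 = c2)
  if (length(vals) != 5L || !is.numeric(vals)) {
    abort_invalid("all five circuit parameters must be single numbers")
  }
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_invalid(
      "circuit parameters must be strictly positive and finite",
      values = vals
    )
  }
  # canonical ordering: element 1 has the smaller time constant
  if (r1 * c1 > r2 * c2) {
    tmp <- c(r1, c1)
    r1 <- r2; c1 <- c2
    r2 <- tmp[1]; c2 <- tmp[2]
  }
  structure(
    list(r_media = r_media, r1 = r1, c1 = c1, r2 = r2, c2 = c2),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>  (R in ohm cm^2, C in uF/cm^2)\n")
  cat(sprintf("  r_media = %.6g\n", x$r_media))
  cat(sprintf("  r1 = %.6g   c1 = %.6g   (tau1 = %.3g s)\n",
              x$r1, x$c1, x$r1 * x$c1 * 1e-6))
  cat(sprintf("  r2 = %.6g   c2 = %.6g   (tau2 = %.3g s)\n",
              x$r2, x$c2, x$r2 * x$c2 * 1e-6))
  m <- barrier_metrics(x)
  cat(sprintf("  TEER = %.6g ohm cm^2,  C_cell = %.6g uF/cm^2\n",
              m$teer_ohm_cm2, m$c_cell_uf_cm2))
  invisible(x)
}

#' Logarithmically spaced frequency grid
#'
#' Builds the frequency sweep used for impedance spectroscopy of the
#' barrier, by default 50 log-spaced points over the instrument band
#' 10 Hz to 100 kHz.
#'
#' @param n Number of frequencies.
#' @param f_min,f_max Band edges in Hz; both must be positive and
#'   `f_min < f_max`.
#'
#' @return A strictly increasing numeric vector of frequencies in Hz.
#' @examples
#' head(log_freq_grid())
#' @export
log_freq_grid <- function(n = 50, f_min = 10, f_max = 1e5) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    abort_invalid("`n` must be an integer >= 2")
  }
  check_frequencies(c(f_min, f_max))
  10^seq(log10(f_min), log10(f_max), length.out = n)
}

check_frequencies <- function(f) {
  if (length(f) == 0L) abort_invalid("frequency grid is empty")
  if (any(!is.finite(f)) || any(f <= 0)) {
    abort_invalid("frequencies must be positive and finite")
  }
  if (is.unsorted(f, strictly = TRUE)) {
    abort_invalid("frequencies must be strictly increasing")
  }
  invisible(f)
}

# Complex impedance of the circuit at frequency f (Hz); capacitances are
# stored in uF/cm^2, hence the 1e-6 inside the time constants.
circuit_z <- function(params, f) {
  w <- 2 * pi * f
  params$r_media +
    params$r1 / (1 + 1i * w * params$r1 * params$c1 * 1e-6) +
    params$r2 / (1 + 1i * w * params$r2 * params$c2 * 1e-6)
}

#' Simulate the impedance spectrum of the epithelial circuit
#'
#' Evaluates the circuit model
#' \deqn{Z(\omega) = R_{media} + \frac{R_1}{1 + j\omega R_1 C_1}
#'                            + \frac{R_2}{1 + j\omega R_2 C_2}}
#' pointwise on a frequency grid. The capacitive sign convention is used:
#' the imaginary part of every model value is non-positive.
#'
#' @param params A [circuit_params()] object.
#' @param frequencies Numeric vector of frequencies in Hz, strictly
#'   increasing; see [log_freq_grid()].
#'
#' @return A tibble of class `eis_spectrum` with columns `frequency_hz`,
#'   `z_real_ohm_cm2`, `z_imag_ohm_cm2`.
#'
#' @examples
#' p <- circuit_params(20, 300, 2.4, 446, 7.2)
#' simulate_impedance(p, log_freq_grid(n = 5))
#' @export
simulate_impedance <- function(params, frequencies = log_freq_grid()) {
  stopifnot(inherits(params, "circuit_params"))
  check_frequencies(frequencies)
  z <- circuit_z(params, frequencies)
  new_spectrum(frequencies, Re(z), Im(z))
}

new_spectrum <- function(frequency_hz, z_real, z_imag) {
  out <- tibble::tibble(
    frequency_hz = as.numeric(frequency_hz),
    z_real_ohm_cm2 = as.numeric(z_real),
    z_imag_ohm_cm2 = as.numeric(z_imag)
  )
  class(out) <- c("eis_spectrum", class(out))
  out
}

# Validate a spectrum-shaped data frame and return it as eis_spectrum.
as_spectrum <- function(data) {
  req <- c("frequency_hz", "z_real_ohm_cm2", "z_imag_ohm_cm2")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    abort_invalid(paste(
      "a spectrum needs columns", paste(req, collapse = ", ")
    ))
  }
  check_frequencies(data$frequency_hz)
  if (any(!is.finite(data$z_real_ohm_cm2)) ||
      any(!is.finite(data$z_imag_ohm_cm2))) {
    abort_invalid("impedance values must be finite")
  }
  new_spectrum(data$frequency_hz, data$z_real_ohm_cm2, data$z_imag_ohm_cm2)
}

spectrum_complex <- function(spec) {
  complex(real = spec$z_real_ohm_cm2, imaginary = spec$z_imag_ohm_cm2)
}

#' Barrier metrics of a fitted or assumed circuit
#'
#' Reduces the five circuit parameters to the two barrier readouts:
#' the transepithelial electrical resistance, TEER = R1 + R2, and the
#' cell-layer capacitance, the series combination
#' 1/C = 1/C1 + 1/C2 of the two membrane capacitances.
#'
#' Both metrics are invariant under relabelling the two RC elements.
#'
#' @param params A [circuit_params()] object.
#' @return A one-row tibble with columns `teer_ohm_cm2` and
#'   `c_cell_uf_cm2`.
#' @examples
#' barrier_metrics(circuit_params(20, 300, 2.4, 446, 7.2))
#' @export
barrier_metrics <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  tibble::tibble(
    teer_ohm_cm2 = params$r1 + params$r2,
    c_cell_uf_cm2 = params$c1 * params$c2 / (params$c1 + params$c2)
  )
}

#' Nyquist-plane coordinates of a spectrum
#'
#' Converts a spectrum to the standard Nyquist plotting convention,
#' \eqn{(\mathrm{Re}\,Z, -\mathrm{Im}\,Z)}; for model-generated spectra
#' the second coordinate is nonnegative at every frequency.
#'
#' @param spectrum A spectrum tibble (columns `frequency_hz`,
#'   `z_real_ohm_cm2`, `z_imag_ohm_cm2`).
#' @return A tibble with columns `frequency_hz`, `z_real_ohm_cm2`,
#'   `neg_z_imag_ohm_cm2`.
#' @examples
#' p <- circuit_params(20, 300, 2.4, 446, 7.2)
#' nyquist_coordinates(simulate_impedance(p))
#' @export
nyquist_coordinates <- function(spectrum) {
  spec <- as_spectrum(spectrum)
  tibble::tibble(
    frequency_hz = spec$frequency_hz,
    z_real_ohm_cm2 = spec$z_real_ohm_cm2,
    neg_z_imag_ohm_cm2 = -spec$z_imag_ohm_cm2
  )
}

#' Nyquist plot of one or more impedance spectra
#'
#' @param ... Named spectra (tibbles with the spectrum columns); the
#'   names become the legend labels.
#' @return A ggplot object: -Im(Z) against Re(Z), equal-ish axes.
#' @examples
#' pre <- simulate_impedance(barrier_preset("pre"))
#' post <- simulate_impedance(barrier_preset("post"))
#' plot_nyquist(pre = pre, post = post)
#' @export
plot_nyquist <- function(...) {
  specs <- list(...)
  if (length(specs) == 0L) abort_invalid("no spectra supplied")
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- paste0("spectrum", seq_along(specs))
  }
  df <- purrr::imap(specs, function(s, nm) {
    dplyr::mutate(nyquist_coordinates(s), condition = nm)
  })
  df <- dplyr::bind_rows(df)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$z_real_ohm_cm2, y = .data$neg_z_imag_ohm_cm2,
    colour = .data$condition
  )) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(Re(Z) ~ (Omega %.% cm^2)),
      y = expression(-Im(Z) ~ (Omega %.% cm^2)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
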