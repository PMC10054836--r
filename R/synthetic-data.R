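#' Instrument noise model
#'
#' Describes the stochastic perturbation applied by the synthetic-data
#' generators. `proportional_gaussian` multiplies each sample by
#' `1 + N(0, level)` (level is a coefficient of variation);
#' `additive_gaussian` adds `N(0, level)` in the signal's own units;
#' `none` leaves the signal exact.
#'
#' With a non-`NULL` seed, every generator call is a pure function of its
#' arguments: identical calls reproduce identical output bit for bit and
#' the session RNG state is left untouched. With `seed = NULL` the
#' session RNG stream is used (so one top-level `set.seed()` governs a
#' whole script).
#'
#' @param kind One of `"none"`, `"proportional_gaussian"`,
#'   `"additive_gaussian"`.
#' @param level CV (dimensionless) or absolute SD, per `kind`; >= 0.
#' @param seed Optional integer seed.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model("proportional_gaussian", 0.02, seed = 1)
#' @export
noise_model <- function(kind = c("none", "proportional_gaussian",
                                 "additive_gaussian"),
                        level = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level < 0) {
    abort_invalid("noise level must be a single nonnegative number")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(kind = kind, level = level, seed = seed),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_model"))
  switch(noise$kind,
    none = x,
    proportional_gaussian = x * (1 + stats::rnorm(length(x), 0, noise$level)),
    additive_gaussian = x + stats::rnorm(length(x), 0, noise$level)
  )
}

#' Barrier circuit presets for the intact and EGTA-disrupted monolayer
#'
#' Synthetic circuit parameters whose derived metrics equal the reported
#' barrier state of the differentiated monolayer before and after EGTA:
#' TEER 746 ohm cm^2 (pre) vs 288 ohm cm^2 (post) with cell capacitance
#' 1.8 uF/cm^2 in both. The individual R1/R2 split is not constrained by
#' those metrics; the presets separate the two time constants by roughly
#' 3x so both elements are resolvable, and are synthetic in that respect.
#'
#' @param condition `"pre"` (intact barrier) or `"post"` (after 2 h of
#'   EGTA).
#' @return A [circuit_params()] object.
#' @examples
#' barrier_metrics(barrier_preset("pre"))
#' barrier_metrics(barrier_preset("post"))
#' @export
barrier_preset <- function(condition = c("pre", "post")) {
  condition <- match.arg(condition)
  if (condition == "pre") {
    circuit_params(r_media = 20, r1 = 300, c1 = 2.4, r2 = 446, c2 = 7.2)
  } else {
    circuit_params(r_media = 20, r1 = 116, c1 = 2.4, r2 = 172, c2 = 7.2)
  }
}

#' Generate a noisy impedance spectrum
#'
#' Evaluates the circuit model on the grid ([simulate_impedance()]) and
#' applies the noise model independently to the real and imaginary
#' parts, emulating one instrument sweep.
#'
#' @param params A [circuit_params()] object.
#' @param frequencies Frequency grid, Hz (default [log_freq_grid()]).
#' @param noise A [noise_model()]; default 2% proportional.
#' @return A spectrum tibble (class `eis_spectrum`).
#' @examples
#' gen_spectrum(barrier_preset("pre"),
#'              noise = noise_model("proportional_gaussian", 0.02, seed = 1))
#' @export
gen_spectrum <- function(params, frequencies = log_freq_grid(),
                         noise = noise_model("proportional_gaussian", 0.02)) {
  clean <- simulate_impedance(params, frequencies)
  with_noise_seed(noise$seed, {
    new_spectrum(
      clean$frequency_hz,
      apply_noise(clean$z_real_ohm_cm2, noise),
      apply_noise(clean$z_imag_ohm_cm2, noise)
    )
  })
}

#' Generate a pre/post-treatment spectrum pair
#'
#' One spectrum per barrier condition, sharing grid and noise model
#' (independent noise draws; with a seeded model the pair as a whole is
#' reproducible). Defaults encode the reported intact/disrupted barrier.
#'
#' @param pre,post [circuit_params()] for the two conditions.
#' @inheritParams gen_spectrum
#' @return A named list of two spectra, `pre` and `post`.
#' @examples
#' tc <- gen_teer_timecourse(noise = noise_model("none"))
#' names(tc)
#' @export
gen_teer_timecourse <- function(pre = barrier_preset("pre"),
                                post = barrier_preset("post"),
                                frequencies = log_freq_grid(),
                                noise = noise_model("proportional_gaussian",
                                                    0.02)) {
  with_noise_seed(noise$seed, {
    unseeded <- noise_model(noise$kind, noise$level)
    list(
      pre = gen_spectrum(pre, frequencies, unseeded),
      post = gen_spectrum(post, frequencies, unseeded)
    )
  })
}

#' Generate a synthetic stripping voltammogram
#'
#' A phenomenological single-peak trace: a Gaussian oxidation peak on a
#' linear baseline, sampled on the protocol's potential grid, with
#' optional instrument noise on the currents. The stripping physics
#' (deposition, diffusion, ionophore binding) is not simulated; the peak
#' height is the carrier of concentration information.
#'
#' @param protocol A [swv_protocol()].
#' @param peak_center Peak potential, V; default 0.1 V for Cu and
#'   -0.45 V for Zn (the observed oxidation potentials).
#' @param peak_height Peak amplitude, A. 0 gives a pure baseline.
#' @param peak_width Gaussian sigma, V; must exceed 2x the scan step.
#' @param baseline Length-2 numeric: intercept (A) and slope (A/V).
#' @param noise A [noise_model()].
#' @return A [voltammogram()].
#' @examples
#' gen_voltammogram(swv_protocol("Cu"), peak_height = 1e-6,
#'                  noise = noise_model("none"))
#' @export
gen_voltammogram <- function(protocol,
                             peak_center = NULL,
                             peak_height = 1e-6,
                             peak_width = 0.030,
                             baseline = c(0, 0),
                             noise = noise_model("proportional_gaussian",
                                                 0.02)) {
  stopifnot(inherits(protocol, "swv_protocol"))
  peak_center <- peak_center %||%
    switch(protocol$ion, Cu = 0.1, Zn = -0.45)
  if (peak_width <= 2 * protocol$step_v) {
    abort_invalid("peak_width must exceed 2x the potential step")
  }
  if (peak_height < 0) abort_invalid("peak_height must be nonnegative")
  grid <- potential_grid(protocol)
  if (peak_height > 0 &&
      (peak_center < min(grid) || peak_center > max(grid))) {
    abort_invalid("peak_center lies outside the scan range")
  }
  clean <- peak_height * exp(-(grid - peak_center)^2 / (2 * peak_width^2)) +
    baseline[1] + baseline[2] * grid
  with_noise_seed(noise$seed, voltammogram(protocol, apply_noise(clean, noise)))
}

#' Generate a synthetic calibration data set
#'
#' Peak heights are placed on the log-linear line
#' `slope * log10(C) + intercept` (defaults: the printed line for the
#' ion, [calibration_line()]), replicated with noise. In `"table"` mode
#' the peak heights are returned directly, ready for
#' [fit_calibration()]; in `"traces"` mode each replicate becomes a full
#' voltammogram so the whole pipeline (peak extraction then regression)
#' is exercised.
#'
#' @param ion `"Cu"` or `"Zn"`.
#' @param concentrations Concentration panel, mol/L (> 0); default
#'   [calibration_concentrations()].
#' @param replicates Replicate measurements per concentration.
#' @param noise A [noise_model()] applied to the peak heights.
#' @param mode `"table"` or `"traces"`.
#' @param slope,intercept Calibration-line coefficients; default the
#'   printed line for `ion`.
#' @param protocol Protocol for `"traces"` mode; default
#'   `swv_protocol(ion)`.
#' @return In `"table"` mode a tibble `concentration_m`, `replicate_id`,
#'   `peak_current_a`; in `"traces"` mode the same plus a `trace`
#'   list-column of voltammograms (heights noisy, traces otherwise
#'   clean).
#' @examples
#' gen_calibration_set("Cu", replicates = 1, noise = noise_model("none"))
#' @export
gen_calibration_set <- function(ion = c("Cu", "Zn"),
                                concentrations = calibration_concentrations(),
                                replicates = 3,
                                noise = noise_model("proportional_gaussian",
                                                    0.02),
                                mode = c("table", "traces"),
                                slope = NULL, intercept = NULL,
                                protocol = NULL) {
  ion <- match.arg(ion)
  mode <- match.arg(mode)
  if (any(concentrations <= 0)) abort_invalid("concentrations must be positive")
  if (replicates < 1) abort_invalid("replicates must be >= 1")
  line <- calibration_line(ion)
  slope <- slope %||% line$slope
  intercept <- intercept %||% line$intercept
  grid <- tidyr::expand_grid(
    concentration_m = as.numeric(concentrations),
    replicate_id = seq_len(replicates)
  )
  heights <- with_noise_seed(noise$seed, apply_noise(
    slope * log10(grid$concentration_m) + intercept, noise
  ))
  if (any(heights < 0)) {
    warn("some implied peak heights were negative; clipped to 0")
    heights <- pmax(heights, 0)
  }
  out <- dplyr::mutate(grid, peak_current_a = heights)
  if (mode == "table") return(out)
  protocol <- protocol %||% swv_protocol(ion)
  dplyr::mutate(out, trace = purrr::map(.data$peak_current_a, function(h) {
    gen_voltammogram(protocol, peak_height = h, noise = noise_model("none"))
  }))
}

#' EGTA treatment schedule presets
#'
#' The time-course of peak-current fractions observed across the
#' barrier-disruption experiment: per timepoint, the fraction of the T0
#' apical peak current remaining apically and the fraction appearing
#' basolaterally. The presets encode the reported apical decreases —
#' Cu: 40% at 1 h and 70% at 2 h (fractions 1, 0.60, 0.30); Zn: 45% and
#' 54% (fractions 1, 0.55, 0.46). Basolateral fractions mirror the
#' apical losses (mass-conserving transfer), which the source reports
#' only qualitatively as rising basolateral peaks.
#'
#' @param ion `"Cu"` or `"Zn"`, or supply all three vectors explicitly.
#' @param timepoint_h Timepoints, h; first must be 0.
#' @param apical_fraction Fraction of the T0 apical peak remaining;
#'   in \[0, 1\], first element 1.
#' @param basolateral_fraction Fraction of the T0 apical peak appearing
#'   basolaterally; in \[0, 1\], first element 0.
#' @return A tibble with the three columns.
#' @examples
#' egta_schedule("Cu")
#' @export
egta_schedule <- function(ion = c("Cu", "Zn"),
                          timepoint_h = c(0, 1, 2),
                          apical_fraction = NULL,
                          basolateral_fraction = NULL) {
  ion <- match.arg(ion)
  apical_fraction <- apical_fraction %||%
    switch(ion, Cu = c(1, 0.60, 0.30), Zn = c(1, 0.55, 0.46))
  basolateral_fraction <- basolateral_fraction %||%
    switch(ion, Cu = c(0, 0.40, 0.70), Zn = c(0, 0.45, 0.54))
  n <- length(timepoint_h)
  if (length(apical_fraction) != n || length(basolateral_fraction) != n) {
    abort_invalid("schedule vectors must have equal length")
  }
  if (any(apical_fraction < 0 | apical_fraction > 1) ||
      any(basolateral_fraction < 0 | basolateral_fraction > 1)) {
    abort_invalid("fractions must lie in [0, 1]")
  }
  if (apical_fraction[1] != 1 || basolateral_fraction[1] != 0) {
    abort_invalid("at T0 the apical fraction must be 1 and the basolateral 0")
  }
  tibble::tibble(
    timepoint_h = as.numeric(timepoint_h),
    apical_fraction = apical_fraction,
    basolateral_fraction = basolateral_fraction
  )
}

#' Generate a full synthetic EGTA transport experiment
#'
#' One voltammogram per (timepoint, compartment): apical traces with
#' peak heights `t0_height * apical_fraction`, basolateral traces with
#' `t0_height * basolateral_fraction` (a zero fraction gives a flat
#' baseline — the "no peak" pre-disruption case). The default T0 height
#' is the calibration-line response at the 1e-6 M dose actually placed
#' apically.
#'
#' @param ion `"Cu"` or `"Zn"`.
#' @param schedule An [egta_schedule()]; default the ion's preset.
#' @param protocol A [swv_protocol()]; default the ion's preset.
#' @param t0_height Apical peak height at T0, A; default from
#'   [calibration_line()] at 1e-6 M.
#' @param noise A [noise_model()] applied per trace.
#' @return A tibble with columns `timepoint_h`, `compartment`, `trace`
#'   (list-column of voltammograms), ready for [extract_transport()].
#' @examples
#' exp <- gen_egta_experiment("Cu", noise = noise_model("none"))
#' transport_report(extract_transport(exp))
#' @export
gen_egta_experiment <- function(ion = c("Cu", "Zn"),
                                schedule = NULL,
                                protocol = NULL,
                                t0_height = NULL,
                                noise = noise_model("proportional_gaussian",
                                                    0.02)) {
  ion <- match.arg(ion)
  schedule <- schedule %||% egta_schedule(ion)
  protocol <- protocol %||% swv_protocol(ion)
  line <- calibration_line(ion)
  t0_height <- t0_height %||% (line$slope * log10(1e-6) + line$intercept)
  if (t0_height <= 0) abort_invalid("t0_height must be positive")
  plan <- tidyr::expand_grid(
    timepoint_h = schedule$timepoint_h,
    compartment = c("apical", "basolateral")
  ) |>
    dplyr::left_join(schedule, by = "timepoint_h") |>
    dplyr::mutate(height = t0_height * ifelse(
      .data$compartment == "apical",
      .data$apical_fraction, .data$basolateral_fraction
    ))
  with_noise_seed(noise$seed, {
    unseeded <- noise_model(noise$kind, noise$level)
    plan$trace <- purrr::map(plan$height, function(h) {
      gen_voltammogram(protocol, peak_height = h, noise = unseeded)
    })
  })
  dplyr::select(plan, "timepoint_h", "compartment", "trace")
}
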