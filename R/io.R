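#' Read and write impedance spectrum CSV files
#'
#' The spectrum dialect is a plain CSV with header
#' `frequency_hz,z_real_ohm_cm2,z_imag_ohm_cm2`, one row per frequency,
#' ascending. Files with shuffled rows are sorted on ingest with a
#' warning; missing columns, non-numeric cells and duplicate frequencies
#' raise a parse error naming the offending line.
#'
#' @param path File path.
#' @param spectrum A spectrum tibble (see [simulate_impedance()]).
#' @return `read_spectrum()` returns an `eis_spectrum` tibble;
#'   `write_spectrum()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_spectrum(simulate_impedance(barrier_preset("pre")), f)
#' read_spectrum(f)
#' @export
read_spectrum <- function(path) {
  df <- read_strict_csv(path, c(frequency_hz = "d", z_real_ohm_cm2 = "d",
                                z_imag_ohm_cm2 = "d"))
  if (is.unsorted(df$frequency_hz, strictly = TRUE)) {
    if (anyDuplicated(df$frequency_hz)) {
      abort_parse(paste0(path, ": duplicate frequencies"))
    }
    warn(paste0(path, ": frequencies out of order; sorted on ingest"))
    df <- dplyr::arrange(df, .data$frequency_hz)
  }
  tryCatch(as_spectrum(df), episens_invalid_input = function(e) {
    abort_parse(paste0(path, ": ", conditionMessage(e)))
  })
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_csv(tibble::as_tibble(as_spectrum(spectrum)), path)
  invisible(path)
}

# Strict typed CSV reader: exact header, no extra/missing columns,
# malformed cells reported with their line numbers.
read_strict_csv <- function(path, col_spec, comment = "") {
  if (!file.exists(path)) abort_parse(paste0("no such file: ", path))
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = do.call(readr::cols, c(
      lapply(col_spec, function(x) readr::col_double()),
      .default = readr::col_skip()
    )),
    comment = comment, show_col_types = FALSE, progress = FALSE
  ))
  missing <- setdiff(names(col_spec), names(df))
  if (length(missing) > 0) {
    abort_parse(paste0(path, ": missing column(s) ",
                       paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_parse(paste0(
      path, ": malformed cells at line(s) ",
      paste(utils::head(unique(probs$row), 5), collapse = ", ")
    ))
  }
  bad <- which(!stats::complete.cases(df[names(col_spec)]))
  if (length(bad) > 0) {
    abort_parse(paste0(path, ": non-numeric or empty cells at data row(s) ",
                       paste(utils::head(bad, 5), collapse = ", ")))
  }
  df
}

#' Read and write voltammogram CSV files
#'
#' The trace dialect is a CSV with header `potential_v,current_a`,
#' preceded by comment lines `# key=value` carrying the square-wave
#' protocol (ion, scan window, step, amplitude, frequency, precondition
#' and cleaning settings). A trace without protocol comments is read as
#' a bare table (no protocol attribute).
#'
#' @param path File path.
#' @param v A voltammogram.
#' @return `read_voltammogram()` returns a `swasv_voltammogram`;
#'   `write_voltammogram()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' v <- gen_voltammogram(swv_protocol("Cu"), noise = noise_model("none"))
#' write_voltammogram(v, f)
#' read_voltammogram(f)
#' @export
read_voltammogram <- function(path) {
  if (!file.exists(path)) abort_parse(paste0("no such file: ", path))
  header <- readLines(path, n = 50)
  meta <- grep("^#", header, value = TRUE)
  protocol <- NULL
  if (length(meta) > 0) {
    kv <- strsplit(sub("^#\\s*", "", meta), "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, `[`, "", 2)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
    num <- function(k) { x <- get(k); if (is.null(x)) NULL else as.numeric(x) }
    ion <- get("ion")
    if (!is.null(ion)) {
      protocol <- tryCatch(
        swv_protocol(
          ion,
          precondition_potential_v = num("precondition_potential_v"),
          precondition_time_s = num("precondition_time_s") %||% 30,
          e_start_v = num("e_start_v"), e_end_v = num("e_end_v"),
          step_v = num("step_v"), amplitude_v = num("amplitude_v"),
          frequency_hz = num("frequency_hz"),
          cleaning_potential_v = num("cleaning_potential_v") %||% 0.3,
          cleaning_time_s = num("cleaning_time_s") %||% 90
        ),
        error = function(e) {
          abort_parse(paste0(path, ": bad protocol header (",
                             conditionMessage(e), ")"))
        }
      )
    }
  }
  df <- read_strict_csv(path, c(potential_v = "d", current_a = "d"),
                        comment = "#")
  tryCatch(as_voltammogram(df, protocol), episens_invalid_input = function(e) {
    abort_parse(paste0(path, ": ", conditionMessage(e)))
  })
}

#' @rdname read_voltammogram
#' @export
write_voltammogram <- function(v, path) {
  v <- as_voltammogram(v)
  proto <- vg_protocol(v)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(proto)) {
    for (k in names(unclass(proto))) {
      writeLines(sprintf("# %s=%s", k, format(proto[[k]], digits = 15)), con)
    }
  }
  writeLines(readr::format_csv(tibble::as_tibble(v)[c("potential_v",
                                                      "current_a")]), con,
             sep = "")
  invisible(path)
}

#' Read a transport-experiment manifest
#'
#' The manifest is a CSV mapping
#' `timepoint_h,compartment,trace_file` with one voltammogram file per
#' (timepoint, compartment); `trace_file` paths are resolved relative to
#' the manifest's directory. The traces are loaded eagerly into a
#' `trace` list-column, ready for [extract_transport()].
#'
#' @param path Manifest file path.
#' @return A tibble with `timepoint_h`, `compartment`, `trace`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_parse(paste0("no such file: ", path))
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      timepoint_h = readr::col_double(),
      compartment = readr::col_character(),
      trace_file = readr::col_character(),
      .default = readr::col_skip()
    ),
    show_col_types = FALSE, progress = FALSE
  ))
  req <- c("timepoint_h", "compartment", "trace_file")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort_parse(paste0(path, ": missing column(s) ",
                       paste(missing, collapse = ", ")))
  }
  bad <- which(!df$compartment %in% c("apical", "basolateral"))
  if (length(bad) > 0) {
    abort_parse(paste0(path, ": compartment must be apical or basolateral",
                       " (data row(s) ", paste(utils::head(bad, 5),
                                               collapse = ", "), ")"))
  }
  dir <- dirname(path)
  dplyr::mutate(
    df[req],
    trace = purrr::map(.data$trace_file, function(f) {
      read_voltammogram(if (grepl("^(/|[A-Za-z]:)", f)) f
                        else file.path(dir, f))
    }),
    trace_file = NULL
  )
}

#' Write a transport experiment to a manifest plus trace files
#'
#' Inverse of [read_manifest()]: one trace CSV per row plus a
#' `manifest.csv` in `dir`.
#'
#' @param experiment A tibble with `timepoint_h`, `compartment`,
#'   `trace` (as from [gen_egta_experiment()]).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_egta_experiment <- function(experiment, dir) {
  req <- c("timepoint_h", "compartment", "trace")
  if (!is.data.frame(experiment) || !all(req %in% names(experiment))) {
    abort_invalid("experiment needs columns timepoint_h, compartment, trace")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trace_t%03d_%s.csv",
                   round(100 * experiment$timepoint_h),
                   experiment$compartment)
  purrr::walk2(experiment$trace, files, function(v, f) {
    write_voltammogram(v, file.path(dir, f))
  })
  manifest <- tibble::tibble(
    timepoint_h = experiment$timepoint_h,
    compartment = experiment$compartment,
    trace_file = files
  )
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' Mean, SD and n across replicate measurements
#'
#' Replicate aggregation in the reporting style `mean +/- SD`: the
#' arithmetic mean and the sample standard deviation (n - 1 denominator;
#' 0 when a single value is supplied).
#'
#' @param values Numeric vector of replicate values (>= 1, finite).
#' @return A one-row tibble with `mean`, `sd`, `n`.
#' @examples
#' aggregate_replicates(c(700, 792))
#' @export
aggregate_replicates <- function(values) {
  if (!is.numeric(values) || length(values) == 0L) {
    abort_invalid("at least one numeric value is required")
  }
  if (any(!is.finite(values))) abort_invalid("values must be finite")
  tibble::tibble(
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else 0,
    n = length(values)
  )
}
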