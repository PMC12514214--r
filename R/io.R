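#' Read a kinetics CSV file
#'
#' Expects a comma-separated file with a header and at least the columns
#' `time_s` and `area_um2` (extra columns are ignored); '.' decimal, UTF-8.
#' Validation errors name the offending data row.
#'
#' @param path Path to the CSV file.
#' @return A [kinetics_series()] with `provenance = "measured"`.
#' @export
read_kinetics_csv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "area_um2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing `%s` at row %d of %s",
                   col, bad[1], path), call. = FALSE)
    }
    df[[col]] <- vals
  }
  nonmono <- which(diff(df$time_s) <= 0)
  if (length(nonmono)) {
    stop(sprintf("`time_s` not strictly increasing at row %d of %s",
                 nonmono[1] + 1L, path), call. = FALSE)
  }
  nonpos <- which(df$area_um2 <= 0)
  if (length(nonpos)) {
    stop(sprintf("non-positive `area_um2` at row %d of %s",
                 nonpos[1], path), call. = FALSE)
  }
  kinetics_series(df$time_s, df$area_um2, provenance = "measured")
}

#' Write a kinetics series (or trajectory) as CSV
#'
#' `write_kinetics_csv()` writes `time_s`, `area_um2` (plus the noiseless
#' model column when present); `write_trajectory_csv()` writes the full
#' simulator output (`time_s`, `volume_fL`, `area_um2`, `iv1`, `iv2`,
#' `iv3`). Values round-trip bit-equal through [read_kinetics_csv()].
#'
#' @param series A [kinetics_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(series, path) {
  df <- as.data.frame(series)
  keep <- intersect(c("time_s", "area_um2", "area_model_um2"), names(df))
  utils::write.csv(format(df[, keep], digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinetics_csv
#' @param trajectory A `cmp_trajectory` from [simulate_system()].
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cmp_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic series
#'
#' JSON sidecar recording the scenario, seed, noise level and ground-truth
#' parameters next to a generated CSV.
#'
#' @param spec The [scenario_spec()] the series was generated from.
#' @param path Output path (conventionally `<series>.json`).
#' @return `path`, invisibly.
#' @export
write_scenario_sidecar <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  gt <- spec$ground_truth
  gt_list <- if (inherits(gt, "phase1_params")) {
    list(model = "phase1", V0 = gt$V0,
         pulse1 = pulse_to_list(gt$pulse1),
         pulse2 = pulse_to_list(gt$pulse2))
  } else if (inherits(gt, "phase3_params")) {
    list(model = "phase3", V0 = gt$V0, pulse3 = pulse_to_list(gt$pulse3),
         V4 = gt$V4, t4 = gt$t4, V_inf = gt$V_inf,
         breakpoint = gt$breakpoint)
  } else {
    list(model = "system", V0 = gt$V0, RC1 = gt$RC1, nx = gt$nx,
         RC2 = gt$RC2, RC3 = gt$RC3, Degt = gt$Degt)
  }
  x <- list(scenario = spec$scenario, seed = spec$seed,
            noise_cv = spec$noise_cv, frame_rate = spec$frame_rate,
            duration = spec$duration, ground_truth = gt_list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
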