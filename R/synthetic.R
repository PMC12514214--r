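#' Sampled single-particle kinetics series
#'
#' Container for a (time, area) trajectory as produced by microscope frame
#' analysis: strictly increasing times in seconds and positive projected
#' areas in \eqn{\mu m^2}, with provenance metadata.
#'
#' @param time_s Numeric vector of times, strictly increasing, seconds.
#' @param area_um2 Numeric vector of areas, positive, \eqn{\mu m^2}.
#' @param provenance `"measured"` or `"synthetic"`.
#' @param scenario Optional scenario tag.
#' @param seed Optional integer noise seed (synthetic series).
#' @param area_model_um2 Optional noiseless model curve carried alongside.
#' @return A data.frame of class `kinetics_series` with attributes
#'   `provenance`, `scenario`, `seed`.
#' @export
kinetics_series <- function(time_s, area_um2,
                            provenance = c("measured", "synthetic"),
                            scenario = NULL, seed = NULL,
                            area_model_um2 = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(time_s), is.numeric(area_um2),
            length(time_s) == length(area_um2), length(time_s) >= 1L)
  if (any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    stop("`area_um2` must be finite and positive", call. = FALSE)
  }
  df <- data.frame(time_s = time_s, area_um2 = area_um2)
  if (!is.null(area_model_um2)) df$area_model_um2 <- area_model_um2
  attr(df, "provenance") <- provenance
  attr(df, "scenario") <- scenario
  attr(df, "seed") <- seed
  class(df) <- c("kinetics_series", "data.frame")
  df
}

#' @export
print.kinetics_series <- function(x, ...) {
  cat(sprintf(
    "<kinetics_series> %d frames, t = [%g, %g] s, A = [%.4g, %.4g] um2 (%s%s)\n",
    nrow(x), x$time_s[1], x$time_s[nrow(x)],
    min(x$area_um2), max(x$area_um2),
    attr(x, "provenance") %||% "unknown",
    if (!is.null(attr(x, "scenario")))
      paste0(", ", attr(x, "scenario")) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.scenarios <- c("sgf_pepsin", "water_ph2", "preacidified_pepsin")

#' Default scenario specification with tabulated ground truth
#'
#' Returns the synthetic-data specification for one of the three experimental
#' scenarios, with the published parameter values as ground truth (loaded
#' from the JSON fixtures shipped under `inst/extdata`):
#' \describe{
#' \item{`sgf_pepsin`}{Medium exchanged for SGF pH 2 with pepsin; the full
#'   three-phase kinetics simulated by the stock-and-flow model
#'   (tabulated simulator parameter set); duration 1800 s.}
#' \item{`water_ph2`}{Acidification to pH 2 in ultrapure water, no pepsin;
#'   Phase I closed form (water column: \eqn{n_1 = 0.0135},
#'   \eqn{t_1^+ = 416.8} s, \eqn{\sigma_1 = 11} s, \eqn{n_2 = 0.0426},
#'   \eqn{t_2^+ = 540} s, \eqn{\sigma_2 = 37.86} s) scaled by a reference
#'   volume, followed by an exponential expansion segment emulating the
#'   dissolution-bound swelling — a plumbing device with no published fitted
#'   model behind it; duration 900 s.}
#' \item{`preacidified_pepsin`}{Particles stored 20 min in SGF pH 2, then
#'   pepsin added; Phase III piecewise model (volumes in pL); duration
#'   900 s.}
#' }
#'
#' @param scenario One of `"sgf_pepsin"`, `"water_ph2"`,
#'   `"preacidified_pepsin"`.
#' @return A list of class `scenario_spec` with fields `scenario`,
#'   `ground_truth`, `duration`, `frame_rate` (2 Hz), `noise_cv` (0.01),
#'   `seed`, and for `water_ph2` additionally `reference_volume_fL`,
#'   `growth_rate` and `growth_start`.
#' @examples
#' scenario_defaults("preacidified_pepsin")$ground_truth$t4  # 141.7
#' @export
scenario_defaults <- function(scenario) {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% .scenarios) {
    stop("unknown scenario; use one of: ",
         paste(.scenarios, collapse = ", "), call. = FALSE)
  }
  extdata <- function(f) system.file("extdata", f, package = "cmpkin",
                                     mustWork = TRUE)
  spec <- switch(scenario,
    sgf_pepsin = list(
      scenario = scenario,
      ground_truth = read_system_config(extdata("table3.json")),
      duration = 1800),
    water_ph2 = {
      gt <- read_phase1_params(extdata("table1_water.json"))
      list(scenario = scenario,
           ground_truth = gt,
           duration = 900,
           reference_volume_fL = 217.45,
           growth_rate = 0.003,
           growth_start = gt$pulse2$center + 3 * gt$pulse2$sigma)
    },
    preacidified_pepsin = list(
      scenario = scenario,
      ground_truth = read_phase3_params(extdata("table2.json")),
      duration = 900))
  spec$frame_rate <- 2
  spec$noise_cv <- 0.01
  spec$seed <- 1L
  class(spec) <- "scenario_spec"
  spec
}

#' Build a (possibly customized) scenario specification
#'
#' Starts from [scenario_defaults()] and overrides any field, e.g. a
#' different noise level, duration, seed, or an alternative ground-truth
#' parameter set.
#'
#' @param scenario Scenario tag, see [scenario_defaults()].
#' @param ... Named overrides of the default fields (`ground_truth`,
#'   `duration`, `frame_rate`, `noise_cv`, `seed`, and for `water_ph2`
#'   `reference_volume_fL`, `growth_rate`, `growth_start`).
#' @return A `scenario_spec`.
#' @examples
#' scenario_spec("preacidified_pepsin", noise_cv = 0, duration = 600)
#' @export
scenario_spec <- function(scenario, ...) {
  spec <- scenario_defaults(scenario)
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(spec), "growth_rate", "growth_start",
                                "reference_volume_fL"))
  if (length(bad)) {
    stop("unknown scenario field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  spec[names(dots)] <- dots
  if (spec$duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (spec$frame_rate <= 0) stop("`frame_rate` must be > 0", call. = FALSE)
  if (spec$noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  spec
}

# noiseless area curve (um^2) of a scenario on a time grid
scenario_model_curve <- function(spec, times) {
  switch(spec$scenario,
    sgf_pepsin = {
      cfg <- spec$ground_truth
      if (cfg$t_end < max(times)) cfg$t_end <- max(times)
      traj <- simulate_system(cfg)
      idx <- as.integer(round(times / cfg$dt)) + 1L
      traj$area_um2[idx]
    },
    water_ph2 = {
      v_rel <- eval_phase1(spec$ground_truth, times)
      ts <- spec$growth_start
      grow <- times > ts
      if (any(grow)) {
        v_at <- eval_phase1(spec$ground_truth, ts)
        v_rel[grow] <- v_at * exp(spec$growth_rate * (times[grow] - ts))
      }
      volume_to_area(v_rel * spec$reference_volume_fL)
    },
    preacidified_pepsin = {
      v_pl <- eval_phase3(spec$ground_truth, times)
      volume_to_area(convert_volume_units(v_pl, "pL", "um3"))
    })
}

#' Generate a synthetic microscope-like area series
#'
#' Evaluates the scenario's noiseless model curve on the uniform frame grid
#' (2 frames per second by default, endpoints inclusive) and applies
#' independent multiplicative lognormal noise with coefficient of variation
#' `noise_cv`. The noise has `meanlog = 0`, i.e. it is unbiased on the
#' median/log scale; its mean exceeds 1 by the lognormal correction factor
#' \eqn{e^{s^2/2}} with \eqn{s^2 = \log(1 + cv^2)} (about \eqn{5\times
#' 10^{-5}} at the default 1% CV). The noiseless curve travels with the
#' series in the `area_model_um2` column.
#'
#' @param spec A [scenario_spec()].
#' @return A [kinetics_series()] with `provenance = "synthetic"`.
#' @examples
#' s <- generate_kinetics(scenario_spec("preacidified_pepsin",
#'                                      noise_cv = 0, duration = 300))
#' head(s)
#' @export
generate_kinetics <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  times <- seq(0, spec$duration, by = 1 / spec$frame_rate)
  model <- scenario_model_curve(spec, times)
  if (spec$noise_cv > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(as.integer(spec$seed))
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    areas <- model * stats::rlnorm(length(model), meanlog = 0,
                                   sdlog = sdlog)
  } else {
    areas <- model
  }
  kinetics_series(times, areas, provenance = "synthetic",
                  scenario = spec$scenario, seed = spec$seed,
                  area_model_um2 = model)
}
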