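# error function via the normal CDF (exact identity)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Gaussian pulse kernel
#'
#' Time-localized (or pH-localized) Gaussian kernel
#' \eqn{g(t) = n \exp(-(t - t^+)^2 / (2\sigma^2))} used both as the
#' insolubility-driven outflow rate of the acid-shrinkage model and as the
#' dips of the casein solubility curve. The kernel is deliberately
#' *unnormalized*: the amplitude `n` is the peak value, so that its definite
#' integral carries the prefactor \eqn{\sqrt{2\pi}/2 \, n \sigma} appearing in
#' the closed-form shrinkage solution.
#'
#' @param n Peak amplitude (\eqn{s^{-1}} as a rate kernel; percent when used
#'   in the solubility curve). Must be non-negative.
#' @param center Pulse center \eqn{t^+} in seconds (or pH units on the pH
#'   axis).
#' @param sigma Width (standard deviation) in seconds; strictly positive.
#' @return An object of class `gaussian_pulse`.
#' @examples
#' p <- gaussian_pulse(n = 0.015, center = 300, sigma = 35.15)
#' gaussian_value(p, 300)  # peak: 0.015
#' @export
gaussian_pulse <- function(n, center, sigma) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (n < 0) stop("pulse amplitude `n` must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("pulse width `sigma` must be > 0", call. = FALSE)
  structure(list(n = n, center = center, sigma = sigma),
            class = "gaussian_pulse")
}

#' @export
print.gaussian_pulse <- function(x, ...) {
  cat(sprintf("<gaussian_pulse> n = %g, center = %g, sigma = %g\n",
              x$n, x$center, x$sigma))
  invisible(x)
}

#' Evaluate a Gaussian pulse
#'
#' @param pulse A [gaussian_pulse()].
#' @param t Time(s) in seconds (vectorized).
#' @return \eqn{n \exp(-(t - t^+)^2/(2\sigma^2))}.
#' @export
gaussian_value <- function(pulse, t) {
  stopifnot(inherits(pulse, "gaussian_pulse"))
  pulse$n * exp(-(t - pulse$center)^2 / (2 * pulse$sigma^2))
}

#' Definite integral of a Gaussian pulse
#'
#' Closed form of \eqn{\int_{t_0}^{t_1} g(t)\,dt} for the unnormalized kernel:
#' \deqn{\frac{\sqrt{2\pi}}{2} n \sigma \left[\mathrm{erf}\!\left(
#'   \frac{t_1 - t^+}{\sqrt2\,\sigma}\right) - \mathrm{erf}\!\left(
#'   \frac{t_0 - t^+}{\sqrt2\,\sigma}\right)\right]}
#' This is the exponent building block of the erf closed-form shrinkage model.
#' `-Inf`/`Inf` limits are allowed; the full-line integral is
#' \eqn{\sqrt{2\pi}\, n \sigma}.
#'
#' @param pulse A [gaussian_pulse()].
#' @param t0,t1 Integration limits in seconds, `t0 <= t1`.
#' @return Dimensionless integral value.
#' @export
gaussian_integral <- function(pulse, t0, t1) {
  stopifnot(inherits(pulse, "gaussian_pulse"))
  if (any(t0 > t1)) stop("need t0 <= t1", call. = FALSE)
  s <- sqrt(2) * pulse$sigma
  sqrt(2 * pi) / 2 * pulse$n * pulse$sigma *
    (erf((t1 - pulse$center) / s) - erf((t0 - pulse$center) / s))
}

#' On/off gate schedules (step, pulse, ramp activation)
#'
#' The chronology of the stock-and-flow model is controlled by binary gates:
#' a `step` switches on at its start time and stays on
#' (\eqn{\sigma^{t^*} = 0} for \eqn{t < t^*}, 1 for \eqn{t \ge t^*}); a
#' `pulse` is on over the half-open window `[start, end)`; a `ramp` is a unit
#' activation held from its start time (only the activation time is
#' specified by the model chronology, so it behaves as a step).
#'
#' @param kind One of `"step"`, `"pulse"`, `"ramp"`.
#' @param start Switch-on time \eqn{t^*} in seconds.
#' @param end End of the window (pulse only); `start < end`.
#' @return An object of class `gate_schedule`.
#' @examples
#' gate_value(gate_schedule("step", 536), c(535.99, 536))  # 0 1
#' gate_value(gate_schedule("pulse", 300, 536), 536)       # 0 (half-open)
#' @export
gate_schedule <- function(kind = c("step", "pulse", "ramp"), start,
                          end = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(start), length(start) == 1L, is.finite(start))
  if (kind == "pulse") {
    if (is.null(end) || !is.numeric(end) || length(end) != 1L ||
        !is.finite(end) || end <= start) {
      stop("a pulse gate needs `end` > `start`", call. = FALSE)
    }
  } else if (!is.null(end)) {
    stop("`end` is only meaningful for pulse gates", call. = FALSE)
  }
  structure(list(kind = kind, start = start, end = end),
            class = "gate_schedule")
}

#' Evaluate a gate schedule
#'
#' Right-continuous: the gate is already on at exactly `start` and (for a
#' pulse) already off at exactly `end`, so back-to-back windows sharing a
#' boundary never double-activate.
#'
#' @param gate A [gate_schedule()].
#' @param t Time(s) in seconds (vectorized).
#' @return 0/1 numeric vector.
#' @export
gate_value <- function(gate, t) {
  stopifnot(inherits(gate, "gate_schedule"))
  if (gate$kind == "pulse") {
    as.numeric(t >= gate$start & t < gate$end)
  } else {
    as.numeric(t >= gate$start)
  }
}

#' Linear time-to-pH mapping during acidification
#'
#' Under gastric-like conditions the medium pH falls approximately linearly
#' with time. The mapping is anchored at the two insolubility peaks of the
#' caseins: \eqn{pH_1^+ = 6.2} reached at \eqn{t_1^+} and \eqn{pH_2^+ = 4.2}
#' (the isoelectric point) at \eqn{t_2^+}:
#' \deqn{pH(t) = pH_1^+ - \frac{t - t_1^+}{t_2^+ - t_1^+} (pH_1^+ - pH_2^+)}
#' The line extrapolates outside \eqn{[t_1^+, t_2^+]}; the mapping is used
#' for axis annotation of the kinetics, not for model dynamics.
#'
#' @param t1_plus,t2_plus Anchor times in seconds, `t1_plus < t2_plus`.
#' @param pH1_plus,pH2_plus Anchor pH values (defaults 6.2 and 4.2, the mean
#'   pH of the two insolubility peaks); `pH1_plus > pH2_plus`.
#' @return An object of class `ph_schedule`.
#' @export
ph_schedule <- function(t1_plus, t2_plus, pH1_plus = 6.2, pH2_plus = 4.2) {
  stopifnot(is.numeric(t1_plus), is.numeric(t2_plus),
            is.numeric(pH1_plus), is.numeric(pH2_plus))
  if (t1_plus >= t2_plus) {
    stop("degenerate pH schedule: need t1_plus < t2_plus", call. = FALSE)
  }
  if (pH1_plus <= pH2_plus) {
    stop("need pH1_plus > pH2_plus (pH decreases with time)", call. = FALSE)
  }
  structure(list(t1_plus = t1_plus, t2_plus = t2_plus,
                 pH1_plus = pH1_plus, pH2_plus = pH2_plus),
            class = "ph_schedule")
}

#' Map time to pH along an acidification schedule
#'
#' @param schedule A [ph_schedule()].
#' @param t Time(s) in seconds (vectorized).
#' @return pH value(s); decreasing and affine in `t`.
#' @export
time_to_ph <- function(schedule, t) {
  stopifnot(inherits(schedule, "ph_schedule"))
  with(schedule,
       pH1_plus - (t - t1_plus) / (t2_plus - t1_plus) * (pH1_plus - pH2_plus))
}

#' pH-dependent casein solubility curve
#'
#' Casein solubility between pH 2 and 7 passes through two minima (near pH 6,
#' protonation-driven aggregation, and near the isoelectric point pH 4.2) and
#' is modelled as 100% minus two Gaussian dips plus a constant offset:
#' \deqn{S(pH) = 100 - \sum_{i=1,2} p_i(n_i, pH_i^+, \sigma_i) + const}
#'
#' @param pulses A list of two [gaussian_pulse()] objects on the pH axis
#'   (amplitudes in percent).
#' @param const Constant offset in percent (default 0).
#' @return An object of class `solubility_params`.
#' @export
solubility_params <- function(pulses, const = 0) {
  stopifnot(is.list(pulses), length(pulses) == 2L,
            all(vapply(pulses, inherits, logical(1), "gaussian_pulse")),
            is.numeric(const), length(const) == 1L, is.finite(const))
  structure(list(pulses = pulses, const = const),
            class = "solubility_params")
}

#' Evaluate the casein solubility curve
#'
#' @param params A [solubility_params()].
#' @param pH pH value(s), vectorized.
#' @return Solubility in percent; bounded above by `100 + const`.
#' @export
solubility_curve <- function(params, pH) {
  stopifnot(inherits(params, "solubility_params"))
  dips <- gaussian_value(params$pulses[[1]], pH) +
    gaussian_value(params$pulses[[2]], pH)
  100 - dips + params$const
}

# ---- JSON plumbing for kernel/gate parameter sets ------------------------

pulse_to_list <- function(p) list(n = p$n, t_plus = p$center, sigma = p$sigma)

pulse_from_list <- function(x) {
  need <- c("n", "t_plus", "sigma")
  if (!all(need %in% names(x))) {
    stop("pulse JSON needs fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  gaussian_pulse(n = x$n, center = x$t_plus, sigma = x$sigma)
}

gate_to_list <- function(g) {
  out <- list(kind = g$kind, start = g$start)
  if (!is.null(g$end)) out$end <- g$end
  out
}

gate_from_list <- function(x) {
  gate_schedule(kind = x$kind, start = x$start, end = x$end)
}
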