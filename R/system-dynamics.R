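#' Configuration of the full stock-and-flow digestion model
#'
#' The particle volume is a single stock changed only by three gated flows,
#' \deqn{dV/dt = -I_{V1} + I_{V2} - I_{V3},}
#' integrated with fixed-step Euler. The default parameter values are the
#' tabulated simulator set for the SGF pH 2 + pepsin experiment; any field
#' can be overridden.
#'
#' \describe{
#' \item{Phase I (acid shrinkage), \eqn{t < t_{pulse1,start}}:}{
#'   \eqn{I_{V1} = V (g_1(t) + g_2(t))}, two Gaussian insolubility pulses.}
#' \item{Phase II (anomalous swelling), active on
#'   \eqn{[t_{pulse1,start}, Degt)}:}{
#'   \eqn{I_{V2} = V g_2(t) + s(V) - \mathrm{pulse2}(t)\, V g_3(t)}. At the
#'   shrinkage minimum the solvent flow reverses, so the tail of \eqn{g_2}
#'   re-enters as inflow; \eqn{s(V)} is a sustained swelling term (see
#'   `phase2_kernel` below); from \eqn{t_{pH2.8}} the pepsin surface
#'   contraction \eqn{g_3} throttles the swelling until \eqn{Degt}.}
#' \item{Phase III (enzymatic decay), from \eqn{Degt}:}{
#'   \eqn{I_{V3} = RC_2 V - RC_3}, a linear decay whose fixed point
#'   \eqn{V_\infty = RC_3/RC_2} sets the final plateau and hence the final
#'   area \eqn{A_\infty = \pi^{1/3}(3 RC_3 / (4 RC_2))^{2/3}}
#'   (see [steady_state_area()]).}
#' }
#'
#' The sustained swelling kernel is pluggable. The default
#' `phase2_kernel = "relative"` uses the power law on relative volume,
#' \eqn{s(V) = RC_1 V_0 (V/V_0)^{nx}}, which keeps \eqn{RC_1} in
#' \eqn{s^{-1}} and reduces to the simple first-order swelling
#' \eqn{RC_1 V} at \eqn{nx = 1}. `"absolute"` uses \eqn{RC_1 V^{nx}} with
#' `V` in fL; note that for \eqn{nx > 1} this form is superlinear and can
#' blow up in finite time at the default rate coefficients.
#'
#' @param V0 Initial volume in fL (default 217.45).
#' @param gauss1,gauss2,gauss3 [gaussian_pulse()] kernels of the two acid
#'   shrinkage steps and the pepsin surface contraction. Defaults:
#'   amplitudes 0.000423, 0.000170, 0.0141; centers 187.5, 300, 510 s;
#'   widths 11, 35.15, 37.16 s.
#' @param RC1 Sustained swelling rate coefficient, \eqn{s^{-1}}
#'   (default 0.0032).
#' @param nx Exponent of the swelling power law (default 1.5).
#' @param RC2 Phase III decay rate coefficient, \eqn{s^{-1}} (default 0.005).
#' @param RC3 Phase III volume change rate, fL/s (default 0.1533).
#' @param t_pulse1_start Start of the swelling window, s (= \eqn{t_2^+},
#'   default 300).
#' @param t_pH28 Start of the pepsin-contraction pulse, s (default 424, the
#'   time pH 2.8 is reached).
#' @param Degt Onset of exponential degradation, s (default 536); ends the
#'   swelling window and the contraction pulse and activates Phase III.
#' @param dt Euler time step, s (default 0.25).
#' @param t_end End of the simulation, s (default 2400).
#' @param phase2_kernel `"relative"` (default) or `"absolute"`, see Details.
#' @param volume_floor Positive floor (fL) the integrator clips to, with a
#'   warning, if a step would drive the volume below it (default 1e-6).
#' @return An object of class `system_config`.
#' @examples
#' cfg <- system_config()
#' steady_state_area(cfg)  # ~11.8 um^2
#' @export
system_config <- function(V0 = 217.45,
                          gauss1 = gaussian_pulse(0.000423, 187.5, 11),
                          gauss2 = gaussian_pulse(0.000170, 300, 35.15),
                          gauss3 = gaussian_pulse(0.0141, 510, 37.16),
                          RC1 = 0.0032, nx = 1.5,
                          RC2 = 0.005, RC3 = 0.1533,
                          t_pulse1_start = 300, t_pH28 = 424, Degt = 536,
                          dt = 0.25, t_end = 2400,
                          phase2_kernel = c("relative", "absolute"),
                          volume_floor = 1e-6) {
  phase2_kernel <- match.arg(phase2_kernel)
  stopifnot(inherits(gauss1, "gaussian_pulse"),
            inherits(gauss2, "gaussian_pulse"),
            inherits(gauss3, "gaussian_pulse"),
            is.numeric(V0), is.numeric(RC1), is.numeric(nx),
            is.numeric(RC2), is.numeric(RC3), is.numeric(dt),
            is.numeric(t_end), is.numeric(volume_floor))
  if (V0 <= 0) stop("`V0` must be > 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (volume_floor <= 0) stop("`volume_floor` must be > 0", call. = FALSE)
  if (RC1 < 0 || RC2 < 0 || RC3 < 0) {
    stop("rate coefficients must be >= 0", call. = FALSE)
  }
  if (!(t_pulse1_start < t_pH28 && t_pH28 < Degt && Degt < t_end)) {
    stop("event chronology must satisfy t_pulse1_start < t_pH28 < Degt ",
         "< t_end", call. = FALSE)
  }
  structure(list(V0 = V0, gauss1 = gauss1, gauss2 = gauss2, gauss3 = gauss3,
                 RC1 = RC1, nx = nx, RC2 = RC2, RC3 = RC3,
                 t_pulse1_start = t_pulse1_start, t_pH28 = t_pH28,
                 Degt = Degt, dt = dt, t_end = t_end,
                 phase2_kernel = phase2_kernel,
                 volume_floor = volume_floor),
            class = "system_config")
}

#' @export
print.system_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<system_config> V0 = %g fL, dt = %g s, t_end = %g s\n",
    "  phase I : g1(n=%g, t+=%g, s=%g), g2(n=%g, t+=%g, s=%g)\n",
    "  phase II: RC1 = %g 1/s, nx = %g (%s kernel), ",
    "g3(n=%g, t+=%g, s=%g)\n",
    "  phase III: RC2 = %g 1/s, RC3 = %g fL/s ",
    "(Vinf = %.4g fL, Ainf = %.4g um2)\n",
    "  chronology: pulse1 [%g, %g), pulse2 [%g, %g), ramp2 from %g\n"),
    x$V0, x$dt, x$t_end,
    x$gauss1$n, x$gauss1$center, x$gauss1$sigma,
    x$gauss2$n, x$gauss2$center, x$gauss2$sigma,
    x$RC1, x$nx, x$phase2_kernel,
    x$gauss3$n, x$gauss3$center, x$gauss3$sigma,
    x$RC2, x$RC3,
    if (x$RC2 > 0) x$RC3 / x$RC2 else NA_real_,
    if (x$RC2 > 0) steady_state_area(x) else NA_real_,
    x$t_pulse1_start, x$Degt, x$t_pH28, x$Degt, x$Degt))
  invisible(x)
}

# sustained swelling term s(V), fL/s
phase2_swell <- function(config, V) {
  if (config$phase2_kernel == "relative") {
    config$RC1 * config$V0 * (V / config$V0)^config$nx
  } else {
    config$RC1 * V^config$nx
  }
}

#' Instantaneous gated flows of the stock-and-flow model
#'
#' Evaluates the three volume flows at time(s) `t` for current volume `V`
#' (see [system_config()] for the flow definitions). Gate boundaries are
#' right-continuous: at exactly \eqn{t = t_{pulse1,start}} the Phase I
#' outflow is already off and the Phase II inflow already on.
#'
#' @param config A [system_config()].
#' @param t Time(s) in seconds (vectorized).
#' @param V Current volume in fL (scalar, or vector matching `t`).
#' @return A data.frame with columns `iv1`, `iv2`, `iv3` in fL/s.
#' @export
system_flows <- function(config, t, V) {
  stopifnot(inherits(config, "system_config"))
  if (any(V <= 0)) stop("`V` must be > 0", call. = FALSE)
  g1 <- gaussian_value(config$gauss1, t)
  g2 <- gaussian_value(config$gauss2, t)
  g3 <- gaussian_value(config$gauss3, t)
  pre    <- as.numeric(t < config$t_pulse1_start)
  pulse1 <- as.numeric(t >= config$t_pulse1_start & t < config$Degt)
  pulse2 <- as.numeric(t >= config$t_pH28 & t < config$Degt)
  ramp2  <- as.numeric(t >= config$Degt)
  data.frame(
    iv1 = pre * V * (g1 + g2),
    iv2 = pulse1 * (V * g2 + phase2_swell(config, V)) - pulse2 * V * g3,
    iv3 = ramp2 * (config$RC2 * V - config$RC3))
}

#' Simulate the full three-phase digestion kinetics
#'
#' Fixed-step Euler integration of the volume balance from \eqn{t = 0}
#' (medium exchange) to `t_end`:
#' \eqn{V(t + dt) = V(t) + dt\,(-I_{V1} + I_{V2} - I_{V3})}. Every step is
#' recorded; the projected area is derived from the volume at each grid
#' point via the spherical approximation. If a step would push the volume
#' below `volume_floor` it is clipped there and a warning is raised once.
#'
#' @param config A [system_config()].
#' @return An object of class `cmp_trajectory`: a data.frame with columns
#'   `time_s`, `volume_fL`, `area_um2`, `iv1`, `iv2`, `iv3`, where the flow
#'   columns hold the flows used for the step starting at that time, so that
#'   `diff(volume_fL) == dt * (-iv1 + iv2 - iv3)[-nrow]` holds exactly
#'   (up to floor clipping).
#' @examples
#' traj <- simulate_system(system_config(t_end = 1200))
#' tail(traj$area_um2, 1)
#' @export
simulate_system <- function(config) {
  stopifnot(inherits(config, "system_config"))
  times <- seq(0, config$t_end, by = config$dt)
  n <- length(times)
  # precompute time-only factors so the state loop is scalar arithmetic
  g1 <- gaussian_value(config$gauss1, times)
  g2 <- gaussian_value(config$gauss2, times)
  g3 <- gaussian_value(config$gauss3, times)
  pre    <- times < config$t_pulse1_start
  pulse1 <- times >= config$t_pulse1_start & times < config$Degt
  pulse2 <- times >= config$t_pH28 & times < config$Degt
  ramp2  <- times >= config$Degt
  k_out <- ifelse(pre, g1 + g2, 0)            # I_V1 = V * k_out
  k_in  <- ifelse(pulse1, g2, 0) - ifelse(pulse2, g3, 0)  # V-linear part of I_V2
  rc1 <- config$RC1; nx <- config$nx; v0 <- config$V0
  rel <- config$phase2_kernel == "relative"
  rc2 <- config$RC2; rc3 <- config$RC3
  dt <- config$dt; floor_v <- config$volume_floor

  vol <- numeric(n); iv1 <- numeric(n); iv2 <- numeric(n); iv3 <- numeric(n)
  vol[1] <- config$V0
  floored <- FALSE
  for (i in seq_len(n - 1L)) {
    V <- vol[i]
    swell <- if (pulse1[i]) {
      if (rel) rc1 * v0 * (V / v0)^nx else rc1 * V^nx
    } else 0
    iv1[i] <- V * k_out[i]
    iv2[i] <- V * k_in[i] + swell
    iv3[i] <- if (ramp2[i]) rc2 * V - rc3 else 0
    Vnext <- V + dt * (-iv1[i] + iv2[i] - iv3[i])
    if (!is.finite(Vnext)) {
      stop(sprintf(
        "integration diverged at step %d (t = %g s): non-finite volume",
        i, times[i]), call. = FALSE)
    }
    if (Vnext < floor_v) {
      Vnext <- floor_v
      floored <- TRUE
    }
    vol[i + 1L] <- Vnext
  }
  # flows at the final grid point (not used for a step)
  fin <- system_flows(config, times[n], vol[n])
  iv1[n] <- fin$iv1; iv2[n] <- fin$iv2; iv3[n] <- fin$iv3
  if (floored) {
    warning("volume hit the positivity floor (", floor_v,
            " fL) and was clipped; check rates/time step", call. = FALSE)
  }
  out <- data.frame(time_s = times, volume_fL = vol,
                    area_um2 = volume_to_area(vol),
                    iv1 = iv1, iv2 = iv2, iv3 = iv3)
  class(out) <- c("cmp_trajectory", "data.frame")
  out
}

#' @export
print.cmp_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cmp_trajectory> %d steps, t = [%g, %g] s, final A = %.4g um2\n",
    nrow(x), x$time_s[1], x$time_s[nrow(x)], x$area_um2[nrow(x)]))
  invisible(x)
}

#' Steady-state projected area of the decay flow
#'
#' The Phase III outflow \eqn{I_{V3} = RC_2 V - RC_3} has fixed point
#' \eqn{V_\infty = RC_3/RC_2}; the corresponding final projected area is
#' \deqn{A_\infty = \pi^{1/3} \left(\tfrac{3}{4} RC_3/RC_2\right)^{2/3}.}
#' Doubling both rate coefficients leaves the result unchanged.
#'
#' @param config A [system_config()] with `RC2 > 0`.
#' @return Area in \eqn{\mu m^2}.
#' @export
steady_state_area <- function(config) {
  stopifnot(inherits(config, "system_config"))
  if (config$RC2 == 0) {
    stop("no steady state: RC2 is zero", call. = FALSE)
  }
  volume_to_area(config$RC3 / config$RC2)
}

# ---- JSON serialization ---------------------------------------------------

#' Read/write a system-model configuration as JSON
#'
#' The fixture `system.file("extdata", "table3.json", package = "cmpkin")`
#' carries the tabulated simulator parameter set for the SGF + pepsin
#' experiment.
#'
#' @param path Path to a JSON file.
#' @return `read_system_config()` returns a [system_config()].
#' @export
read_system_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  args <- list()
  for (f in c("V0", "RC1", "nx", "RC2", "RC3", "t_pulse1_start", "t_pH28",
              "Degt", "dt", "t_end", "phase2_kernel", "volume_floor")) {
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  }
  for (g in c("gauss1", "gauss2", "gauss3")) {
    if (!is.null(x[[g]])) args[[g]] <- pulse_from_list(x[[g]])
  }
  do.call(system_config, args)
}

#' @rdname read_system_config
#' @param config A [system_config()].
#' @export
write_system_config <- function(config, path) {
  stopifnot(inherits(config, "system_config"))
  x <- list(model = "system", V0 = config$V0,
            gauss1 = pulse_to_list(config$gauss1),
            gauss2 = pulse_to_list(config$gauss2),
            gauss3 = pulse_to_list(config$gauss3),
            RC1 = config$RC1, nx = config$nx,
            RC2 = config$RC2, RC3 = config$RC3,
            t_pulse1_start = config$t_pulse1_start, t_pH28 = config$t_pH28,
            Degt = config$Degt, dt = config$dt, t_end = config$t_end,
            phase2_kernel = config$phase2_kernel,
            volume_floor = config$volume_floor)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
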