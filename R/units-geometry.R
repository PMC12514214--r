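#' Convert particle volume to projected area (spherical approximation)
#'
#' Casein microparticles stay spherical throughout swelling and shrinkage, so
#' the microscopically measured circular projection area \eqn{A} and the
#' particle volume \eqn{V} are linked through the radius by
#' \eqn{A = 3V/(4R)}, i.e. \eqn{A = \pi^{1/3} (3V/4)^{2/3}}.
#'
#' @param volume Particle volume in \eqn{\mu m^3} (1 fL = 1 \eqn{\mu m^3}).
#'   Vectorized; all values must be strictly positive.
#' @return Projected area in \eqn{\mu m^2}.
#' @seealso [area_to_volume()] for the inverse, [particle_state()] for a
#'   consistent volume/radius/area triple.
#' @examples
#' volume_to_area(4 / 3 * pi)   # unit sphere -> pi
#' volume_to_area(217.45)       # ~43.7 um^2
#' @export
volume_to_area <- function(volume) {
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume <= 0)) {
    stop("`volume` must be finite and strictly positive (µm³)",
         call. = FALSE)
  }
  pi^(1 / 3) * (3 * volume / 4)^(2 / 3)
}

#' Convert projected area to particle volume (spherical approximation)
#'
#' Inverse of [volume_to_area()]: \eqn{V = (4/3)\sqrt{A^3/\pi}}.
#'
#' @param area Projected circular area in \eqn{\mu m^2}; strictly positive,
#'   vectorized.
#' @return Volume in \eqn{\mu m^3} (= fL).
#' @examples
#' area_to_volume(pi)  # unit sphere -> 4*pi/3
#' @export
area_to_volume <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0)) {
    stop("`area` must be finite and strictly positive (µm²)",
         call. = FALSE)
  }
  4 / 3 * sqrt(area^3 / pi)
}

# exact scale factors to fL (= um^3)
.volume_unit_factors <- c(fL = 1, pL = 1000, um3 = 1)

#' Convert between particle-volume units
#'
#' The closed-form pepsin-decay parameters are tabulated in picolitres while
#' the system-dynamics simulator works in femtolitres; 1 fL = 1 \eqn{\mu m^3}
#' and 1 pL = 1000 fL. Scaling is exact.
#'
#' @param value Numeric vector of volumes.
#' @param from,to Unit tags: one of `"fL"`, `"pL"`, `"um3"`.
#' @return `value` rescaled into `to` units.
#' @examples
#' convert_volume_units(1, "pL", "fL")       # 1000
#' convert_volume_units(217.45, "fL", "pL")  # 0.21745
#' @export
convert_volume_units <- function(value, from, to) {
  if (!is.character(from) || length(from) != 1L ||
      !from %in% names(.volume_unit_factors)) {
    stop("unknown volume unit `from`: use one of ",
         paste(names(.volume_unit_factors), collapse = ", "), call. = FALSE)
  }
  if (!is.character(to) || length(to) != 1L ||
      !to %in% names(.volume_unit_factors)) {
    stop("unknown volume unit `to`: use one of ",
         paste(names(.volume_unit_factors), collapse = ", "), call. = FALSE)
  }
  value * .volume_unit_factors[[from]] / .volume_unit_factors[[to]]
}

#' Consistent state of a spherical particle
#'
#' Builds the mutually consistent (volume, radius, area) triple of a spherical
#' particle from any single one of the three quantities, in the package's
#' canonical units (\eqn{\mu m^3}, \eqn{\mu m}, \eqn{\mu m^2}). The identity
#' \eqn{A = 3V/(4R)} holds for the returned state.
#'
#' @param volume Volume in \eqn{\mu m^3}, or `NULL`.
#' @param radius Radius in \eqn{\mu m}, or `NULL`.
#' @param area Projected area in \eqn{\mu m^2}, or `NULL`.
#'   Exactly one of the three must be given.
#' @return An object of class `particle_state`: a list with fields `volume`,
#'   `radius`, `area`.
#' @examples
#' particle_state(volume = 217.45)
#' @export
particle_state <- function(volume = NULL, radius = NULL, area = NULL) {
  given <- !c(is.null(volume), is.null(radius), is.null(area))
  if (sum(given) != 1L) {
    stop("give exactly one of `volume`, `radius`, `area`", call. = FALSE)
  }
  if (!is.null(radius)) {
    if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
        radius <= 0) {
      stop("`radius` must be a single positive number", call. = FALSE)
    }
    volume <- 4 / 3 * pi * radius^3
  } else if (!is.null(area)) {
    volume <- area_to_volume(area)
    radius <- sqrt(area / pi)
  } else {
    if (length(volume) != 1L) {
      stop("`volume` must be a single positive number", call. = FALSE)
    }
    radius <- (3 * volume / (4 * pi))^(1 / 3)
  }
  out <- list(volume = volume, radius = radius,
              area = volume_to_area(volume))
  class(out) <- "particle_state"
  out
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf(
    "<particle_state> V = %.4g µm³ (fL), R = %.4g µm, A = %.4g µm²\n",
    x$volume, x$radius, x$area))
  invisible(x)
}
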