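#' Physical constants for samara flight analysis
#'
#' Returns the constants used throughout the force balance. Air density
#' defaults to 1.23 kg/m^3 (dry air near 15 degrees C); gravitational
#' acceleration to 9.81 m/s^2. Both can be overridden, e.g. for altitude
#' or temperature corrections.
#'
#' @param g gravitational acceleration, m/s^2.
#' @param rho_air air density, kg/m^3.
#' @return A named list of class `samara_constants` with elements `g` and
#'   `rho_air`.
#' @examples
#' samara_constants()
#' samara_constants(rho_air = 1.18) # warm-day air
#' @export
samara_constants <- function(g = 9.81, rho_air = 1.23) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g), g > 0,
            is.numeric(rho_air), length(rho_air) == 1L, is.finite(rho_air),
            rho_air > 0)
  structure(list(g = g, rho_air = rho_air), class = "samara_constants")
}

#' @export
print.samara_constants <- function(x, ...) {
  cat("Physical constants: g =", x$g, "m/s^2, rho_air =", x$rho_air,
      "kg/m^3\n")
  invisible(x)
}

# degrees <-> radians; angles live in degrees everywhere except inside trig
deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi
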