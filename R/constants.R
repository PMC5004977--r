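#' Physical constants used by the hydrodynamic model
#'
#' The glide model works in a fixed unit convention: gravitational
#' acceleration of 9.8 m s^-2, one standard atmosphere (101,325 Pa) of
#' hydrostatic pressure per 10 m of depth, and a surface air density of
#' 1.225 kg m^-3 (air at 15 degrees C). All are overridable for sensitivity
#' work, but every depth-to-pressure conversion in the package goes through
#' this one object so the convention cannot drift between modules.
#'
#' @param g Gravitational acceleration, m s^-2.
#' @param atm_pa Pascals per standard atmosphere.
#' @param m_per_atm Metres of seawater depth per atmosphere of hydrostatic
#'   pressure.
#' @param rho_air_surface Density of air at the sea surface, kg m^-3.
#'
#' @return A list of class `hydro_constants`.
#' @examples
#' hydro_constants()
#' @export
hydro_constants <- function(g = 9.8, atm_pa = 101325, m_per_atm = 10,
                            rho_air_surface = 1.225) {
  stopifnot(g > 0, atm_pa > 0, m_per_atm > 0, rho_air_surface > 0)
  structure(
    list(g = g, atm_pa = atm_pa, m_per_atm = m_per_atm,
         rho_air_surface = rho_air_surface),
    class = "hydro_constants"
  )
}

#' @export
print.hydro_constants <- function(x, ...) {
  cat("<hydro_constants>",
      sprintf("g = %g m s^-2", x$g),
      sprintf("1 atm = %g Pa = %g m of depth", x$atm_pa, x$m_per_atm),
      sprintf("rho_air(surface) = %g kg m^-3", x$rho_air_surface),
      sep = "\n")
  invisible(x)
}

#' Gauge pressure at depth
#'
#' Converts depth to gauge (above-atmospheric) hydrostatic pressure under
#' the 1 atm per 10 m convention: P = 101325 * d / 10 Pa.
#'
#' @param d Depth in metres, non-negative. Vectorised.
#' @param const A [hydro_constants()] object.
#' @return Gauge pressure in Pa.
#' @examples
#' gauge_pressure(c(0, 10, 1000))
#' @export
gauge_pressure <- function(d, const = hydro_constants()) {
  if (any(d < 0, na.rm = TRUE)) {
    abort("`d` must be non-negative (depth below the surface in metres).",
          class = "glidebuoy_error_domain")
  }
  const$atm_pa * d / const$m_per_atm
}
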