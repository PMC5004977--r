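#' Hydrodynamic glide-model parameters
#'
#' The four unknowns of the glide force balance for one animal (or one
#' animal-dive combination):
#' \describe{
#'   \item{drag_term}{Combined drag term (Cd * A) / m in m^2 kg^-1; scales
#'     the v^2 deceleration. Typical prior mean 10e-6.}
#'   \item{rho_tissue}{Density of the non-gas body compartment at surface
#'     pressure, kg m^-3. A lipid-store body-condition proxy.}
#'   \item{vair_per_mass}{Diving gas volume carried from the surface, ml
#'     per kg of body mass. Compresses with depth by Boyle's law.}
#'   \item{r}{Tissue compressibility: fractional volume decrease per Pa,
#'     order 0.4e-9.}
#' }
#'
#' @param drag_term Combined drag term, m^2 kg^-1, in [5e-6, 20e-6].
#' @param rho_tissue Surface tissue density, kg m^-3, in [800, 1200].
#' @param vair_per_mass Diving gas volume, ml kg^-1, >= 0.
#' @param r Tissue compressibility, Pa^-1, in [0.3e-9, 0.7e-9] (or 0 to
#'   switch compression off).
#' @return A list of class `hydro_params`.
#' @examples
#' hydro_params(12.6e-6, 1031.5, 27.4, 0.38e-9)
#' @export
hydro_params <- function(drag_term = 10e-6, rho_tissue = 1031.5,
                         vair_per_mass = 27.4, r = 0.38e-9) {
  if (drag_term < 5e-6 || drag_term > 20e-6) {
    abort("`drag_term` outside [5e-6, 20e-6] m^2 kg^-1.",
          class = "glidebuoy_error_params")
  }
  if (rho_tissue < 800 || rho_tissue > 1200) {
    abort("`rho_tissue` outside [800, 1200] kg m^-3.",
          class = "glidebuoy_error_params")
  }
  if (vair_per_mass < 0) {
    abort("`vair_per_mass` must be >= 0 ml kg^-1.",
          class = "glidebuoy_error_params")
  }
  if (r != 0 && (r < 0.3e-9 || r > 0.7e-9)) {
    abort("`r` outside [0.3e-9, 0.7e-9] Pa^-1 (use 0 for incompressible).",
          class = "glidebuoy_error_params")
  }
  structure(list(drag_term = drag_term, rho_tissue = rho_tissue,
                 vair_per_mass = vair_per_mass, r = r),
            class = "hydro_params")
}

#' @export
print.hydro_params <- function(x, ...) {
  cat("<hydro_params>",
      sprintf("  (Cd A)/m    = %.3g m^2 kg^-1", x$drag_term),
      sprintf("  rho_tissue  = %.1f kg m^-3 (surface)", x$rho_tissue),
      sprintf("  V_air/m     = %.1f ml kg^-1", x$vair_per_mass),
      sprintf("  r           = %.3g Pa^-1", x$r),
      sep = "\n")
  invisible(x)
}

#' Tissue density at depth
#'
#' Tissue volume shrinks linearly with gauge pressure, V(d) = V0 (1 - r P),
#' so density increases as rho(d) = rho_tissue / (1 - r P(d)). At r =
#' 0.38e-9 Pa^-1 the body compresses by about 0.4% at 1000 m.
#'
#' @param rho_tissue Surface tissue density, kg m^-3.
#' @param r Tissue compressibility, Pa^-1.
#' @param d Depth, m. Vectorised.
#' @param const A [hydro_constants()].
#' @return Tissue density at depth, kg m^-3.
#' @examples
#' tissue_density_at_depth(1031, 0.38e-9, 1000)  # ~1035
#' @export
tissue_density_at_depth <- function(rho_tissue, r, d,
                                    const = hydro_constants()) {
  shrink <- 1 - r * gauge_pressure(d, const)
  if (any(shrink <= 0)) {
    abort("r * P >= 1: tissue volume would vanish; nonphysical state.",
          class = "glidebuoy_error_domain")
  }
  rho_tissue / shrink
}

#' Gas volume and density at depth (Boyle's law)
#'
#' Gas compartments are unprotected from ambient pressure, so volume scales
#' with the inverse of absolute pressure and gas density with absolute
#' pressure: at depth d the absolute pressure is (1 + d/10) atm, the
#' carried volume is the surface volume / (1 + d/10), and the gas density
#' is the surface air density * (1 + d/10).
#'
#' @param vair_per_mass Surface diving gas volume, ml kg^-1.
#' @param d Depth, m. Vectorised.
#' @param const A [hydro_constants()].
#' @return A tibble with columns `depth_m`, `volume_per_mass` (ml kg^-1)
#'   and `rho_air` (kg m^-3).
#' @examples
#' gas_state_at_depth(27.4, c(0, 10, 1000))
#' @export
gas_state_at_depth <- function(vair_per_mass, d, const = hydro_constants()) {
  if (any(vair_per_mass < 0)) {
    abort("`vair_per_mass` must be >= 0.", class = "glidebuoy_error_params")
  }
  q <- 1 + d / const$m_per_atm  # absolute pressure in atm
  tibble::tibble(depth_m = d,
                 volume_per_mass = vair_per_mass / q,
                 rho_air = const$rho_air_surface * q)
}

#' Modelled acceleration during a glide
#'
#' The glide force balance: a gliding body decelerates under drag and
#' accelerates or decelerates under the net buoyancy of its (slightly
#' compressible) tissue and its Boyle's-law gas store,
#'
#' \deqn{a = -\tfrac12 \frac{C_d A}{m}\rho_{sw} v^2
#'       + g \sin p \, \frac{\rho_{sw} - \rho_{tissue}(d)}{\rho_{tissue}(d)}
#'       + g \sin p \, \frac{V_{air}(d)}{m}\,(\rho_{sw} - \rho_{air}(d)).}
#'
#' Drag always opposes motion; both buoyancy terms project onto the
#' movement axis through sin(pitch), with negative pitch meaning downward
#' travel. Lift and induced drag are not modelled, which is why fitted
#' segments are restricted to steep (|pitch| >= 30 deg) glides.
#'
#' @param params A [hydro_params()] object, or a data frame / list with
#'   elements `drag_term`, `rho_tissue`, `vair_per_mass`, `r` (recycled
#'   against the data).
#' @param v Speed along the movement direction, m s^-1, >= 0.
#' @param p Pitch, rad, in [-pi/2, pi/2]; negative = downward.
#' @param d Depth, m.
#' @param rho_sw Ambient seawater density at the glide depth, kg m^-3.
#' @param const A [hydro_constants()].
#' @return Acceleration in m s^-2 (positive = speeding up along the
#'   movement direction). Vectorised.
#' @examples
#' glide_acceleration(hydro_params(12.6e-6, 1031.5, 27.4, 0.38e-9),
#'                    v = 1.5, p = -60 * pi / 180, d = 200, rho_sw = 1027.8)
#' @export
glide_acceleration <- function(params, v, p, d, rho_sw,
                               const = hydro_constants()) {
  if (any(v < 0)) abort("`v` must be >= 0.", class = "glidebuoy_error_domain")
  if (any(abs(p) > pi / 2 + 1e-9)) {
    abort("`p` must lie in [-pi/2, pi/2] rad.", class = "glidebuoy_error_domain")
  }
  drag_term <- params$drag_term
  rho_t_d <- tissue_density_at_depth(params$rho_tissue, params$r, d, const)
  q <- 1 + d / const$m_per_atm
  vair_m3 <- params$vair_per_mass * 1e-6 / q          # m^3 kg^-1 at depth
  rho_air <- const$rho_air_surface * q
  gs <- const$g * sin(p)
  -0.5 * drag_term * rho_sw * v^2 +
    gs * (rho_sw - rho_t_d) / rho_t_d +
    gs * vair_m3 * (rho_sw - rho_air)
}

#' Integrate a glide trajectory
#'
#' Forward integration of the glide force balance at fixed pitch: dv/dt is
#' [glide_acceleration()] at the current state and dd/dt = -v sin(p)
#' (descending at negative pitch increases depth). Classical fixed-step
#' 4th-order Runge-Kutta; ambient density is looked up from
#' `density_profile` at every stage.
#'
#' @param params A [hydro_params()].
#' @param v0 Initial speed, m s^-1 (> 0).
#' @param p Pitch held during the glide, rad.
#' @param d0 Initial depth, m.
#' @param duration Glide duration, s.
#' @param dt Integration step, s (<= 0.1).
#' @param density_profile A `density_profile` function (see
#'   [density_profile_from_ctd()]).
#' @param const A [hydro_constants()].
#' @return A tibble with columns `time_s`, `depth_m`, `speed`; attribute
#'   `truncated` is TRUE if the body came to rest before `duration`.
#' @examples
#' prof <- constant_density_profile(1027)
#' simulate_glide(hydro_params(), 1.5, -pi / 3, 100, 10, 0.05, prof)
#' @export
simulate_glide <- function(params, v0, p, d0, duration, dt = 0.05,
                           density_profile = constant_density_profile(),
                           const = hydro_constants()) {
  if (dt > 0.1 || dt <= 0) {
    abort("`dt` must be in (0, 0.1] s.", class = "glidebuoy_error_numeric")
  }
  if (v0 <= 0) abort("`v0` must be > 0.", class = "glidebuoy_error_domain")
  n <- ceiling(duration / dt)
  time_s <- numeric(n + 1); depth_m <- numeric(n + 1); speed <- numeric(n + 1)
  time_s[1] <- 0; depth_m[1] <- d0; speed[1] <- v0
  deriv <- function(v, d) {
    d <- max(d, 0)
    c(dv = glide_acceleration(params, max(v, 0), p, d, density_profile(d),
                              const),
      dd = -max(v, 0) * sin(p))
  }
  truncated <- FALSE
  i <- 1L
  while (i <= n) {
    v <- speed[i]; d <- depth_m[i]
    k1 <- deriv(v, d)
    k2 <- deriv(v + dt / 2 * k1[1], d + dt / 2 * k1[2])
    k3 <- deriv(v + dt / 2 * k2[1], d + dt / 2 * k2[2])
    k4 <- deriv(v + dt * k3[1], d + dt * k3[2])
    v_new <- v + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    d_new <- d + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    if (v_new <= 0) { truncated <- TRUE; break }
    i <- i + 1L
    time_s[i] <- time_s[i - 1L] + dt
    speed[i] <- v_new
    depth_m[i] <- max(d_new, 0)
  }
  out <- tibble::tibble(time_s = time_s[seq_len(i)],
                        depth_m = depth_m[seq_len(i)],
                        speed = speed[seq_len(i)])
  attr(out, "truncated") <- truncated
  out
}

#' Terminal glide speed
#'
#' The speed at which drag exactly balances net buoyancy along the movement
#' direction (a = 0), found analytically from the force balance: v_term =
#' sqrt(2 b / (k rho_sw)) where b is the net buoyancy acceleration and k
#' the drag term. Returns 0 when buoyancy opposes the movement direction
#' (no terminal speed exists; the glide decays to rest).
#'
#' @inheritParams glide_acceleration
#' @return Terminal speed in m s^-1.
#' @export
terminal_speed <- function(params, p, d, rho_sw, const = hydro_constants()) {
  buoy <- glide_acceleration(params, v = 0, p = p, d = d, rho_sw = rho_sw,
                             const = const)
  ifelse(buoy <= 0, 0, sqrt(2 * buoy / (params$drag_term * rho_sw)))
}
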