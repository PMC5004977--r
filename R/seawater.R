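#' Seawater density (international equation of state, EOS-80)
#'
#' Density of seawater from temperature, practical salinity and gauge
#' pressure, using the UNESCO 1983 international equation of state
#' (Millero & Poisson one-atmosphere equation plus the secant bulk modulus
#' high-pressure terms). The implementation reproduces the published check
#' values to the printed precision (e.g. rho(S=35, T=5, P=0) = 1027.67547
#' kg m^-3; rho(S=35, T=25, P=1000 bar) = 1062.53817 kg m^-3).
#'
#' @param temperature Temperature in degrees C, in [-2, 40].
#' @param salinity Practical salinity (psu), in [0, 42].
#' @param pressure Gauge pressure in Pa (0 at the sea surface).
#' @return Density in kg m^-3. Vectorised over all arguments.
#' @examples
#' seawater_density(0, 35, 0)     # ~1028.11
#' seawater_density(5, 35, 0)     # ~1027.68
#' @export
seawater_density <- function(temperature, salinity, pressure = 0) {
  check_sw_state(temperature, salinity, pressure)
  p_bar <- pressure / 1e5
  rho0 <- sw_rho_1atm(salinity, temperature)
  k <- sw_secant_bulk_modulus(salinity, temperature, p_bar)
  rho0 / (1 - p_bar / k)
}

# One-atmosphere density (Millero & Poisson 1981). T in degC, S in psu.
sw_rho_1atm <- function(S, T) {
  rho_w <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  A <- 8.24493e-1 - 4.0899e-3 * T + 7.6438e-5 * T^2 - 8.2467e-7 * T^3 +
    5.3875e-9 * T^4
  B <- -5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2
  C <- 4.8314e-4
  rho_w + A * S + B * S^1.5 + C * S^2
}

# Secant bulk modulus K(S, T, P), P in bar (UNESCO 1983).
sw_secant_bulk_modulus <- function(S, T, P) {
  Kw <- 19652.21 + 148.4206 * T - 2.327105 * T^2 + 1.360477e-2 * T^3 -
    5.155288e-5 * T^4
  K0 <- Kw +
    S * (54.6746 - 0.603459 * T + 1.09987e-2 * T^2 - 6.1670e-5 * T^3) +
    S^1.5 * (7.944e-2 + 1.6483e-2 * T - 5.3009e-4 * T^2)
  Aw <- 3.239908 + 1.43713e-3 * T + 1.16092e-4 * T^2 - 5.77905e-7 * T^3
  A <- Aw + S * (2.2838e-3 - 1.0981e-5 * T - 1.6078e-6 * T^2) +
    1.91075e-4 * S^1.5
  Bw <- 8.50935e-5 - 6.12293e-6 * T + 5.2787e-8 * T^2
  B <- Bw + S * (-9.9348e-7 + 2.0816e-8 * T + 9.1697e-10 * T^2)
  K0 + A * P + B * P^2
}

check_sw_state <- function(temperature, salinity, pressure) {
  if (any(temperature < -2 | temperature > 40, na.rm = TRUE)) {
    abort("`temperature` outside the valid range [-2, 40] degC.",
          class = "glidebuoy_error_state")
  }
  if (any(salinity < 0 | salinity > 42, na.rm = TRUE)) {
    abort("`salinity` outside the valid range [0, 42] psu.",
          class = "glidebuoy_error_state")
  }
  if (any(pressure < 0, na.rm = TRUE)) {
    abort("`pressure` must be gauge pressure >= 0 Pa.",
          class = "glidebuoy_error_state")
  }
  invisible(TRUE)
}

#' Isothermal compressibility of seawater
#'
#' kappa = (1/rho) (d rho / d P) at constant temperature and salinity,
#' evaluated by a symmetric finite difference on [seawater_density()].
#' The default step of 1e4 Pa is small enough that halving it changes the
#' result by under 1e-3 relative (checked in the test suite), and large
#' enough to stay clear of floating-point cancellation.
#'
#' @inheritParams seawater_density
#' @param step Finite-difference half-step in Pa.
#' @param density_fun Density function `f(temperature, salinity, pressure)`;
#'   defaults to [seawater_density()]. Supplying a stub (e.g. a constant
#'   density) is useful for testing.
#' @return Compressibility in Pa^-1.
#' @examples
#' seawater_compressibility(0, 35, 0) * 1e9   # ~0.463 (in 1e-9 Pa^-1)
#' @export
seawater_compressibility <- function(temperature, salinity, pressure = 0,
                                     step = 1e4,
                                     density_fun = seawater_density) {
  if (step <= 0) abort("`step` must be positive.", class = "glidebuoy_error_numeric")
  p_lo <- pressure - step
  p_hi <- pressure + step
  if (any(p_lo < -1e-9)) {
    # reflect so we never ask the EOS for negative gauge pressure
    p_lo <- pmax(p_lo, 0)
    p_hi <- p_lo + 2 * step
  }
  rho_lo <- density_fun(temperature, salinity, p_lo)
  rho_hi <- density_fun(temperature, salinity, p_hi)
  rho_mid <- density_fun(temperature, salinity, (p_lo + p_hi) / 2)
  kappa <- (rho_hi - rho_lo) / (2 * step) / rho_mid
  if (any(kappa < 0)) {
    abort(paste("Non-monotone density over the finite-difference step;",
                "reduce `step`."),
          class = "glidebuoy_error_numeric")
  }
  kappa
}

#' Build a CTD profile
#'
#' A CTD (conductivity-temperature-depth) cast as a validated tibble:
#' strictly increasing depth grid with temperature and salinity. Casts with
#' temperature only (no conductivity cell) take a constant salinity.
#'
#' @param depth_m Depths in metres, non-negative, strictly increasing.
#' @param temperature_C Temperature at each depth, degC.
#' @param salinity_psu Salinity at each depth (psu), or a single constant;
#'   defaults to 35 for temperature-only casts.
#' @return A tibble of class `ctd_profile` with columns `depth_m`,
#'   `temperature_C`, `salinity_psu` and attribute `max_cast_depth`.
#' @examples
#' ctd_profile(c(0, 50, 200, 600), c(17, 10, 6, 5), 35)
#' @export
ctd_profile <- function(depth_m, temperature_C, salinity_psu = 35) {
  if (length(depth_m) == 0) {
    abort("Empty CTD cast.", class = "glidebuoy_error_input")
  }
  if (any(depth_m < 0) || any(diff(depth_m) <= 0)) {
    abort("`depth_m` must be non-negative and strictly increasing.",
          class = "glidebuoy_error_input")
  }
  salinity_psu <- rep_len(salinity_psu, length(depth_m))
  check_sw_state(temperature_C, salinity_psu, 0)
  out <- tibble::tibble(depth_m = as.numeric(depth_m),
                        temperature_C = as.numeric(temperature_C),
                        salinity_psu = as.numeric(salinity_psu))
  attr(out, "max_cast_depth") <- max(out$depth_m)
  class(out) <- c("ctd_profile", class(out))
  out
}

#' Read a CTD cast from CSV
#'
#' Expects a header with columns `depth_m`, `temperature_C` and optionally
#' `salinity_psu`.
#'
#' @param path CSV file path.
#' @param salinity_default Constant salinity (psu) used when the cast has no
#'   salinity column.
#' @return A [ctd_profile()].
#' @export
read_ctd <- function(path, salinity_default = 35) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("depth_m", "temperature_C") %in% names(df))) {
    abort("CTD CSV needs columns `depth_m` and `temperature_C`.",
          class = "glidebuoy_error_input")
  }
  sal <- if ("salinity_psu" %in% names(df)) df$salinity_psu else salinity_default
  ctd_profile(df$depth_m, df$temperature_C, sal)
}

#' Ambient seawater density profile from a CTD cast
#'
#' Returns a function of depth giving ambient seawater density. Within the
#' cast, temperature and salinity are linearly interpolated; below the
#' deepest cast point they are held constant at their deepest values while
#' hydrostatic pressure keeps increasing with depth, so density keeps
#' rising smoothly past the end of the cast. Pressure is taken from
#' [gauge_pressure()] so the whole package shares one depth-pressure
#' convention.
#'
#' @param profile A [ctd_profile()].
#' @param const A [hydro_constants()] object.
#' @return A function `f(depth_m) -> kg m^-3`, classed `density_profile`,
#'   carrying the source profile as attribute `ctd`.
#' @examples
#' prof <- density_profile_from_ctd(ctd_profile(c(0, 600), c(6, 3), 35))
#' prof(c(0, 300, 1200))
#' @export
density_profile_from_ctd <- function(profile, const = hydro_constants()) {
  if (!inherits(profile, "ctd_profile")) {
    profile <- ctd_profile(profile$depth_m, profile$temperature_C,
                           profile$salinity_psu %||% 35)
  }
  dmax <- attr(profile, "max_cast_depth")
  dgrid <- profile$depth_m
  tgrid <- profile$temperature_C
  sgrid <- profile$salinity_psu
  f <- function(depth_m) {
    if (any(depth_m < 0, na.rm = TRUE)) {
      abort("Depth must be >= 0 m.", class = "glidebuoy_error_domain")
    }
    if (length(dgrid) == 1L) {
      tt <- rep_len(tgrid, length(depth_m))
      ss <- rep_len(sgrid, length(depth_m))
    } else {
      tt <- approx(dgrid, tgrid, xout = pmin(depth_m, dmax), rule = 2)$y
      ss <- approx(dgrid, sgrid, xout = pmin(depth_m, dmax), rule = 2)$y
    }
    seawater_density(tt, ss, gauge_pressure(depth_m, const))
  }
  structure(f, class = c("density_profile", "function"),
            ctd = profile, max_cast_depth = dmax)
}

#' Constant-density profile
#'
#' Degenerate [density_profile_from_ctd()] companion for tests and
#' idealised simulations: the same density at every depth.
#'
#' @param rho Seawater density in kg m^-3.
#' @return A `density_profile` function.
#' @export
constant_density_profile <- function(rho = 1027) {
  structure(function(depth_m) rep_len(rho, length(depth_m)),
            class = c("density_profile", "function"),
            max_cast_depth = Inf)
}

#' @export
print.density_profile <- function(x, ...) {
  dmax <- attr(x, "max_cast_depth")
  cat("<density_profile>\n")
  if (is.finite(dmax)) {
    cat(sprintf("  cast to %g m; T, S held constant below\n", dmax))
  } else {
    cat("  constant density\n")
  }
  probe <- c(0, 100, 500, 1000)
  cat(sprintf("  rho(%4g m) = %.2f kg m^-3\n", probe, x(probe)), sep = "")
  invisible(x)
}

#' Plot a density profile against depth
#'
#' @param object A `density_profile`.
#' @param max_depth Deepest depth to draw, m.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.density_profile <- function(object, max_depth = 1500, ...) {
  d <- seq(0, max_depth, length.out = 200)
  df <- tibble::tibble(depth_m = d, rho_sw = object(d))
  ggplot2::ggplot(df, ggplot2::aes(.data$rho_sw, .data$depth_m)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(rho[sw] ~ (kg ~ m^-3)), y = "Depth (m)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
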