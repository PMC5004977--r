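#' Draw a ground-truth parameter set for simulation
#'
#' Emulates the population structure the hierarchical model assumes:
#' per-individual tissue density and drag term drawn from truncated normal
#' population distributions, per-dive diving gas volume drawn around a
#' global mean, and one global tissue compressibility. Defaults emulate
#' the magnitudes reported for deep-diving beaked whales: individual
#' densities centred on 1031.5 kg m^-3 with a ~1.5 kg m^-3 spread, drag
#' terms around 10e-6 m^2 kg^-1, a 27.4 ml kg^-1 mean gas volume with
#' substantial dive-by-dive variation, and r = 0.38e-9 Pa^-1.
#'
#' @param n_individuals Number of animals.
#' @param n_dives Dives per animal.
#' @param rho_mean,rho_sd Population mean and s.d. of tissue density,
#'   kg m^-3 (truncated to the prior support [800, 1200]).
#' @param drag_mean,drag_sd Population mean and s.d. of the drag term,
#'   m^2 kg^-1 (truncated to [5e-6, 20e-6]).
#' @param gas_mean,gas_sd Global mean and dive-level s.d. of diving gas
#'   volume, ml kg^-1 (dive values truncated to [0, 200]).
#' @param r Global tissue compressibility, Pa^-1.
#' @param seed Integer seed; recorded in the result.
#' @return A list of class `population_truth`: `individuals` (tibble with
#'   `individual_id`, `rho_tissue`, `drag_term`), `dives` (tibble with
#'   `individual_id`, `dive_id`, `vair_per_mass`), `r`, `hyper`, `seed`.
#' @export
draw_truth <- function(n_individuals = 12, n_dives = 12,
                       rho_mean = 1031.5, rho_sd = 1.5,
                       drag_mean = 10e-6, drag_sd = 2e-6,
                       gas_mean = 27.4, gas_sd = 8,
                       r = 0.38e-9, seed = 1) {
  if (rho_mean < 800 || rho_mean > 1200 || drag_mean < 5e-6 ||
      drag_mean > 20e-6 || gas_mean < 5 || gas_mean > 50 ||
      (r != 0 && (r < 0.3e-9 || r > 0.7e-9))) {
    abort("Truth hyperparameters must lie within the prior support.",
          class = "glidebuoy_error_config")
  }
  set.seed(seed)
  ids <- sprintf("whale%02d", seq_len(n_individuals))
  individuals <- tibble::tibble(
    individual_id = ids,
    rho_tissue = rtruncnorm(n_individuals, rho_mean, rho_sd, 800, 1200),
    drag_term = rtruncnorm(n_individuals, drag_mean, drag_sd, 5e-6, 20e-6)
  )
  dives <- tidyr::expand_grid(individual_id = ids,
                              dive_id = seq_len(n_dives))
  dives$vair_per_mass <- rtruncnorm(nrow(dives), gas_mean, gas_sd, 0, 200)
  structure(
    list(individuals = individuals, dives = dives, r = r,
         hyper = list(rho_mean = rho_mean, rho_sd = rho_sd,
                      drag_mean = drag_mean, drag_sd = drag_sd,
                      gas_mean = gas_mean, gas_sd = gas_sd),
         seed = seed),
    class = "population_truth"
  )
}

# rejection-sampled truncated normal (sd = 0 collapses to the mean)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] < lower | out[todo] > upper]
  }
  out
}

#' @export
print.population_truth <- function(x, ...) {
  cat("<population_truth>",
      sprintf("  %d individuals x %d dives (seed %d)",
              nrow(x$individuals), max(x$dives$dive_id), x$seed),
      sprintf("  rho_tissue %.1f-%.1f kg m^-3; drag %.2g-%.2g m^2 kg^-1",
              min(x$individuals$rho_tissue), max(x$individuals$rho_tissue),
              min(x$individuals$drag_term), max(x$individuals$drag_term)),
      sprintf("  gas %.1f-%.1f ml kg^-1; r = %.3g Pa^-1",
              min(x$dives$vair_per_mass), max(x$dives$vair_per_mass), x$r),
      sep = "\n")
  invisible(x)
}

#' Simulate a glide-segment table with known truth
#'
#' Directly emulates the data structure the Bayesian model is fitted to:
#' glide states (speed, pitch, depth, phase) are drawn per the design, the
#' true acceleration is computed through [glide_acceleration()] with each
#' individual's and dive's true parameters, and Gaussian observation noise
#' with per-segment s.d. drawn from `sigma_a_range` (emulating the
#' residual-RMS measurement error of real 5-s segments) is added. The
#' |pitch| >= 30 deg segment filter is enforced by construction.
#'
#' @param truth A [draw_truth()] result.
#' @param glides_per_individual Segments per animal.
#' @param depth_range Depth range of glides, m.
#' @param pitch_range_deg Range of |pitch|, degrees (>= 30).
#' @param speed_range Range of glide speeds, m s^-1.
#' @param sigma_a_range Range of per-segment observation s.d., m s^-2.
#' @param density_profile Ambient density profile.
#' @param seed Integer seed.
#' @param const A [hydro_constants()].
#' @return A glide-segment tibble with the standard fitting columns plus
#'   `a_true` (noise-free model acceleration).
#' @export
simulate_glide_table <- function(truth, glides_per_individual = 240,
                                 depth_range = c(20, 800),
                                 pitch_range_deg = c(30, 80),
                                 speed_range = c(0.7, 2.5),
                                 sigma_a_range = c(0.005, 0.05),
                                 density_profile = NULL, seed = 1,
                                 const = hydro_constants()) {
  if (pitch_range_deg[1] < 30) {
    abort("`pitch_range_deg` must respect the >= 30 deg segment filter.",
          class = "glidebuoy_error_config")
  }
  if (is.null(density_profile)) {
    density_profile <- density_profile_from_ctd(
      ctd_profile(c(0, 50, 200, 600), c(8, 6, 4, 3), 35), const)
  }
  set.seed(seed)
  n_dives <- max(truth$dives$dive_id)
  rows <- purrr::pmap_dfr(truth$individuals, function(individual_id,
                                                      rho_tissue, drag_term) {
    n <- glides_per_individual
    if (n < 1) abort("Design yields zero segments.",
                     class = "glidebuoy_error_config")
    phase <- rep(c("descent", "ascent"), length.out = n)
    pmag <- runif(n, pitch_range_deg[1], pitch_range_deg[2]) * pi / 180
    tibble::tibble(
      individual_id = individual_id,
      dive_id = rep(seq_len(n_dives), length.out = n),
      phase = phase,
      v = runif(n, speed_range[1], speed_range[2]),
      p = ifelse(phase == "descent", -pmag, pmag),
      d = runif(n, depth_range[1], depth_range[2]),
      sigma_a = runif(n, sigma_a_range[1], sigma_a_range[2]),
      rho_tissue = rho_tissue,
      drag_term = drag_term
    )
  })
  rows <- dplyr::left_join(rows, truth$dives,
                           by = c("individual_id", "dive_id"))
  rows$rho_sw <- density_profile(rows$d)
  rows$a_true <- glide_acceleration(
    list(drag_term = rows$drag_term, rho_tissue = rows$rho_tissue,
         vair_per_mass = rows$vair_per_mass, r = truth$r),
    rows$v, rows$p, rows$d, rows$rho_sw, const)
  rows$a <- rows$a_true + rnorm(nrow(rows), 0, rows$sigma_a)
  dplyr::select(rows, "individual_id", "dive_id", "phase", "v", "a",
                "sigma_a", "d", "p", "rho_sw", "a_true")
}

#' Default dive plan for simulated tag records
#'
#' Describes the stroke-and-glide dive structure the record simulator
#' lays out: dive depth, per-phase pitch, cruise speed, stroke/glide
#' duty cycle and sampling rate.
#'
#' @param n_dives Number of dives.
#' @param max_depth Target maximum dive depth, m (<= 1500).
#' @param pitch_descent_deg,pitch_ascent_deg Phase pitch magnitudes, deg.
#' @param cruise_speed Speed stroking relaxes towards, m s^-1.
#' @param glide_s,stroke_s Durations of alternating glide and stroke bouts
#'   within descent/ascent, s.
#' @param bottom_s Bottom-phase duration (stroking), s.
#' @param surface_s Surface interval between dives, s.
#' @param sample_rate Sampling rate of all channels, Hz.
#' @param stroke_freq Stroking oscillation frequency, Hz (0.3-0.5).
#' @param stroke_amp Stroking oscillation amplitude on the dorso-ventral
#'   axis, m s^-2 (must exceed the detection threshold).
#' @param stall_speed Speed below which a glide is abandoned and stroking
#'   resumes, m s^-1. This is what couples gliding time to net buoyancy:
#'   glides against net buoyancy decelerate and stall early, glides aided
#'   by it run their full length.
#' @param accel_noise_sd Accelerometer white-noise s.d., m s^-2.
#' @return A list of class `dive_plan`.
#' @export
dive_plan <- function(n_dives = 3, max_depth = 450,
                      pitch_descent_deg = 60, pitch_ascent_deg = 60,
                      cruise_speed = 1.5, glide_s = 40, stroke_s = 10,
                      bottom_s = 60, surface_s = 120, sample_rate = 5,
                      stroke_freq = 0.4, stroke_amp = 0.8,
                      stall_speed = 1.0, accel_noise_sd = 0.02) {
  stopifnot(max_depth <= 1500, pitch_descent_deg <= 90,
            pitch_ascent_deg <= 90)
  structure(as.list(environment()), class = "dive_plan")
}

#' Simulate a stroke-and-glide tag record
#'
#' Builds a full synthetic deployment for one animal: repeated dives in
#' which descent and ascent alternate stroking bouts (speed relaxing
#' towards the cruise speed with a 5-s time constant, plus a stroking
#' oscillation on the dorso-ventral axis) with passive glide bouts
#' integrated through [simulate_glide()] under the animal's true
#' parameters. Depth is the integral of v sin(pitch); the accelerometer
#' records gravity components consistent with pitch (surge axis
#' g sin(p), dorso-ventral axis g cos(p)) plus the stroking oscillation
#' and white noise. Roll is held near zero so the stability filter passes
#' by construction.
#'
#' @param truth A [draw_truth()] result (first individual is used unless
#'   `individual` names another id).
#' @param plan A [dive_plan()].
#' @param density_profile Ambient density profile.
#' @param seed Integer seed.
#' @param individual Which individual id from `truth` to simulate.
#' @param const A [hydro_constants()].
#' @return A [tag_record()] with attributes `glide_truth` (tibble of
#'   planted glide intervals) and `truth_params`.
#' @export
simulate_tag_record <- function(truth, plan = dive_plan(),
                                density_profile = NULL, seed = 1,
                                individual = NULL,
                                const = hydro_constants()) {
  if (is.null(density_profile)) {
    density_profile <- density_profile_from_ctd(
      ctd_profile(c(0, 50, 200, 600), c(8, 6, 4, 3), 35), const)
  }
  set.seed(seed + 7L)
  ind <- if (is.null(individual)) truth$individuals[1, ] else
    truth$individuals[truth$individuals$individual_id == individual, ]
  if (nrow(ind) != 1) abort("Unknown individual id.",
                            class = "glidebuoy_error_config")
  fs <- plan$sample_rate
  dt <- 1 / fs
  p_desc <- -plan$pitch_descent_deg * pi / 180
  p_asc <- plan$pitch_ascent_deg * pi / 180

  time_s <- c(); depth <- c(); pitch_tr <- c(); speed_tr <- c()
  stroking_tr <- c(); glide_truth <- list()
  t_now <- 0; d_now <- 0

  emit <- function(n, d, p, v, strk) {
    time_s <<- c(time_s, t_now + seq_len(n) * dt - dt)
    depth <<- c(depth, rep_len(d, n)); pitch_tr <<- c(pitch_tr, rep_len(p, n))
    speed_tr <<- c(speed_tr, rep_len(v, n))
    stroking_tr <<- c(stroking_tr, rep_len(strk, n))
    t_now <<- t_now + n * dt
  }

  run_phase <- function(pitch, params, vair, stop_fun) {
    v <- plan$cruise_speed
    repeat {
      # stroking bout: speed relaxes to cruise with a 5-s time constant
      n <- round(plan$stroke_s * fs)
      for (i in seq_len(n)) {
        v <- v + dt * (plan$cruise_speed - v) / 5
        d_now <<- max(0, d_now - v * sin(pitch) * dt)
        emit(1, d_now, pitch, v, TRUE)
        if (stop_fun(d_now)) return(invisible())
      }
      # glide bout: passive dynamics, sub-stepped when the tag rate is coarse
      g0 <- t_now
      k_sub <- max(1L, ceiling(dt / 0.1))
      traj_f <- simulate_glide(params, v0 = v, p = pitch, d0 = d_now,
                               duration = plan$glide_s, dt = dt / k_sub,
                               density_profile = density_profile,
                               const = const)
      traj <- traj_f[seq(1, nrow(traj_f), by = k_sub), , drop = FALSE]
      stalled <- attr(traj_f, "truncated")
      below <- which(traj$speed < plan$stall_speed)
      if (length(below)) {
        traj <- traj[seq_len(max(below[1] - 1, 1)), , drop = FALSE]
        stalled <- TRUE
      }
      ntr <- nrow(traj) - 1
      if (ntr >= 1) {
        for (i in seq_len(ntr) + 1) {
          emit(1, max(0, traj$depth_m[i]), pitch, traj$speed[i], FALSE)
          d_now <<- max(0, traj$depth_m[i])
          if (stop_fun(d_now)) break
        }
      }
      glide_truth[[length(glide_truth) + 1L]] <<-
        tibble::tibble(start_s = g0, end_s = t_now)
      if (stop_fun(d_now)) return(invisible())
      v <- max(tail(traj$speed, 1), 0.3)   # stroking spins speed back up
      if (stalled) v <- max(v, plan$stall_speed)
    }
  }

  for (dv in seq_len(plan$n_dives)) {
    vair <- truth$dives$vair_per_mass[
      truth$dives$individual_id == ind$individual_id &
        truth$dives$dive_id == ((dv - 1) %% max(truth$dives$dive_id) + 1)]
    params <- list(drag_term = ind$drag_term, rho_tissue = ind$rho_tissue,
                   vair_per_mass = vair, r = truth$r)
    # surface interval (stroking at the surface, pitch 0)
    emit(round(plan$surface_s * fs), 0, 0, 0.5, TRUE)
    run_phase(p_desc, params, vair, function(d) d >= plan$max_depth)
    # bottom: level stroking
    emit(round(plan$bottom_s * fs), d_now, 0, plan$cruise_speed, TRUE)
    run_phase(p_asc, params, vair, function(d) d <= 0)
  }
  emit(round(plan$surface_s * fs), 0, 0, 0.5, TRUE)

  n <- length(time_s)
  ph <- 2 * pi * plan$stroke_freq * time_s
  osc <- ifelse(stroking_tr, plan$stroke_amp * sin(ph), 0)
  ax <- const$g * sin(pitch_tr) + rnorm(n, 0, plan$accel_noise_sd)
  ay <- rnorm(n, 0, plan$accel_noise_sd)
  az <- const$g * cos(pitch_tr) + osc + rnorm(n, 0, plan$accel_noise_sd)

  rec <- tag_record(time_s, depth, ax, ay, az,
                    individual_id = ind$individual_id,
                    location = "synthetic")
  attr(rec, "glide_truth") <- dplyr::bind_rows(glide_truth)
  attr(rec, "truth_params") <- c(as.list(ind), r = truth$r)
  attr(rec, "speed_truth") <- speed_tr
  attr(rec, "pitch_truth") <- pitch_tr
  rec
}
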