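#' Pitch and roll from whale-frame acceleration
#'
#' Estimates the gravitational component of the accelerometer signal with a
#' centred moving average, normalises it to |g| = 9.8 m s^-2, and converts
#' to attitude angles: pitch is the arcsine of the normalised gravity
#' component on the designated pitch axis (negative = downward), roll the
#' arctangent of the two remaining axes.
#'
#' Standard biologging geometry puts sin(pitch) on the longitudinal (surge)
#' axis, which is the default here; `pitch_axis = "dorsoventral"` instead
#' takes the arcsine of the dorso-ventral axis, a convention some studies
#' state literally. Samples whose smoothed gravity-magnitude estimate
#' deviates from 9.8 by more than 30% are flagged unreliable (the animal
#' was accelerating too hard for a static-gravity attitude estimate).
#'
#' @param record A [tag_record()], or a data frame with `ax`, `ay`, `az`.
#' @param smoothing_window Moving-average window, s (>= 2 samples).
#' @param sample_rate Sampling rate, Hz; taken from the record attribute
#'   when present.
#' @param pitch_axis `"longitudinal"` (default) or `"dorsoventral"`.
#' @return A tibble with columns `pitch` (rad), `roll` (rad), `g_mag`
#'   (m s^-2, smoothed magnitude) and `reliable` (logical).
#' @export
compute_pitch_roll <- function(record, smoothing_window = 3,
                               sample_rate = attr(record, "sample_rate"),
                               pitch_axis = c("longitudinal", "dorsoventral")) {
  pitch_axis <- match.arg(pitch_axis)
  if (is.null(sample_rate)) {
    abort("`sample_rate` is required when `record` is a plain data frame.",
          class = "glidebuoy_error_input")
  }
  k <- max(2L, round(smoothing_window * sample_rate))
  gx <- moving_average(record$ax, k)
  gy <- moving_average(record$ay, k)
  gz <- moving_average(record$az, k)
  g_mag <- sqrt(gx^2 + gy^2 + gz^2)
  reliable <- abs(g_mag - 9.8) <= 0.3 * 9.8
  scale <- ifelse(g_mag > 0, g_mag, 1)
  nx <- gx / scale; ny <- gy / scale; nz <- gz / scale
  if (pitch_axis == "longitudinal") {
    pitch <- asin(pmin(pmax(nx, -1), 1))
    roll <- atan2(ny, nz)
  } else {
    pitch <- asin(pmin(pmax(nz, -1), 1))
    roll <- atan2(ny, nx)
  }
  tibble::tibble(pitch = pitch, roll = roll, g_mag = g_mag,
                 reliable = reliable)
}

# centred moving average with edge shrinkage (partial windows at the ends)
moving_average <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  half_lo <- floor((k - 1) / 2)
  half_hi <- k - 1 - half_lo
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect glides from the dorso-ventral accelerometer axis
#'
#' Stroking produces an oscillation on the dorso-ventral axis at the stroke
#' frequency; gliding does not. The signal is high-pass filtered (zero-phase
#' forward-backward 2nd-order Butterworth) to remove the gravitational
#' component, the envelope is taken as the absolute filtered signal dilated
#' by a 1-s running-maximum window, and samples where the envelope exceeds
#' `stroke_threshold` are labelled stroking. Glides are the maximal
#' complementary intervals.
#'
#' @param accel_dv Dorso-ventral acceleration series, m s^-2.
#' @param sample_rate Sampling rate, Hz.
#' @param highpass_cutoff High-pass cutoff, Hz, in [0.05, 1]. Default 0.2.
#' @param stroke_threshold Envelope threshold, m s^-2, in (0, 2].
#' @param dilate_window Envelope dilation window, s.
#' @param time_offset Time of the first sample, s (so returned intervals
#'   are on the record clock).
#' @return A tibble of glide intervals with columns `start_s`, `end_s`
#'   (non-overlapping, sorted); attribute `stroking` holds the per-sample
#'   logical.
#' @export
detect_glides <- function(accel_dv, sample_rate, highpass_cutoff = 0.2,
                          stroke_threshold = 0.3, dilate_window = 1,
                          time_offset = 0) {
  if (highpass_cutoff < 0.05 || highpass_cutoff > 1) {
    abort("`highpass_cutoff` must lie in [0.05, 1] Hz.",
          class = "glidebuoy_error_params")
  }
  if (stroke_threshold <= 0 || stroke_threshold > 2) {
    abort("`stroke_threshold` must lie in (0, 2] m s^-2.",
          class = "glidebuoy_error_params")
  }
  n <- length(accel_dv)
  if (n < 5 * sample_rate / highpass_cutoff) {
    abort("Series shorter than 5x the filter impulse-response scale.",
          class = "glidebuoy_error_input")
  }
  bf <- signal::butter(2, highpass_cutoff / (sample_rate / 2), type = "high")
  hp <- signal::filtfilt(bf, accel_dv)
  env <- running_max(abs(hp), max(1L, round(dilate_window * sample_rate)))
  stroking <- env > stroke_threshold
  glides <- runs_to_intervals(!stroking, sample_rate, time_offset)
  attr(glides, "stroking") <- stroking
  glides
}

# centred running maximum over a k-sample window
running_max <- function(x, k) {
  if (k <= 1L) return(x)
  half <- floor(k / 2)
  out <- x
  n <- length(x)
  for (off in seq_len(half)) {
    out <- pmax(out,
                c(x[-seq_len(off)], rep(-Inf, off)),
                c(rep(-Inf, off), x[seq_len(n - off)]))
  }
  out
}

# TRUE-runs of a logical vector as [start_s, end_s] intervals
runs_to_intervals <- function(flag, sample_rate, time_offset = 0) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start_s = time_offset + (starts[keep] - 1L) / sample_rate,
    end_s = time_offset + (ends[keep] - 1L) / sample_rate
  )
}

#' Speed from depth rate and pitch
#'
#' For tags without a speed sensor, speed during steep travel is the rate
#' of change of depth divided by the sine of pitch. The geometry degenerates
#' at shallow pitch, which is why fitted segments require |pitch| >= 30 deg.
#'
#' @param depth_rate Rate of change of depth, m s^-1 (positive down).
#' @param pitch Pitch, rad.
#' @param min_abs_sin_pitch Smallest |sin(pitch)| accepted; default
#'   sin(30 deg).
#' @return Speed, m s^-1 (positive along the movement direction).
#' @export
speed_from_depth_pitch <- function(depth_rate, pitch,
                                   min_abs_sin_pitch = sin(pi / 6)) {
  s <- sin(pitch)
  if (any(abs(s) < min_abs_sin_pitch)) {
    abort("|sin(pitch)| below the steep-glide bound; speed-from-depth undefined.",
          class = "glidebuoy_error_filtered")
  }
  abs(depth_rate / s)
}

#' Calibrate propeller rotation rate against swim speed
#'
#' Builds the per-deployment calibration line for a flywheel/propeller
#' speed sensor: over consecutive 5-s windows in which the whale travelled
#' steeply (mean |sin(pitch)| above `min_abs_sin_pitch`), reference speed
#' is the mean vertical depth rate divided by the mean sine of pitch, and
#' an ordinary least-squares line of reference speed on rotation rate is
#' fitted (the predictive direction, since the line is applied to rotation
#' data).
#'
#' @param record A [tag_record()] with a `prop_rps` column.
#' @param pitch Pitch series, rad (e.g. from [compute_pitch_roll()]).
#' @param window Window length, s.
#' @param min_abs_sin_pitch Qualifying threshold on mean |sin(pitch)|;
#'   0.9 or 0.8 in practice.
#' @return A list of class `speed_calibration` with `slope`
#'   ((m s^-1)/(rot s^-1)), `intercept`, `r_squared`, `resolution`
#'   (= slope x 1 rotation / window) and `n_windows`.
#' @export
calibrate_speed <- function(record, pitch, window = 5,
                            min_abs_sin_pitch = 0.9) {
  if (!min_abs_sin_pitch %in% c(0.8, 0.9)) {
    warn("`min_abs_sin_pitch` outside the conventional {0.8, 0.9}.")
  }
  if (!"prop_rps" %in% names(record)) {
    abort("Record has no `prop_rps` channel.",
          class = "glidebuoy_error_config")
  }
  fs <- attr(record, "sample_rate")
  k <- round(window * fs)
  n_win <- floor(nrow(record) / k)
  if (n_win < 1) {
    abort("Record shorter than one calibration window.",
          class = "glidebuoy_error_input")
  }
  idx <- rep(seq_len(n_win), each = k)
  df <- tibble::tibble(
    win = idx,
    depth = record$depth_m[seq_along(idx)],
    t = record$time_s[seq_along(idx)],
    sinp = sin(pitch[seq_along(idx)]),
    rps = record$prop_rps[seq_along(idx)]
  )
  wins <- df |>
    dplyr::group_by(.data$win) |>
    dplyr::summarise(
      depth_rate = (dplyr::last(.data$depth) - dplyr::first(.data$depth)) /
        (dplyr::last(.data$t) - dplyr::first(.data$t)),
      mean_sinp = mean(.data$sinp),
      mean_abs_sinp = mean(abs(.data$sinp)),
      mean_rps = mean(.data$rps),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$mean_abs_sinp > min_abs_sin_pitch) |>
    dplyr::mutate(ref_speed = abs(.data$depth_rate / .data$mean_sinp))
  if (nrow(wins) < 10) {
    abort(sprintf("Only %d qualifying windows (< 10); cannot calibrate.",
                  nrow(wins)),
          class = "glidebuoy_error_insufficient_data")
  }
  fit <- lm(ref_speed ~ mean_rps, data = wins)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         resolution = unname(coef(fit)[2]) / window,
         n_windows = nrow(wins)),
    class = "speed_calibration"
  )
}

#' @export
print.speed_calibration <- function(x, ...) {
  cat("<speed_calibration>",
      sprintf("  speed = %.4f + %.4f x rotation rate (R^2 = %.3f, n = %d)",
              x$intercept, x$slope, x$r_squared, x$n_windows),
      sprintf("  resolution = %.4f m s^-1", x$resolution),
      sep = "\n")
  invisible(x)
}

#' Split a depth record into dives and dive phases
#'
#' A dive is an excursion deeper than `dive_threshold`. The descent phase
#' runs from the dive start until smoothed pitch first turns positive or
#' depth first exceeds `bottom_fraction` x maximum depth, whichever comes
#' first; the ascent phase is defined symmetrically from the dive end; the
#' bottom phase is what remains between them (empty for V-shaped dives).
#'
#' @param record A [tag_record()].
#' @param pitch Optional pitch series, rad; when omitted, phases use the
#'   depth criterion only.
#' @param dive_threshold Depth defining a dive, m.
#' @param bottom_fraction Fraction of maximum depth bounding descent and
#'   ascent.
#' @param pitch_smooth Smoothing window applied to pitch, s.
#' @return A tibble with one row per dive: `dive_id`, `start_s`, `end_s`,
#'   `descent_end_s`, `ascent_start_s`, `max_depth`.
#' @export
segment_dives <- function(record, pitch = NULL, dive_threshold = 20,
                          bottom_fraction = 0.75, pitch_smooth = 5) {
  fs <- attr(record, "sample_rate")
  deep <- record$depth_m > dive_threshold
  if (!any(deep)) {
    return(tibble::tibble(dive_id = integer(), start_s = numeric(),
                          end_s = numeric(), descent_end_s = numeric(),
                          ascent_start_s = numeric(), max_depth = numeric()))
  }
  if (!is.null(pitch)) pitch <- moving_average(pitch, max(2L, round(pitch_smooth * fs)))
  ivals <- runs_to_intervals(deep, fs, record$time_s[1])
  purrr::imap_dfr(seq_len(nrow(ivals)), function(i, ...) {
    in_dive <- record$time_s >= ivals$start_s[i] &
      record$time_s <= ivals$end_s[i]
    idx <- which(in_dive)
    dd <- record$depth_m[idx]
    tt <- record$time_s[idx]
    maxd <- max(dd)
    i_max <- idx[which.max(dd)]
    # descent: first exit by pitch sign or depth fraction
    cand_desc <- idx[dd >= bottom_fraction * maxd][1]
    if (!is.null(pitch)) {
      up <- idx[pitch[idx] > 0 & idx <= i_max]
      if (length(up)) cand_desc <- min(cand_desc, up[1])
    }
    # ascent: symmetric, scanning back from the end
    deep_idx <- idx[dd >= bottom_fraction * maxd]
    cand_asc <- deep_idx[length(deep_idx)]
    if (!is.null(pitch)) {
      down <- idx[pitch[idx] < 0 & idx >= i_max]
      if (length(down)) cand_asc <- max(cand_asc, down[length(down)])
    }
    if (cand_desc > cand_asc) cand_desc <- cand_asc <- i_max
    tibble::tibble(dive_id = i, start_s = tt[1], end_s = tt[length(tt)],
                   descent_end_s = record$time_s[cand_desc],
                   ascent_start_s = record$time_s[cand_asc],
                   max_depth = maxd)
  })
}

#' Circular variance of roll
#'
#' 1 minus the mean resultant length of the roll angles: 0 for a constant
#' roll, 1 for angles spread uniformly (or antipodally) around the circle.
#' Used as the glide-stability filter (< 0.1 keeps a segment).
#'
#' @param roll Roll angles, rad (>= 2 samples).
#' @return A number in [0, 1].
#' @export
roll_circular_variance <- function(roll) {
  if (length(roll) < 2) {
    abort("Need >= 2 roll samples.", class = "glidebuoy_error_input")
  }
  1 - sqrt(mean(cos(roll))^2 + mean(sin(roll))^2)
}

#' Extract filtered 5-s glide segments
#'
#' Turns detected glide intervals into the analysis table the hydrodynamic
#' model is fitted to. Each glide is partitioned into consecutive 5-s
#' windows from its start; alternate windows (the 1st, 3rd, 5th, ...) are
#' kept to reduce autocorrelation and trailing partial windows are
#' discarded. Per kept window: acceleration `a` is the OLS slope of speed
#' versus time, `sigma_a` the root-mean-square of the fit residuals, and
#' `v`, `d`, `p` the window means of speed, depth and pitch; ambient
#' density is looked up at the mean depth. Windows are dropped unless they
#' are steep (|pitch| >= `min_pitch_deg`), stable (roll circular variance
#' < `max_roll_circvar`) and fall in the descent or ascent phase of a dive.
#'
#' @param record A [tag_record()].
#' @param glides Glide intervals from [detect_glides()].
#' @param phases Dive phases from [segment_dives()].
#' @param density_profile A `density_profile` function.
#' @param attitude Output of [compute_pitch_roll()] for the record;
#'   computed with defaults when omitted.
#' @param speed Per-sample speed, m s^-1. Default `"auto"`: propeller speed
#'   via `calibration` when the record has a `prop_rps` channel, otherwise
#'   depth-rate / sin(pitch). A numeric vector supplies speed directly.
#' @param calibration A [calibrate_speed()] result (required for propeller
#'   records under `"auto"`).
#' @param window Segment length, s.
#' @param min_pitch_deg Minimum |pitch| in degrees.
#' @param max_roll_circvar Stability filter threshold.
#' @return A tibble of glide segments: `individual_id`, `dive_id`, `phase`,
#'   `v`, `a`, `sigma_a`, `d`, `p`, `rho_sw`, `roll_circvar`, plus window
#'   times. Attribute `filter_counts` reports how many windows each filter
#'   dropped.
#' @export
extract_glide_segments <- function(record, glides, phases, density_profile,
                                   attitude = NULL, speed = "auto",
                                   calibration = NULL, window = 5,
                                   min_pitch_deg = 30,
                                   max_roll_circvar = 0.1) {
  fs <- attr(record, "sample_rate")
  id <- attr(record, "individual_id") %||% "unknown"
  if (is.null(attitude)) attitude <- compute_pitch_roll(record)
  pitch <- attitude$pitch; roll <- attitude$roll

  if (identical(speed, "auto")) {
    if ("prop_rps" %in% names(record)) {
      if (is.null(calibration)) {
        abort("Propeller record needs a `calibration` to convert rotation rate to speed.",
              class = "glidebuoy_error_config")
      }
      speed <- calibration$intercept + calibration$slope * record$prop_rps
    } else {
      drate <- central_diff(record$depth_m, 1 / fs)
      s <- sin(pitch)
      speed <- ifelse(abs(s) >= sin(min_pitch_deg * pi / 180) * 0.99,
                      abs(drate / s), NA_real_)
    }
  }
  stopifnot(length(speed) == nrow(record))

  counts <- c(windows = 0L, kept = 0L, partial = 0L, alternate = 0L,
              pitch = 0L, roll = 0L, phase = 0L, speed_na = 0L)
  segs <- list()
  for (gi in seq_len(nrow(glides))) {
    g0 <- glides$start_s[gi]; g1 <- glides$end_s[gi]
    n_full <- floor((g1 - g0) / window)
    if (n_full < 1) next
    for (k in seq_len(n_full)) {
      counts["windows"] <- counts["windows"] + 1L
      if (k %% 2 == 0) { counts["alternate"] <- counts["alternate"] + 1L; next }
      w0 <- g0 + (k - 1) * window
      w1 <- w0 + window
      sel <- which(record$time_s >= w0 & record$time_s < w1)
      if (length(sel) < 3) { counts["partial"] <- counts["partial"] + 1L; next }
      p_mean <- mean(pitch[sel])
      if (abs(p_mean) < min_pitch_deg * pi / 180) {
        counts["pitch"] <- counts["pitch"] + 1L; next
      }
      cv <- roll_circular_variance(roll[sel])
      if (cv >= max_roll_circvar) { counts["roll"] <- counts["roll"] + 1L; next }
      t_mid <- (w0 + w1) / 2
      ph <- phase_of(t_mid, phases)
      if (!ph %in% c("descent", "ascent")) {
        counts["phase"] <- counts["phase"] + 1L; next
      }
      vv <- speed[sel]
      if (anyNA(vv)) { counts["speed_na"] <- counts["speed_na"] + 1L; next }
      tt <- record$time_s[sel] - w0
      fit <- lm(vv ~ tt)
      res <- fit$residuals
      counts["kept"] <- counts["kept"] + 1L
      segs[[length(segs) + 1L]] <- tibble::tibble(
        individual_id = id,
        dive_id = dive_of(t_mid, phases),
        phase = ph,
        start_s = w0, end_s = w1,
        v = mean(vv),
        a = unname(coef(fit)[2]),
        sigma_a = sqrt(mean(res^2)),
        d = mean(record$depth_m[sel]),
        p = p_mean,
        rho_sw = density_profile(mean(record$depth_m[sel])),
        roll_circvar = cv
      )
    }
  }
  out <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble::tibble(individual_id = character(), dive_id = integer(),
                   phase = character(), start_s = numeric(), end_s = numeric(),
                   v = numeric(), a = numeric(), sigma_a = numeric(),
                   d = numeric(), p = numeric(), rho_sw = numeric(),
                   roll_circvar = numeric())
  attr(out, "filter_counts") <- counts
  out
}

central_diff <- function(x, dt) {
  n <- length(x)
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
}

phase_of <- function(t, phases) {
  row <- phases[phases$start_s <= t & phases$end_s >= t, ]
  if (nrow(row) == 0) return("surface")
  row <- row[1, ]
  if (t <= row$descent_end_s) "descent"
  else if (t >= row$ascent_start_s) "ascent"
  else "bottom"
}

dive_of <- function(t, phases) {
  row <- phases[phases$start_s <= t & phases$end_s >= t, ]
  if (nrow(row) == 0) NA_integer_ else as.integer(row$dive_id[1])
}
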