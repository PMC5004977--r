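test_that("pitch and roll recover static orientations", {
  fs <- 5
  t <- seq(0, 20, by = 1 / fs)
  mk <- function(ax, ay, az) {
    tibble::tibble(ax = rep(ax, length(t)), ay = rep(ay, length(t)),
                   az = rep(az, length(t)))
  }
  # 60 degrees downward: surge axis reads -g sin(60)
  att <- compute_pitch_roll(mk(-9.8 * sin(pi / 3), 0, 9.8 * cos(pi / 3)),
                            sample_rate = fs)
  expect_equal(att$pitch, rep(-pi / 3, length(t)), tolerance = 1e-6)
  expect_equal(att$roll, rep(0, length(t)), tolerance = 1e-6)
  # horizontal
  att0 <- compute_pitch_roll(mk(0, 0, 9.8), sample_rate = fs)
  expect_equal(att0$pitch, rep(0, length(t)))
  expect_equal(att0$roll, rep(0, length(t)))
  # straight up: boundary of the arcsine
  att90 <- compute_pitch_roll(mk(9.8, 0, 0), sample_rate = fs)
  expect_equal(att90$pitch, rep(pi / 2, length(t)), tolerance = 1e-6)
  # the dorso-ventral convention reads the arcsine off the z axis
  attz <- compute_pitch_roll(mk(9.8 * cos(pi / 4), 0, 9.8 * sin(pi / 4)),
                             sample_rate = fs, pitch_axis = "dorsoventral")
  expect_equal(attz$pitch, rep(pi / 4, length(t)), tolerance = 1e-6)
})

test_that("dynamic acceleration flags samples as unreliable", {
  fs <- 5
  t <- seq(0, 20, by = 1 / fs)
  df <- tibble::tibble(ax = rep(9.8 * 1.5, length(t)), ay = 0 * t, az = 0 * t)
  att <- compute_pitch_roll(df, sample_rate = fs)
  expect_true(all(!att$reliable))
})

test_that("glide detection separates silence from stroking oscillation", {
  fs <- 10
  # all-quiet record: one glide spanning everything
  n <- 100 * fs + 1
  g <- detect_glides(rep(0, n), fs, highpass_cutoff = 0.2,
                     stroke_threshold = 0.3)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start_s, g$end_s), c(0, 100))
  # continuous 0.4 Hz stroking above threshold: no glide of a second or more
  t <- seq(0, 100, by = 1 / fs)
  s <- detect_glides(0.6 * sin(2 * pi * 0.4 * t), fs, 0.2, 0.3)
  if (nrow(s) > 0) expect_true(all(s$end_s - s$start_s < 1))
  # a stroking bout flanked by silence: two glides around it
  burst <- c(rep(0, 30 * fs), 0.6 * sin(2 * pi * 0.4 * t[1:(30 * fs)]),
             rep(0, 30 * fs))
  gb <- detect_glides(burst, fs, 0.2, 0.3)
  long <- gb[gb$end_s - gb$start_s > 5, ]
  expect_equal(nrow(long), 2)
  expect_lt(long$end_s[1], long$start_s[2])
})

test_that("glide detection validates its inputs", {
  expect_error(detect_glides(rep(0, 1001), 10, highpass_cutoff = 2,
                             stroke_threshold = 0.3),
               class = "glidebuoy_error_params")
  expect_error(detect_glides(rep(0, 1001), 10, 0.2, stroke_threshold = 0),
               class = "glidebuoy_error_params")
  # series shorter than 5x the impulse-response scale of the filter
  expect_error(detect_glides(rep(0, 50), 10, 0.2, 0.3),
               class = "glidebuoy_error_input")
})

test_that("speed calibration recovers a noiseless propeller line", {
  fs <- 1
  t <- seq(0, 999, by = 1)
  v <- 1.5 + 0.5 * sin(2 * pi * t / 400)     # slowly varying speed
  p <- rep(-75 * pi / 180, length(t))
  depth <- 100 + cumsum(-v * sin(p))
  rec <- tag_record(t, depth, 9.8 * sin(p), 0 * t, 9.8 * cos(p),
                    prop_rps = v / 0.5)
  cal <- calibrate_speed(rec, p, window = 5, min_abs_sin_pitch = 0.9)
  expect_equal(cal$slope, 0.5, tolerance = 1e-3)
  expect_equal(cal$intercept, 0, tolerance = 2e-3)
  expect_gt(cal$r_squared, 0.999)
  expect_equal(cal$resolution, cal$slope / 5)
})

test_that("speed calibration refuses shallow-pitch records", {
  fs <- 1
  t <- seq(0, 499, by = 1)
  p <- rep(-20 * pi / 180, length(t))   # |sin p| = 0.34, never qualifies
  depth <- 100 + cumsum(rep(0.5, length(t)))
  rec <- tag_record(t, depth, 9.8 * sin(p), 0 * t, 9.8 * cos(p),
                    prop_rps = rep(3, length(t)))
  expect_error(calibrate_speed(rec, p),
               class = "glidebuoy_error_insufficient_data")
  # and a record without the propeller channel at all
  rec2 <- tag_record(t, depth, 9.8 * sin(p), 0 * t, 9.8 * cos(p))
  expect_error(calibrate_speed(rec2, p), class = "glidebuoy_error_config")
})

test_that("speed from depth rate and pitch follows the geometry", {
  expect_equal(speed_from_depth_pitch(-1.0, -pi / 2), 1.0)
  expect_equal(speed_from_depth_pitch(-0.5, -pi / 6), 1.0)
  expect_error(speed_from_depth_pitch(1, 0), class = "glidebuoy_error_filtered")
})

test_that("dive segmentation separates V dives, square dives and surface records", {
  fs <- 1
  # V dive: linear to 200 m and back
  t <- 0:400
  depth_v <- c(seq(0, 200, length.out = 201), seq(199, 0, length.out = 200))
  rec_v <- tag_record(t, depth_v, 0 * t, 0 * t, rep(9.8, length(t)))
  ph_v <- segment_dives(rec_v, dive_threshold = 20, bottom_fraction = 1)
  expect_equal(nrow(ph_v), 1)
  expect_equal(ph_v$descent_end_s, ph_v$ascent_start_s)
  expect_equal(ph_v$max_depth, 200)
  # square dive: flat bottom produces a bottom phase
  depth_sq <- c(seq(0, 200, length.out = 101), rep(200, 200),
                seq(200, 0, length.out = 100))
  rec_sq <- tag_record(0:400, depth_sq, numeric(401), numeric(401),
                       rep(9.8, 401))
  ph_sq <- segment_dives(rec_sq, dive_threshold = 20, bottom_fraction = 0.75)
  expect_gt(ph_sq$ascent_start_s, ph_sq$descent_end_s)
  # surface-only record: no dives
  rec_s <- tag_record(0:100, rep(2, 101), numeric(101), numeric(101),
                      rep(9.8, 101))
  expect_equal(nrow(segment_dives(rec_s)), 0)
})

test_that("roll circular variance spans constant to antipodal spreads", {
  expect_equal(roll_circular_variance(rep(0.3, 10)), 0, tolerance = 1e-12)
  expect_equal(roll_circular_variance(c(0, pi)), 1, tolerance = 1e-12)
  unif <- seq(0, 2 * pi, length.out = 101)[-101]
  expect_equal(roll_circular_variance(unif), 1, tolerance = 1e-10)
  expect_error(roll_circular_variance(0.1), class = "glidebuoy_error_input")
})

test_that("alternate-drop splitting matches brute-force enumeration for 5-60 s", {
  prof <- constant_density_profile(1027)
  for (dur in 5:60) {
    fx <- make_descent_record(dur)
    segs <- extract_glide_segments(fx$record, fx$glides, fx$phases, prof,
                                   speed = fx$speed)
    expect_equal(nrow(segs), brute_force_segment_count(dur),
                 info = paste("duration", dur))
  }
  # the printed examples: 12 s -> 1 segment (0-5), 17 s -> 2 (0-5, 10-15)
  fx12 <- make_descent_record(12)
  s12 <- extract_glide_segments(fx12$record, fx12$glides, fx12$phases, prof,
                                speed = fx12$speed)
  expect_equal(nrow(s12), 1)
  expect_equal(c(s12$start_s, s12$end_s), c(0, 5))
  fx17 <- make_descent_record(17)
  s17 <- extract_glide_segments(fx17$record, fx17$glides, fx17$phases, prof,
                                speed = fx17$speed)
  expect_equal(nrow(s17), 2)
  expect_equal(s17$start_s, c(0, 10))
})

test_that("segment regression recovers speed slope and window means", {
  prof <- constant_density_profile(1027)
  fx <- make_descent_record(5, dvdt = 0.02)
  segs <- extract_glide_segments(fx$record, fx$glides, fx$phases, prof,
                                 speed = fx$speed)
  expect_equal(segs$a, 0.02, tolerance = 1e-10)
  expect_equal(segs$sigma_a, 0, tolerance = 1e-10)
  expect_equal(segs$v, mean(fx$speed[fx$record$time_s < 5]), tolerance = 1e-10)
  expect_equal(segs$p, -pi / 3, tolerance = 1e-6)
  expect_equal(segs$rho_sw, 1027)
  expect_equal(segs$phase, "descent")
})

test_that("shallow-pitch and bottom-phase windows are filtered out", {
  prof <- constant_density_profile(1027)
  # 20 degree pitch: steepness filter rejects
  fx <- make_descent_record(10, pitch_deg = -20)
  segs <- extract_glide_segments(fx$record, fx$glides, fx$phases, prof,
                                 speed = fx$speed)
  expect_equal(nrow(segs), 0)
  expect_gt(attr(segs, "filter_counts")[["pitch"]], 0)
  # same glide relabelled as bottom phase: phase filter rejects
  fx2 <- make_descent_record(10)
  fx2$phases$descent_end_s <- 0
  fx2$phases$ascent_start_s <- 10
  segs2 <- extract_glide_segments(fx2$record, fx2$glides, fx2$phases, prof,
                                  speed = fx2$speed)
  expect_equal(nrow(segs2), 0)
  expect_gt(attr(segs2, "filter_counts")[["phase"]], 0)
})

test_that("extracted acceleration matches the forward dynamics within 2%", {
  prof <- constant_density_profile(1027)
  pars <- list(drag_term = 12e-6, rho_tissue = 1034, vair_per_mass = 20,
               r = 0.4e-9)
  traj <- simulate_glide(pars, v0 = 2.0, p = -pi / 3, d0 = 100,
                         duration = 5, dt = 0.02, density_profile = prof)
  fit <- lm(speed ~ time_s, data = traj)
  a_fit <- unname(coef(fit)[2])
  # true mean acceleration over the window, from the dynamics themselves
  a_true <- mean(glide_acceleration(pars, traj$speed, -pi / 3, traj$depth_m,
                                    prof(traj$depth_m)))
  expect_equal(a_fit, a_true, tolerance = 0.02)
})

test_that("tag records round-trip through CSV with mean-decimation support", {
  t <- seq(0, 99.8, by = 0.2)
  rec <- tag_record(t, 50 + 10 * sin(t / 20), 0 * t, 0 * t, rep(9.8, length(t)),
                    individual_id = "ha_test")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(rec), path)
  back <- read_tag_record(path, individual_id = "ha_test")
  expect_equal(back$depth_m, rec$depth_m)
  expect_equal(attr(back, "sample_rate"), 5, tolerance = 1e-6)
  # 50 -> 5 Hz style block means
  x <- 1:100
  expect_equal(decimate_series(x, 10), colMeans(matrix(x, nrow = 10)))
  expect_error(tag_record(c(0, 1, 1.5), c(0, 0, 0), 1:3, 1:3, 1:3),
               class = "glidebuoy_error_input")
})
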