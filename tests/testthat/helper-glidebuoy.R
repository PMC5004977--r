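# Shared fixtures, all built in code.

# independent brute-force implementation of the 5-s alternate-drop rule
brute_force_segment_count <- function(duration, window = 5) {
  count <- 0L
  k <- 1L
  while ((k * window) <= duration) {
    if (k %% 2 == 1) count <- count + 1L
    k <- k + 1L
  }
  count
}

# a minimal steep-descent record with directly supplied speed, for
# exercising the segment splitter without the detection stage
make_descent_record <- function(duration, fs = 5, pitch_deg = -60,
                                v0 = 1.5, dvdt = 0.01) {
  t <- seq(0, duration, by = 1 / fs)
  v <- v0 + dvdt * t
  p <- pitch_deg * pi / 180
  depth <- 100 + cumsum(c(0, diff(t)) * -v * sin(p))
  rec <- tag_record(
    time_s = t, depth_m = depth,
    ax = 9.8 * sin(p) + 0 * t,
    ay = 0 * t,
    az = 9.8 * cos(p) + 0 * t,
    individual_id = "fixture"
  )
  list(record = rec, speed = v,
       glides = tibble::tibble(start_s = 0, end_s = duration),
       phases = tibble::tibble(dive_id = 1L, start_s = 0, end_s = duration,
                               descent_end_s = duration,
                               ascent_start_s = duration,
                               max_depth = max(depth)))
}

# small stratified CTD typical of a temperate deep site
fixture_ctd <- function() {
  ctd_profile(depth_m = c(0, 50, 100, 200, 400, 600),
              temperature_C = c(12, 9, 7, 5.5, 5, 4.8),
              salinity_psu = 35)
}

fixture_profile <- function() density_profile_from_ctd(fixture_ctd())
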