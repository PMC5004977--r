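#' Construct a tag record
#'
#' A tag record is a regular time series from one deployment: depth,
#' whale-frame 3-axis acceleration (`ax` longitudinal/surge, positive
#' forward; `ay` lateral; `az` dorso-ventral, positive dorsal) and an
#' optional propeller rotation rate. All channels share one sampling rate
#' here; decimate higher-rate accelerometer channels first (see
#' [decimate_series()]).
#'
#' @param time_s Sample times, s, strictly increasing and regular.
#' @param depth_m Depth, m (>= -1; small negative excursions from surface
#'   sensor noise are tolerated).
#' @param ax,ay,az Whale-frame acceleration, m s^-2 (|.| < 40).
#' @param prop_rps Optional propeller rotation rate, rotations s^-1.
#' @param individual_id Deployment/animal identifier.
#' @param location Optional study-site label.
#' @return A tibble of class `tag_record` with attributes `individual_id`,
#'   `sample_rate` (Hz) and `location`.
#' @export
tag_record <- function(time_s, depth_m, ax, ay, az, prop_rps = NULL,
                       individual_id = "unknown", location = NA_character_) {
  n <- length(time_s)
  stopifnot(length(depth_m) == n, length(ax) == n, length(ay) == n,
            length(az) == n)
  dt <- diff(time_s)
  if (n < 2 || any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt) + 1e-9) {
    abort("`time_s` must be strictly increasing and regularly sampled.",
          class = "glidebuoy_error_input")
  }
  if (any(depth_m < -1)) {
    abort("`depth_m` below -1 m; depth channel looks uncalibrated.",
          class = "glidebuoy_error_input")
  }
  if (any(abs(c(ax, ay, az)) >= 40)) {
    abort("Acceleration magnitude >= 40 m s^-2; not a plausible whale-frame record.",
          class = "glidebuoy_error_input")
  }
  out <- tibble::tibble(time_s = time_s, depth_m = depth_m,
                        ax = ax, ay = ay, az = az)
  if (!is.null(prop_rps)) {
    stopifnot(length(prop_rps) == n)
    out$prop_rps <- prop_rps
  }
  attr(out, "individual_id") <- individual_id
  attr(out, "sample_rate") <- 1 / mean(dt)
  attr(out, "location") <- location
  class(out) <- c("tag_record", class(out))
  out
}

#' Read a tag record from CSV
#'
#' Expects columns `time_s`, `depth_m`, `ax`, `ay`, `az` and optionally
#' `prop_rps`.
#'
#' @param path CSV file path.
#' @param individual_id Identifier for the deployment; defaults to the file
#'   name without extension.
#' @param location Optional study-site label.
#' @return A [tag_record()].
#' @export
read_tag_record <- function(path, individual_id = NULL,
                            location = NA_character_) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "depth_m", "ax", "ay", "az")
  if (!all(need %in% names(df))) {
    abort(paste("Tag CSV needs columns", paste(need, collapse = ", ")),
          class = "glidebuoy_error_input")
  }
  tag_record(df$time_s, df$depth_m, df$ax, df$ay, df$az,
             prop_rps = df[["prop_rps"]],
             individual_id = individual_id %||%
               sub("\\.[^.]*$", "", basename(path)),
             location = location)
}

#' Decimate a series by block means
#'
#' Mean-decimation used to bring high-rate accelerometer channels (e.g.
#' 50 Hz) down to the processing rate (e.g. 5 Hz): consecutive blocks of
#' `factor` samples are averaged. A trailing partial block is dropped.
#'
#' @param x Numeric series.
#' @param factor Integer decimation factor (>= 1).
#' @return The decimated series, length `floor(length(x) / factor)`.
#' @export
decimate_series <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(x)
  n <- floor(length(x) / factor)
  colMeans(matrix(x[seq_len(n * factor)], nrow = factor))
}
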