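#' Percentage of time spent gliding, by dive phase
#'
#' The external validation diagnostic for body-density estimates: for each
#' dive, the percentage of descent-phase and ascent-phase time (below
#' `min_depth`) spent gliding, and their difference (ascent minus descent,
#' percentage points). Denser-than-seawater animals glide more during
#' descent (negative difference); near-neutral animals glide similar
#' amounts in both phases. Each sample is attributed by its own depth.
#'
#' @param record A [tag_record()].
#' @param glides Glide intervals from [detect_glides()].
#' @param phases Dive phases from [segment_dives()].
#' @param min_depth Only samples deeper than this count, m.
#' @return A one-row tibble of class `glide_phase_summary`:
#'   `individual_id`, `pct_glide_descent`, `pct_glide_ascent`,
#'   `difference` (ascent - descent), `sd_descent`, `sd_ascent` (per-dive
#'   s.d.s), `n_dives`. Attribute `per_dive` holds the per-dive table.
#'   Dives never exceeding `min_depth` yield a flagged empty summary.
#' @export
glide_time_by_phase <- function(record, glides, phases, min_depth = 100) {
  fs <- attr(record, "sample_rate")
  id <- attr(record, "individual_id") %||% "unknown"
  in_glide <- rep(FALSE, nrow(record))
  for (i in seq_len(nrow(glides))) {
    in_glide[record$time_s >= glides$start_s[i] &
               record$time_s <= glides$end_s[i]] <- TRUE
  }
  per_dive <- purrr::map_dfr(seq_len(nrow(phases)), function(i) {
    ph <- phases[i, ]
    sel_desc <- record$time_s >= ph$start_s &
      record$time_s <= ph$descent_end_s & record$depth_m > min_depth
    sel_asc <- record$time_s >= ph$ascent_start_s &
      record$time_s <= ph$end_s & record$depth_m > min_depth
    tibble::tibble(
      dive_id = ph$dive_id,
      pct_glide_descent = if (any(sel_desc))
        100 * mean(in_glide[sel_desc]) else NA_real_,
      pct_glide_ascent = if (any(sel_asc))
        100 * mean(in_glide[sel_asc]) else NA_real_
    )
  })
  per_dive <- per_dive[complete.cases(per_dive), , drop = FALSE]
  if (nrow(per_dive) == 0) {
    out <- tibble::tibble(individual_id = id, pct_glide_descent = NA_real_,
                          pct_glide_ascent = NA_real_, difference = NA_real_,
                          sd_descent = NA_real_, sd_ascent = NA_real_,
                          n_dives = 0L)
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- tibble::tibble(
    individual_id = id,
    pct_glide_descent = mean(per_dive$pct_glide_descent),
    pct_glide_ascent = mean(per_dive$pct_glide_ascent),
    sd_descent = if (nrow(per_dive) > 1) sd(per_dive$pct_glide_descent) else 0,
    sd_ascent = if (nrow(per_dive) > 1) sd(per_dive$pct_glide_ascent) else 0,
    n_dives = nrow(per_dive)
  )
  out$difference <- out$pct_glide_ascent - out$pct_glide_descent
  out <- out[, c("individual_id", "pct_glide_descent", "pct_glide_ascent",
                 "difference", "sd_descent", "sd_ascent", "n_dives")]
  attr(out, "per_dive") <- per_dive
  attr(out, "empty") <- FALSE
  class(out) <- c("glide_phase_summary", class(out))
  out
}

#' Posterior summary table
#'
#' Pooled-chain posterior means and equal-tailed 95% credible intervals
#' (2.5% and 97.5% quantiles) with the Gelman-Rubin diagnostic; rows with
#' Rhat > 1.1 are flagged non-converged.
#'
#' @param result A `gb_posterior` from [run_mcmc()].
#' @return A tibble: `parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `rhat`,
#'   `converged`.
#' @export
posterior_summary <- function(result) {
  s <- result$summary
  s$converged <- is.na(s$rhat) | s$rhat <= 1.1
  if (any(!s$converged)) {
    warn(sprintf("%d parameter(s) with Rhat > 1.1 flagged non-converged.",
                 sum(!s$converged)))
  }
  s
}

#' @rdname posterior_summary
#' @param x A `gb_posterior`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gb_posterior <- function(x, ...) posterior_summary(x)

#' One-row model-level summary of a fitted glide model
#'
#' @param x A `gb_posterior`.
#' @param ... Unused.
#' @return A tibble with `dic`, `pD`, `dbar`, `n_parameters`, `n_chains`,
#'   `n_draws`, `max_rhat`.
#' @exportS3Method generics::glance
glance.gb_posterior <- function(x, ...) {
  tibble::tibble(
    dic = x$dic, pD = x$pD, dbar = x$dbar,
    n_parameters = nrow(x$summary),
    n_chains = length(x$chains),
    n_draws = nrow(x$chains[[1]]) * length(x$chains),
    max_rhat = max(x$rhat, na.rm = TRUE)
  )
}

#' Posterior density panels
#'
#' Kernel-density plot of the pooled draws for each monitored parameter.
#'
#' @param object A `gb_posterior`.
#' @param parameters Optional character vector restricting the panels.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gb_posterior <- function(object, parameters = NULL, ...) {
  draws <- as.matrix(object$chains)
  df <- tibble::as_tibble(draws) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter",
                        values_to = "value")
  if (!is.null(parameters)) {
    df <- dplyr::filter(df, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "Posterior density")
}

#' Dive profile with glide and stroking periods
#'
#' The standard record diagnostic: depth against time, coloured by
#' detected locomotion state.
#'
#' @param record A [tag_record()].
#' @param glides Glide intervals from [detect_glides()].
#' @return A ggplot.
#' @export
plot_dive_profile <- function(record, glides) {
  in_glide <- rep(FALSE, nrow(record))
  for (i in seq_len(nrow(glides))) {
    in_glide[record$time_s >= glides$start_s[i] &
               record$time_s <= glides$end_s[i]] <- TRUE
  }
  df <- tibble::tibble(time_s = record$time_s, depth_m = record$depth_m,
                       state = ifelse(in_glide, "glide", "stroke"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$depth_m,
                                   colour = .data$state, group = 1)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(glide = "#2e7d32",
                                            stroke = "#1565c0")) +
    ggplot2::labs(x = "Time (s)", y = "Depth (m)", colour = NULL)
}

#' Write a glide-segment table to CSV
#'
#' @param segments Glide-segment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  readr::write_csv(segments, path)
  invisible(path)
}

#' Read a glide-segment table from CSV
#'
#' @param path CSV written by [write_segments()].
#' @return A glide-segment tibble.
#' @export
read_segments <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
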