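#' Prior specification for the glide model
#'
#' Defaults follow the biologically motivated set used for deep-diving
#' odontocetes: uniform (non-informative) priors for tissue compressibility
#' (0.3e-9 to 0.7e-9 Pa^-1), tissue density (800 to 1200 kg m^-3) and the
#' global diving gas volume (5 to 50 ml kg^-1), and an informative normal
#' prior for the combined drag term, mean 10.0e-6 and s.d. 2.0e-6
#' m^2 kg^-1, truncated to [5.0e-6, 20.0e-6]. The drag prior mean comes
#' from Cd ~ 0.0030 and a surface-area-to-mass ratio typical of a 6800 kg,
#' 23 m^2 whale. Between-group standard deviations in hierarchical models
#' get wide uniform hyperpriors; dive-level gas volumes are truncated to
#' [0, 200] ml kg^-1 (the global [5, 50] prior constrains the mean only).
#'
#' @param rho_lower,rho_upper Tissue density bounds, kg m^-3.
#' @param gas_lower,gas_upper Global gas-volume bounds, ml kg^-1.
#' @param drag_mean,drag_sd,drag_lower,drag_upper Drag-term prior, m^2 kg^-1.
#' @param r_lower,r_upper Compressibility bounds, Pa^-1.
#' @param sd_density_upper,sd_drag_upper,sd_gas_upper Upper bounds of the
#'   uniform hyperpriors on between-group s.d.s (kg m^-3, m^2 kg^-1,
#'   ml kg^-1).
#' @param gas_group_lower,gas_group_upper Support of group-level gas values,
#'   ml kg^-1.
#' @return A list of class `gb_priors`.
#' @export
gb_priors <- function(rho_lower = 800, rho_upper = 1200,
                      gas_lower = 5, gas_upper = 50,
                      drag_mean = 10e-6, drag_sd = 2e-6,
                      drag_lower = 5e-6, drag_upper = 20e-6,
                      r_lower = 0.3e-9, r_upper = 0.7e-9,
                      sd_density_upper = 20, sd_drag_upper = 10e-6,
                      sd_gas_upper = 50,
                      gas_group_lower = 0, gas_group_upper = 200) {
  stopifnot(rho_lower < rho_upper, gas_lower < gas_upper,
            drag_lower < drag_upper, r_lower < r_upper,
            drag_sd > 0, sd_density_upper > 0)
  structure(as.list(environment()), class = "gb_priors")
}

#' Structure of the glide model: at which level each parameter varies
#'
#' Tissue density and the drag term can be shared across all animals
#' (`"global"`), estimated independently per animal (`"individual"`), or
#' drawn per animal from an estimated population distribution
#' (`"hierarchical"`). Diving gas volume can additionally vary by dive
#' (`"dive"` independent, or `"hierarchical-dive"` around an estimated
#' global mean). Tissue compressibility, when included, is always a single
#' global scalar.
#'
#' @param density,drag One of `"global"`, `"individual"`, `"hierarchical"`.
#' @param gas One of `"global"`, `"individual"`, `"dive"`,
#'   `"hierarchical-dive"`.
#' @param compressibility Include the tissue-compressibility term? When
#'   `FALSE` the tissue is modelled as incompressible (r = 0).
#' @return A list of class `gb_model_spec`.
#' @examples
#' gb_model_spec("hierarchical", "hierarchical", "hierarchical-dive")
#' @export
gb_model_spec <- function(density = "global", drag = "global",
                          gas = "global", compressibility = TRUE) {
  density <- match.arg(density, c("global", "individual", "hierarchical"))
  drag <- match.arg(drag, c("global", "individual", "hierarchical"))
  gas <- match.arg(gas, c("global", "individual", "dive", "hierarchical-dive"))
  structure(list(density = density, drag = drag, gas = gas,
                 compressibility = isTRUE(compressibility)),
            class = "gb_model_spec")
}

#' @export
format.gb_model_spec <- function(x, ...) {
  sprintf("density=%s, drag=%s, gas=%s, r=%s",
          x$density, x$drag, x$gas,
          if (x$compressibility) "global" else "excluded")
}

#' @export
print.gb_model_spec <- function(x, ...) {
  cat("<gb_model_spec>", format(x), "\n")
  invisible(x)
}

#' Build the Bayesian glide model
#'
#' Assembles the hierarchical model for a table of 5-s glide segments:
#' each observed segment acceleration is normal around the hydrodynamic
#' forward model's prediction, with the segment's own residual RMS as its
#' known observation s.d., so high-quality segments carry more weight,
#'
#' \deqn{a_i \sim N(\mathrm{glide\_acceleration}(\theta_{g(i)},
#'   v_i, p_i, d_i, \rho_{sw,i}), \sigma_{a,i}^2).}
#'
#' Group-level parameters (per animal, per dive) follow the structure in
#' `spec`; hierarchical levels draw group values from truncated normal
#' population distributions with estimated mean and s.d. The model is
#' emitted as JAGS code plus a prepared data list, together with an
#' R-side deviance evaluator used for DIC and for grid-posterior checks
#' (computed from this package's own [glide_acceleration()], independently
#' of the sampler).
#'
#' @param segments Glide-segment tibble with columns `individual_id`,
#'   `dive_id`, `v`, `p`, `d`, `rho_sw`, `a`, `sigma_a` (see
#'   [extract_glide_segments()] / [simulate_glide_table()]).
#' @param spec A [gb_model_spec()].
#' @param priors A [gb_priors()].
#' @param fixed Named list pinning parameters to constants instead of
#'   estimating them, e.g. `list(drag_term = 12e-6, vair_per_mass = 27.4,
#'   r = 0.38e-9)` leaves only tissue density free. Fixed parameters are
#'   dropped from the prior and the monitors.
#' @param const A [hydro_constants()].
#' @return A list of class `gb_model`: JAGS `code`, `data`, `monitors`,
#'   index maps, and the deviance closure.
#' @export
build_model <- function(segments, spec = gb_model_spec(),
                        priors = gb_priors(), fixed = list(),
                        const = hydro_constants()) {
  need <- c("individual_id", "dive_id", "v", "p", "d", "rho_sw",
            "a", "sigma_a")
  if (nrow(segments) == 0) {
    abort("`segments` is empty.", class = "glidebuoy_error_input")
  }
  if (!all(need %in% names(segments))) {
    abort(paste("`segments` must have columns:", paste(need, collapse = ", ")),
          class = "glidebuoy_error_input")
  }
  if (any(segments$sigma_a <= 0)) {
    abort("`sigma_a` must be positive for every segment.",
          class = "glidebuoy_error_input")
  }
  bad_fixed <- setdiff(names(fixed),
                       c("drag_term", "rho_tissue", "vair_per_mass", "r"))
  if (length(bad_fixed)) {
    abort(paste("Unknown fixed parameter:", paste(bad_fixed, collapse = ", ")),
          class = "glidebuoy_error_config")
  }

  individuals <- sort(unique(segments$individual_id))
  dive_key <- paste(segments$individual_id, segments$dive_id, sep = "//")
  dives <- sort(unique(dive_key))

  # group index per segment for each parameter
  idx_for <- function(level, kind) {
    switch(level,
           global = rep(1L, nrow(segments)),
           individual = ,
           hierarchical = match(segments$individual_id, individuals),
           dive = ,
           `hierarchical-dive` = match(dive_key, dives))
  }
  n_groups <- function(level) {
    switch(level, global = 1L,
           individual = , hierarchical = length(individuals),
           dive = , `hierarchical-dive` = length(dives))
  }

  rho_idx <- idx_for(spec$density)
  drag_idx <- idx_for(spec$drag)
  gas_idx <- idx_for(spec$gas)

  pr <- priors
  lines <- c("model {")
  monitors <- character()

  # --- tissue density (kg m^-3) ---
  if (!is.null(fixed$rho_tissue)) {
    lines <- c(lines, sprintf("  rho_tissue[1] <- %.10g", fixed$rho_tissue))
    rho_idx <- rep(1L, nrow(segments)); n_rho <- 1L
  } else {
    n_rho <- n_groups(spec$density)
    lines <- c(lines, switch(
      spec$density,
      global = sprintf("  rho_tissue[1] ~ dunif(%.15g, %.15g)",
                       pr$rho_lower, pr$rho_upper),
      individual = c(
        sprintf("  for (j in 1:%d) {", n_rho),
        sprintf("    rho_tissue[j] ~ dunif(%.15g, %.15g)",
                pr$rho_lower, pr$rho_upper),
        "  }"),
      hierarchical = c(
        sprintf("  rho_mu ~ dunif(%.15g, %.15g)", pr$rho_lower, pr$rho_upper),
        sprintf("  rho_sd ~ dunif(0, %.15g)", pr$sd_density_upper),
        "  rho_tau <- pow(rho_sd, -2)",
        sprintf("  for (j in 1:%d) {", n_rho),
        sprintf("    rho_tissue[j] ~ dnorm(rho_mu, rho_tau) T(%.15g, %.15g)",
                pr$rho_lower, pr$rho_upper),
        "  }")
    ))
    monitors <- c(monitors, "rho_tissue",
                  if (spec$density == "hierarchical") c("rho_mu", "rho_sd"))
  }

  # --- drag term, worked in units of 1e-6 m^2 kg^-1 ---
  dl <- pr$drag_lower * 1e6; du <- pr$drag_upper * 1e6
  dm <- pr$drag_mean * 1e6; ds <- pr$drag_sd * 1e6
  if (!is.null(fixed$drag_term)) {
    lines <- c(lines, sprintf("  drag6[1] <- %.10g", fixed$drag_term * 1e6))
    drag_idx <- rep(1L, nrow(segments)); n_drag <- 1L
  } else {
    n_drag <- n_groups(spec$drag)
    lines <- c(lines, switch(
      spec$drag,
      global = sprintf("  drag6[1] ~ dnorm(%.15g, %.15g) T(%.15g, %.15g)",
                       dm, ds^-2, dl, du),
      individual = c(
        sprintf("  for (j in 1:%d) {", n_drag),
        sprintf("    drag6[j] ~ dnorm(%.15g, %.15g) T(%.15g, %.15g)", dm, ds^-2, dl, du),
        "  }"),
      hierarchical = c(
        sprintf("  drag_mu6 ~ dnorm(%.15g, %.15g) T(%.15g, %.15g)", dm, ds^-2, dl, du),
        sprintf("  drag_sd6 ~ dunif(0, %.15g)", pr$sd_drag_upper * 1e6),
        "  drag_tau6 <- pow(drag_sd6, -2)",
        sprintf("  for (j in 1:%d) {", n_drag),
        sprintf("    drag6[j] ~ dnorm(drag_mu6, drag_tau6) T(%.15g, %.15g)", dl, du),
        "  }")
    ))
    monitors <- c(monitors, "drag6",
                  if (spec$drag == "hierarchical") c("drag_mu6", "drag_sd6"))
  }

  # --- diving gas volume (ml kg^-1) ---
  if (!is.null(fixed$vair_per_mass)) {
    lines <- c(lines, sprintf("  gas[1] <- %.10g", fixed$vair_per_mass))
    gas_idx <- rep(1L, nrow(segments)); n_gas <- 1L
  } else {
    n_gas <- n_groups(spec$gas)
    lines <- c(lines, switch(
      spec$gas,
      global = sprintf("  gas[1] ~ dunif(%.15g, %.15g)", pr$gas_lower, pr$gas_upper),
      individual = c(
        sprintf("  for (j in 1:%d) {", n_gas),
        sprintf("    gas[j] ~ dunif(%.15g, %.15g)", pr$gas_lower, pr$gas_upper),
        "  }"),
      dive = c(
        sprintf("  for (j in 1:%d) {", n_gas),
        sprintf("    gas[j] ~ dunif(%.15g, %.15g)",
                pr$gas_group_lower, pr$gas_group_upper),
        "  }"),
      `hierarchical-dive` = c(
        sprintf("  gas_mu ~ dunif(%.15g, %.15g)", pr$gas_lower, pr$gas_upper),
        sprintf("  gas_sd ~ dunif(0, %.15g)", pr$sd_gas_upper),
        "  gas_tau <- pow(gas_sd, -2)",
        sprintf("  for (j in 1:%d) {", n_gas),
        sprintf("    gas[j] ~ dnorm(gas_mu, gas_tau) T(%.15g, %.15g)",
                pr$gas_group_lower, pr$gas_group_upper),
        "  }")
    ))
    monitors <- c(monitors, "gas",
                  if (spec$gas == "hierarchical-dive") c("gas_mu", "gas_sd"))
  }

  # --- compressibility, worked in units of 1e-9 Pa^-1 ---
  if (!is.null(fixed$r)) {
    lines <- c(lines, sprintf("  r9 <- %.10g", fixed$r * 1e9))
  } else if (spec$compressibility) {
    lines <- c(lines, sprintf("  r9 ~ dunif(%.15g, %.15g)",
                              pr$r_lower * 1e9, pr$r_upper * 1e9))
    monitors <- c(monitors, "r9")
  } else {
    lines <- c(lines, "  r9 <- 0")
  }

  # --- likelihood: the glide force balance ---
  lines <- c(lines,
    "  for (i in 1:N) {",
    "    rhot[i] <- rho_tissue[rho_idx[i]] / (1 - r9 * P9[i])",
    paste0("    mu[i] <- -0.5e-6 * drag6[drag_idx[i]] * rho_sw[i] * v2[i]",
           " + gsinp[i] * (rho_sw[i] - rhot[i]) / rhot[i]",
           " + gsinp[i] * gas[gas_idx[i]] * 1.0E-6 / q[i]",
           " * (rho_sw[i] - rho_air[i])"),
    "    a[i] ~ dnorm(mu[i], prec[i])",
    "  }",
    "}")

  q <- 1 + segments$d / const$m_per_atm
  data <- list(
    N = nrow(segments),
    a = segments$a,
    v2 = segments$v^2,
    gsinp = const$g * sin(segments$p),
    rho_sw = segments$rho_sw,
    P9 = 1e-9 * gauge_pressure(segments$d, const),
    q = q,
    rho_air = const$rho_air_surface * q,
    prec = segments$sigma_a^-2,
    rho_idx = rho_idx,
    drag_idx = drag_idx,
    gas_idx = gas_idx
  )

  model <- structure(
    list(kind = "glide", code = paste(lines, collapse = "\n"),
         data = data, monitors = monitors, spec = spec, priors = priors,
         fixed = fixed, const = const, segments = segments,
         individuals = individuals, dives = dives,
         n_rho = n_rho, n_drag = n_drag, n_gas = n_gas),
    class = "gb_model"
  )
  model$deviance <- make_deviance_fun(model)
  model
}

#' @export
print.gb_model <- function(x, ...) {
  cat("<gb_model>", format(x$spec), "\n")
  cat(sprintf("  %d segments, %d individuals, %d dives\n",
              x$data$N, length(x$individuals), length(x$dives)))
  cat(sprintf("  free parameter blocks: %s\n",
              paste(x$monitors, collapse = ", ")))
  invisible(x)
}

# Deviance of the glide likelihood at one draw (named vector of monitored
# parameters). Recomputes mu through glide_acceleration(), not through
# JAGS, so DIC and the grid oracle are an independent route through the
# forward model.
make_deviance_fun <- function(model) {
  seg <- model$segments
  const <- model$const
  fx <- model$fixed
  spec <- model$spec
  d_rho <- model$data$rho_idx
  d_drag <- model$data$drag_idx
  d_gas <- model$data$gas_idx
  function(draw) {
    get_block <- function(base, n) {
      if (n == 1L && !is.na(match(base, names(draw)))) return(draw[[base]])
      unname(draw[paste0(base, "[", seq_len(n), "]")])
    }
    rho_g <- if (!is.null(fx$rho_tissue)) fx$rho_tissue else
      get_block("rho_tissue", model$n_rho)
    drag_g <- if (!is.null(fx$drag_term)) fx$drag_term else
      get_block("drag6", model$n_drag) * 1e-6
    gas_g <- if (!is.null(fx$vair_per_mass)) fx$vair_per_mass else
      get_block("gas", model$n_gas)
    r <- if (!is.null(fx$r)) fx$r else if (spec$compressibility)
      draw[["r9"]] * 1e-9 else 0
    pars <- list(drag_term = drag_g[d_drag], rho_tissue = rho_g[d_rho],
                 vair_per_mass = gas_g[d_gas], r = r)
    mu <- glide_acceleration(pars, seg$v, seg$p, seg$d, seg$rho_sw, const)
    -2 * sum(dnorm(seg$a, mu, seg$sigma_a, log = TRUE))
  }
}

#' Run MCMC for a glide model
#'
#' Samples the posterior with JAGS. The default protocol is three
#' independent chains of 24,000 iterations, the first 12,000 discarded as
#' burn-in and the remainder thinned by 36 (333 retained draws per chain).
#' Chains are seeded deterministically from `seed`, so the same seed gives
#' identical output. Initial values are the prior means, jittered by 1%
#' per chain; a chain whose initial log posterior is not finite is
#' restarted from the unjittered prior means (up to 5 attempts).
#'
#' @param model A [build_model()] object.
#' @param n_chains Number of chains.
#' @param n_iter Total iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded per chain.
#' @param thin Thinning factor for the retained draws.
#' @param seed Integer seed controlling initial values and chain RNGs.
#' @param n_adapt JAGS adaptation iterations (before the protocol proper).
#' @param quiet Suppress JAGS progress output.
#' @param dic Compute DIC from the retained draws (skip for very long
#'   chains where only the draws are needed).
#' @return A `gb_posterior`: retained chains (a [coda::mcmc.list]),
#'   summary table, Gelman-Rubin diagnostics, DIC and effective number of
#'   parameters.
#' @export
run_mcmc <- function(model, n_chains = 3, n_iter = 24000, n_burn = 12000,
                     thin = 36, seed = 1, n_adapt = 1000, quiet = TRUE,
                     dic = TRUE) {
  stopifnot(inherits(model, "gb_model"), n_burn < n_iter, thin >= 1)
  inits <- lapply(seq_len(n_chains), function(ch) {
    make_inits(model, seed = seed, chain = ch, max_tries = 5)
  })
  jm <- NULL
  msgs <- utils::capture.output(
    jm <- rjags::jags.model(textConnection(model$code), data = model$data,
                            inits = inits, n.chains = n_chains,
                            n.adapt = n_adapt, quiet = quiet)
  )
  stats::update(jm, n.iter = n_burn, progress.bar = "none")
  chains <- rjags::coda.samples(jm, variable.names = model$monitors,
                                n.iter = n_iter - n_burn, thin = thin,
                                progress.bar = "none")
  new_gb_posterior(model, chains, seed = seed,
                   protocol = list(n_chains = n_chains, n_iter = n_iter,
                                   n_burn = n_burn, thin = thin),
                   dic = dic)
}

# prior-mean inits, jittered 1% per chain, with finite-posterior retries
make_inits <- function(model, seed, chain, max_tries = 5) {
  pr <- model$priors
  spec <- model$spec
  means <- list()
  if (is.null(model$fixed$rho_tissue)) {
    m <- (pr$rho_lower + pr$rho_upper) / 2
    means$rho_tissue <- rep(m, model$n_rho)
    if (spec$density == "hierarchical") {
      means$rho_mu <- m; means$rho_sd <- pr$sd_density_upper / 2
    }
  }
  if (is.null(model$fixed$drag_term)) {
    m <- pr$drag_mean * 1e6
    means$drag6 <- rep(m, model$n_drag)
    if (spec$drag == "hierarchical") {
      means$drag_mu6 <- m; means$drag_sd6 <- pr$sd_drag_upper * 1e6 / 2
    }
  }
  if (is.null(model$fixed$vair_per_mass)) {
    m <- (pr$gas_lower + pr$gas_upper) / 2
    means$gas <- rep(m, model$n_gas)
    if (spec$gas == "hierarchical-dive") {
      means$gas_mu <- m; means$gas_sd <- pr$sd_gas_upper / 2
    }
  }
  if (is.null(model$fixed$r) && spec$compressibility) {
    means$r9 <- (pr$r_lower + pr$r_upper) / 2 * 1e9
  }
  # clamp a jittered block back into its prior support
  bounds <- list(
    rho_tissue = c(pr$rho_lower, pr$rho_upper),
    rho_mu = c(pr$rho_lower, pr$rho_upper),
    drag6 = c(pr$drag_lower, pr$drag_upper) * 1e6,
    drag_mu6 = c(pr$drag_lower, pr$drag_upper) * 1e6,
    gas = if (spec$gas %in% c("dive", "hierarchical-dive"))
      c(pr$gas_group_lower, pr$gas_group_upper) else
        c(pr$gas_lower, pr$gas_upper),
    gas_mu = c(pr$gas_lower, pr$gas_upper),
    r9 = c(pr$r_lower, pr$r_upper) * 1e9,
    rho_sd = c(0, pr$sd_density_upper),
    drag_sd6 = c(0, pr$sd_drag_upper * 1e6),
    gas_sd = c(0, pr$sd_gas_upper)
  )
  clamp <- function(v, nm) {
    b <- bounds[[nm]]
    if (is.null(b)) return(v)
    eps <- 1e-6 * diff(b)
    pmin(pmax(v, b[1] + eps), b[2] - eps)
  }
  dev <- model$deviance
  for (try in seq_len(max_tries)) {
    set.seed((seed * 1000L + chain * 101L + try) %% .Machine$integer.max)
    jitter <- if (try == 1) 0.01 else 0   # retries fall back to exact means
    vals <- lapply(means, function(v) v * (1 + jitter * rnorm(length(v))))
    vals <- mapply(clamp, vals, names(vals), SIMPLIFY = FALSE)
    draw <- flatten_inits(vals, model)
    if (is.finite(dev(draw))) {
      vals$.RNG.name <- "base::Mersenne-Twister"
      vals$.RNG.seed <- (seed * 1000L + chain) %% .Machine$integer.max
      return(vals)
    }
  }
  abort("Could not find a finite-posterior initialisation.",
        class = "glidebuoy_error_init")
}

flatten_inits <- function(vals, model) {
  out <- c()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) == 1L) out[nm] <- v
    else out[paste0(nm, "[", seq_along(v), "]")] <- v
  }
  # scalar blocks are addressed both ways in the deviance closure
  for (nm in c("rho_tissue", "drag6", "gas")) {
    key <- paste0(nm, "[1]")
    if (!is.null(vals[[nm]]) && length(vals[[nm]]) == 1L) out[key] <- vals[[nm]]
  }
  out
}

new_gb_posterior <- function(model, chains, seed, protocol, dic = TRUE) {
  rhat <- gelman_rubin(chains)
  summ <- summarise_chains(chains, rhat)
  dic <- if (dic) compute_dic_chains(model, chains) else
    list(dic = NA_real_, pD = NA_real_, dbar = NA_real_, n_dropped = 0L)
  structure(
    list(chains = chains, summary = summ, rhat = rhat,
         dic = dic$dic, pD = dic$pD, dbar = dic$dbar,
         n_dropped = dic$n_dropped,
         spec = model$spec, model = model, seed = seed,
         protocol = protocol),
    class = "gb_posterior"
  )
}

summarise_chains <- function(chains, rhat) {
  draws <- as.matrix(chains)
  tibble::tibble(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    q2.5 = apply(draws, 2, quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(draws, 2, quantile, probs = 0.975, names = FALSE),
    rhat = unname(rhat[colnames(draws)])
  )
}

#' @export
print.gb_posterior <- function(x, ...) {
  cat("<gb_posterior>", format(x$spec), "\n")
  cat(sprintf("  %d chains x %d retained draws; DIC = %.1f (pD = %.1f)\n",
              length(x$chains), nrow(x$chains[[1]]), x$dic, x$pD))
  print(x$summary, n = 12)
  invisible(x)
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within variance-ratio form: with m chains of n
#' draws, W the mean within-chain variance and B/n the variance of the
#' chain means, Rhat = sqrt(((n-1)/n W + B/n) / W).
#'
#' @param chains A [coda::mcmc.list], or a list of equal-size numeric
#'   matrices (draws x parameters).
#' @return Named vector of Rhat values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  mats <- lapply(chains, as.matrix)
  m <- length(mats)
  if (m < 2) abort("Need >= 2 chains.", class = "glidebuoy_error_input")
  n <- nrow(mats[[1]])
  if (n < 10) abort("Need >= 10 draws per chain.",
                    class = "glidebuoy_error_input")
  p <- ncol(mats[[1]])
  nms <- colnames(mats[[1]]) %||% paste0("par", seq_len(p))
  out <- vapply(seq_len(p), function(j) {
    xs <- vapply(mats, function(mat) mat[, j], numeric(n))
    w <- mean(apply(xs, 2, var))
    b_over_n <- var(colMeans(xs))
    if (w == 0) {
      warn(sprintf("Degenerate chain (zero within-chain variance) for %s.",
                   nms[j]))
      return(NA_real_)
    }
    sqrt(((n - 1) / n * w + b_over_n) / w)
  }, numeric(1))
  names(out) <- nms
  out
}

compute_dic_chains <- function(model, chains) {
  draws <- as.matrix(chains)
  dev <- apply(draws, 1, function(row) model$deviance(row))
  finite <- is.finite(dev)
  n_dropped <- sum(!finite)
  if (n_dropped > 0) {
    warn(sprintf("Dropped %d non-finite deviance draws.", n_dropped))
  }
  dbar <- mean(dev[finite])
  d_at_mean <- model$deviance(colMeans(draws[finite, , drop = FALSE]))
  pD <- dbar - d_at_mean
  list(dic = dbar + pD, pD = pD, dbar = dbar, n_dropped = n_dropped)
}

#' Deviance information criterion of a fitted glide model
#'
#' DIC = Dbar + pD with Dbar the posterior mean deviance and pD = Dbar -
#' D(posterior mean) the effective number of parameters. Lower DIC means a
#' better fit relative to model complexity. Deviance is evaluated in R
#' through the package's own forward model at every retained draw;
#' non-finite draws are dropped with a warning.
#'
#' @param result A `gb_posterior` from [run_mcmc()].
#' @param model Optionally, the `gb_model`; defaults to the one stored in
#'   `result`.
#' @return A list with `dic`, `pD` and `dbar`.
#' @export
compute_dic <- function(result, model = result$model) {
  compute_dic_chains(model, result$chains)[c("dic", "pD", "dbar")]
}

#' Fit several model structures and compare them by DIC
#'
#' Runs [run_mcmc()] for each [gb_model_spec()] and tabulates DIC, pD and
#' the key global posterior means, sorted so the best (lowest-DIC) model
#' comes first.
#'
#' @param segments Glide-segment tibble.
#' @param specs A list of [gb_model_spec()] objects (>= 1; names become
#'   row labels).
#' @param priors A [gb_priors()].
#' @param seed Integer seed (each spec is offset deterministically).
#' @param ... Passed to [run_mcmc()] (e.g. a reduced protocol).
#' @return A tibble with one row per spec: `spec`, `dic`, `pD`,
#'   `rho_tissue_mean`, `gas_mean`, `drag_mean`, `r_mean`, and the fitted
#'   `gb_posterior` objects in a list column `fit`.
#' @export
fit_and_compare <- function(segments, specs, priors = gb_priors(),
                            seed = 1, ...) {
  stopifnot(length(specs) >= 1)
  labels <- names(specs) %||% vapply(specs, format, character(1))
  labels[labels == ""] <- vapply(specs[labels == ""], format, character(1))
  fits <- purrr::map(seq_along(specs), function(i) {
    model <- build_model(segments, specs[[i]], priors)
    run_mcmc(model, seed = seed + 31L * (i - 1L), ...)
  })
  rows <- purrr::map2_dfr(fits, labels, function(fit, lab) {
    tibble::tibble(
      spec = lab,
      dic = fit$dic,
      pD = fit$pD,
      rho_tissue_mean = global_mean(fit, "rho_tissue", "rho_mu"),
      gas_mean = global_mean(fit, "gas", "gas_mu"),
      drag_mean = global_mean(fit, "drag6", "drag_mu6") * 1e-6,
      r_mean = if (fit$spec$compressibility)
        global_mean(fit, "r9", NULL) * 1e-9 else 0
    )
  })
  rows$fit <- unname(fits)
  dplyr::arrange(rows, .data$dic)
}

# global posterior mean of a parameter block: the hyper-mean when present,
# otherwise the mean over group-level means
global_mean <- function(fit, base, hyper) {
  s <- fit$summary
  if (!is.null(hyper) && hyper %in% s$parameter) {
    return(s$mean[s$parameter == hyper])
  }
  rows <- grepl(paste0("^", base, "(\\[|$)"), s$parameter)
  mean(s$mean[rows])
}

#' Brute-force grid posterior for tissue density
#'
#' Independent check of the sampler: with drag, gas volume and
#' compressibility pinned, the posterior of a single shared tissue density
#' is computed on a regular grid over its prior support by direct
#' evaluation of the likelihood, normalised by the trapezoid rule.
#'
#' @param segments Glide-segment tibble.
#' @param fixed Named list with `drag_term`, `vair_per_mass`, `r`.
#' @param priors A [gb_priors()].
#' @param n_grid Number of grid points.
#' @param const A [hydro_constants()].
#' @return A tibble with `rho_tissue` and normalised `density`.
#' @export
grid_posterior_rho_tissue <- function(segments, fixed, priors = gb_priors(),
                                      n_grid = 2001,
                                      const = hydro_constants()) {
  stopifnot(all(c("drag_term", "vair_per_mass", "r") %in% names(fixed)))
  grid <- seq(priors$rho_lower, priors$rho_upper, length.out = n_grid)
  loglik <- vapply(grid, function(rho) {
    pars <- list(drag_term = fixed$drag_term, rho_tissue = rho,
                 vair_per_mass = fixed$vair_per_mass, r = fixed$r)
    mu <- glide_acceleration(pars, segments$v, segments$p, segments$d,
                             segments$rho_sw, const)
    sum(dnorm(segments$a, mu, segments$sigma_a, log = TRUE))
  }, numeric(1))
  w <- exp(loglik - max(loglik))
  h <- diff(grid[1:2])
  z <- h * (sum(w) - (w[1] + w[length(w)]) / 2)   # trapezoid
  tibble::tibble(rho_tissue = grid, density = w / z)
}
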