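quick_segments <- function(n_ind = 2, n_dives = 2, glides = 30, seed = 42,
                           ...) {
  tr <- draw_truth(n_individuals = n_ind, n_dives = n_dives, seed = seed, ...)
  list(truth = tr,
       segments = simulate_glide_table(tr, glides_per_individual = glides,
                                       seed = seed + 1))
}

test_that("model structure puts the right number of parameters at each level", {
  qs <- quick_segments(n_ind = 3, n_dives = 2)
  m_global <- build_model(qs$segments, gb_model_spec())
  # four unknowns: density, drag, gas, compressibility
  expect_equal(sort(m_global$monitors),
               sort(c("rho_tissue", "drag6", "gas", "r9")))
  expect_equal(m_global$n_rho, 1L)
  m_h <- build_model(qs$segments,
                     gb_model_spec("hierarchical", "individual",
                                   "hierarchical-dive"))
  expect_equal(m_h$n_rho, 3L)        # 3 individuals + mu + sd
  expect_true(all(c("rho_mu", "rho_sd") %in% m_h$monitors))
  expect_equal(m_h$n_drag, 3L)
  expect_equal(m_h$n_gas, 6L)        # 3 individuals x 2 dives
  expect_error(build_model(qs$segments[0, ], gb_model_spec()),
               class = "glidebuoy_error_input")
  expect_error(build_model(qs$segments, gb_model_spec(),
                           fixed = list(nope = 1)),
               class = "glidebuoy_error_config")
})

test_that("deviance at the generating parameters of a noiseless table is the floor", {
  tr <- draw_truth(n_individuals = 1, n_dives = 1, rho_sd = 0, drag_sd = 0,
                   gas_sd = 0, seed = 3)
  seg <- simulate_glide_table(tr, glides_per_individual = 25,
                              sigma_a_range = c(0.01, 0.01), seed = 4)
  seg$a <- seg$a_true   # strip the observation noise
  m <- build_model(seg, gb_model_spec())
  draw <- c("rho_tissue[1]" = tr$individuals$rho_tissue[1],
            "drag6[1]" = tr$individuals$drag_term[1] * 1e6,
            "gas[1]" = tr$dives$vair_per_mass[1],
            "r9" = tr$r * 1e9)
  # zero residuals: deviance reduces to the sigma normalisation constant
  floor_dev <- -2 * sum(dnorm(0, 0, seg$sigma_a, log = TRUE))
  expect_equal(m$deviance(draw), floor_dev, tolerance = 1e-10)
})

test_that("Gelman-Rubin matches manual arithmetic and flags divergent chains", {
  # hand toy: 2 chains x 10 draws, formula recomputed longhand in the test
  set.seed(9)
  c1 <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "x"))
  c2 <- matrix(rnorm(10, 0.5), ncol = 1, dimnames = list(NULL, "x"))
  w <- (var(c1[, 1]) + var(c2[, 1])) / 2
  b_over_n <- var(c(mean(c1[, 1]), mean(c2[, 1])))
  expected <- sqrt((9 / 10 * w + b_over_n) / w)
  expect_equal(unname(gelman_rubin(list(c1, c2))["x"]), expected,
               tolerance = 1e-12)
  # chains from one distribution are near 1
  set.seed(10)
  same <- lapply(1:3, function(i)
    matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x")))
  expect_lt(gelman_rubin(same)["x"], 1.1)
  # disjoint supports blow up
  far <- list(matrix(rnorm(100, 0), ncol = 1),
              matrix(rnorm(100, 100), ncol = 1))
  expect_gt(gelman_rubin(far)[1], 10)
  # degenerate chains warn
  flat <- list(matrix(rep(1, 20), ncol = 1), matrix(rep(1, 20), ncol = 1))
  expect_warning(gelman_rubin(flat))
  expect_error(gelman_rubin(list(c1)), class = "glidebuoy_error_input")
})

test_that("Gelman-Rubin agrees with the coda implementation on mixed chains", {
  set.seed(11)
  chains <- coda::mcmc.list(lapply(1:3, function(i)
    coda::mcmc(matrix(rnorm(3000), ncol = 2,
                      dimnames = list(NULL, c("a", "b"))))))
  mine <- gelman_rubin(chains)
  ref <- coda::gelman.diag(chains, autoburnin = FALSE,
                           multivariate = FALSE)$psrf[, 1]
  expect_equal(unname(mine), unname(ref), tolerance = 0.02)
})

test_that("posterior for a linear parameter matches the conjugate closed form", {
  # with density, drag and r pinned, the gas volume enters the likelihood
  # linearly, so the posterior has a closed weighted-least-squares form
  tr <- draw_truth(1, 1, rho_sd = 0, drag_sd = 0, gas_sd = 0, seed = 7)
  seg <- simulate_glide_table(tr, glides_per_individual = 40,
                              depth_range = c(5, 60), seed = 8)
  fx <- list(drag_term = tr$individuals$drag_term[1],
             rho_tissue = tr$individuals$rho_tissue[1], r = tr$r)
  m <- build_model(seg, gb_model_spec("global", "global", "dive"), fixed = fx)
  fit <- run_mcmc(m, n_iter = 12000, n_burn = 2000, thin = 5, seed = 4)
  base <- list(drag_term = fx$drag_term, rho_tissue = fx$rho_tissue,
               vair_per_mass = 0, r = fx$r)
  c0 <- glide_acceleration(base, seg$v, seg$p, seg$d, seg$rho_sw)
  base$vair_per_mass <- 1
  c1 <- glide_acceleration(base, seg$v, seg$p, seg$d, seg$rho_sw) - c0
  prec <- sum(c1^2 / seg$sigma_a^2)
  m_star <- sum(c1 * (seg$a - c0) / seg$sigma_a^2) / prec
  s_star <- sqrt(1 / prec)
  draws <- as.vector(as.matrix(fit$chains))
  n_eff <- sum(coda::effectiveSize(fit$chains))
  expect_lt(abs(mean(draws) - m_star), 3 * s_star / sqrt(n_eff))
  expect_equal(sd(draws), s_star, tolerance = 0.1)
  # a single near-free parameter: effective parameter count close to 1
  expect_equal(fit$pD, 1, tolerance = 0.35)
})

test_that("identical seeds give bit-identical posteriors", {
  qs <- quick_segments(n_ind = 2, glides = 20)
  m <- build_model(qs$segments, gb_model_spec())
  f1 <- run_mcmc(m, n_iter = 800, n_burn = 300, thin = 2, seed = 99)
  f2 <- run_mcmc(m, n_iter = 800, n_burn = 300, thin = 2, seed = 99)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$dic, f2$dic)
})

test_that("truncated priors are respected in every retained draw", {
  qs <- quick_segments(n_ind = 2, glides = 25)
  m <- build_model(qs$segments,
                   gb_model_spec("hierarchical", "hierarchical",
                                 "hierarchical-dive"))
  fit <- run_mcmc(m, n_iter = 2000, n_burn = 500, thin = 2, seed = 5)
  draws <- as.matrix(fit$chains)
  drag_cols <- grepl("^drag6", colnames(draws)) &
    !grepl("sd", colnames(draws))
  expect_true(all(draws[, drag_cols] >= 5 & draws[, drag_cols] <= 20))
  expect_true(all(draws[, "r9"] >= 0.3 & draws[, "r9"] <= 0.7))
  rho_cols <- grepl("^rho_tissue", colnames(draws))
  expect_true(all(draws[, rho_cols] >= 800 & draws[, rho_cols] <= 1200))
})

test_that("with uninformative data the posterior reproduces the prior", {
  # a single segment with enormous observation error carries no information
  seg <- tibble::tibble(individual_id = "w1", dive_id = 1L,
                        phase = "descent", v = 1.5, a = 0, sigma_a = 1e9,
                        d = 100, p = -pi / 3, rho_sw = 1027)
  m <- build_model(seg, gb_model_spec())
  fit <- run_mcmc(m, n_iter = 42000, n_burn = 2000, thin = 40, seed = 6)
  draws <- as.matrix(fit$chains)
  ks_rho <- stats::ks.test(draws[, "rho_tissue"], "punif", 800, 1200)
  expect_gt(ks_rho$p.value, 0.01)
  ks_r <- stats::ks.test(draws[, "r9"], "punif", 0.3, 0.7)
  expect_gt(ks_r$p.value, 0.01)
  ks_gas <- stats::ks.test(draws[, "gas"], "punif", 5, 50)
  expect_gt(ks_gas$p.value, 0.01)
})

test_that("near-point priors collapse the effective parameter count", {
  tr <- draw_truth(1, 1, rho_sd = 0, drag_sd = 0, gas_sd = 0, seed = 13)
  seg <- simulate_glide_table(tr, glides_per_individual = 20, seed = 14)
  rho0 <- tr$individuals$rho_tissue[1]
  pr <- gb_priors(rho_lower = rho0 - 1e-4, rho_upper = rho0 + 1e-4)
  m <- build_model(seg, gb_model_spec(),
                   fixed = list(drag_term = tr$individuals$drag_term[1],
                                vair_per_mass = tr$dives$vair_per_mass[1],
                                r = tr$r),
                   priors = pr)
  fit <- run_mcmc(m, n_iter = 3000, n_burn = 1000, thin = 2, seed = 7)
  expect_lt(abs(fit$pD), 0.05)
  expect_equal(fit$dic, fit$dbar, tolerance = 0.1)
})

test_that("the grid posterior is a proper density peaked near the truth", {
  tr <- draw_truth(1, 1, rho_sd = 0, drag_sd = 0, gas_sd = 0, seed = 15)
  seg <- simulate_glide_table(tr, glides_per_individual = 60, seed = 16)
  fx <- list(drag_term = tr$individuals$drag_term[1],
             vair_per_mass = tr$dives$vair_per_mass[1], r = tr$r)
  grid <- grid_posterior_rho_tissue(seg, fx)
  h <- diff(grid$rho_tissue[1:2])
  mass <- h * (sum(grid$density) -
                 (grid$density[1] + tail(grid$density, 1)) / 2)
  expect_equal(mass, 1, tolerance = 1e-6)
  mode_at <- grid$rho_tissue[which.max(grid$density)]
  expect_equal(mode_at, tr$individuals$rho_tissue[1], tolerance = 1e-3)
})

test_that("fit_and_compare ranks specs by DIC and reports global means", {
  qs <- quick_segments(n_ind = 2, glides = 25)
  specs <- list(global = gb_model_spec(),
                incompressible = gb_model_spec(compressibility = FALSE))
  tab <- fit_and_compare(qs$segments, specs, seed = 2,
                         n_iter = 1500, n_burn = 500, thin = 2)
  expect_equal(nrow(tab), 2)
  expect_true(!is.unsorted(tab$dic))
  expect_true(all(c("rho_tissue_mean", "gas_mean", "drag_mean", "r_mean")
                  %in% names(tab)))
  # single-spec call degenerates to a one-row table
  tab1 <- fit_and_compare(qs$segments, specs[1], seed = 2,
                          n_iter = 1000, n_burn = 400, thin = 2)
  expect_equal(nrow(tab1), 1)
})
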