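test_that("GP prior draws have the configured marginal variance", {
  grid <- seq(-10, 10, length.out = 41)
  cfg <- gp_config(amplitude = 1.5, length_scale = 3, grid = grid)
  n_draw <- 500L
  u_mid <- vapply(seq_len(n_draw), function(s) {
    evaluate_potential(sample_gp_potential(cfg, seed = s), 0)
  }, numeric(1L))
  v <- cfg$amplitude^2
  se <- v * sqrt(2 / n_draw)
  expect_lt(abs(var(u_mid) - v), 3 * se)
  expect_lt(abs(mean(u_mid)), 3 * cfg$amplitude / sqrt(n_draw))
})

test_that("longer length scales give smoother potentials", {
  grid <- seq(-10, 10, length.out = 201)
  sign_changes <- function(ell) {
    mean(vapply(1:60, function(s) {
      u <- sample_gp_potential(gp_config(amplitude = 1, length_scale = ell,
                                         grid = grid), seed = s)
      sum(diff(sign(diff(u$grid_U))) != 0)
    }, numeric(1L)))
  }
  expect_gt(sign_changes(1), sign_changes(5))
})

test_that("drift observations are exact in the noise-free limit", {
  spec <- double_well_potential(2, 5)
  cfg <- sim_config(temperature = 0, n_steps = 200L, x0 = 2.5, seed = 1)
  tr <- simulate_langevin(spec, cfg)
  obs <- drift_observations(tr, cfg$zeta, cfg$temperature)
  kT_ref <- thermal_energy(300)
  expect_equal(obs$y, kT_ref * evaluate_force(spec, obs$x),
               tolerance = 1e-10)
  expect_equal(attr(obs, "noise_var"), 0)
})

test_that("doubling temperature doubles the drift observation variance", {
  tr <- quick_sim(harmonic_potential(0.5), 100L, seed = 2)
  v300 <- attr(drift_observations(tr, 2e-4, 300), "noise_var")
  v600 <- attr(drift_observations(tr, 2e-4, 600), "noise_var")
  expect_identical(v600, 2 * v300)
  expect_equal(v300, 2 * thermal_energy(300) * 2e-4 / 1e-6)
})

test_that("flat potential drift averages to zero; harmonic slope is -k kT", {
  # flat region: binned mean drift ~ 0
  tr <- quick_sim(flat_well_potential(1, 50, 4), 5e4, seed = 3)
  obs <- drift_observations(tr, 2e-4, 300)
  se <- sqrt(attr(obs, "noise_var") / nrow(obs))
  expect_lt(abs(mean(obs$y)), 3 * se)
  # harmonic: regression slope of y on x estimates -k * kT
  k <- 0.5
  trh <- quick_sim(harmonic_potential(k), 2e5, seed = 4)
  oh <- drift_observations(trh, 2e-4, 300)
  slope <- coef(lm(y ~ x, data = oh))[["x"]]
  expect_equal(slope, -k * thermal_energy(300), tolerance = 0.1)
})

test_that("GP regression recovers harmonic stiffness within 15%", {
  k <- 0.5
  tr <- quick_sim(harmonic_potential(k), 2e5, seed = 5)
  est <- fit_gp_potential(tr, 2e-4, 300)
  # quadratic fit to U_hat near the minimum; curvature is resolved at the
  # kernel's length scale, so the window spans 1.5 of it
  i0 <- which.min(est$U_hat)
  near <- abs(est$grid - est$grid[i0]) < 1.5 * est$length_scale
  qf <- lm(U ~ I((x - x0)^2),
           data = data.frame(U = est$U_hat[near], x = est$grid[near],
                             x0 = est$grid[i0]))
  k_hat <- 2 * coef(qf)[[2L]]
  expect_lt(abs(k_hat - k) / k, 0.15)
})

test_that("GP reconstruction finds both wells and the barrier scale", {
  spec <- double_well_potential(2, 5)
  tr <- quick_sim(spec, 2e5, seed = 6, x0 = -5)
  est <- fit_gp_potential(tr, 2e-4, 300)
  u <- est$U_hat
  interior <- 2:(length(u) - 1L)
  mins <- interior[u[interior] < u[interior - 1L] &
                   u[interior] < u[interior + 1L]]
  # keep minima deeper than the local uncertainty
  mins <- mins[u[mins] < max(u) - est$sd[mins]]
  locs <- sort(est$grid[mins])
  expect_length(locs, 2L)
  expect_lt(abs(locs[1L] + 5), 1)
  expect_lt(abs(locs[2L] - 5), 1)
  # barrier height between 1 and 3 kT
  sep <- est$grid > locs[1L] & est$grid < locs[2L]
  barrier <- max(u[sep]) - min(u[mins])
  expect_gt(barrier, 1)
  expect_lt(barrier, 3)
})

test_that("unvisited grid regions revert to the prior uncertainty", {
  tr <- quick_sim(harmonic_potential(1), 2e4, seed = 7)
  grid <- seq(-30, 30, length.out = 121) # far beyond the explored span
  est <- fit_gp_potential(tr, 2e-4, 300,
                          gp_config(amplitude = 2, length_scale = 3,
                                    grid = grid))
  edge <- est$n_obs == 0L & abs(est$grid) > 20
  core <- est$n_obs > 50L
  # far from any data the force posterior reverts to the prior sd A/ell
  expect_equal(est$f_sd[edge], rep(2 / 3, sum(edge)), tolerance = 1e-6)
  expect_gt(min(est$f_sd[edge]), max(est$f_sd[core]))
})

test_that("simulate-from-fit self-consistency within 2 pointwise sd", {
  spec <- double_well_potential(1.5, 4)
  tr <- quick_sim(spec, 1e5, seed = 8, x0 = -4)
  est <- fit_gp_potential(tr, 2e-4, 300)
  # rebuild a tabulated potential on a padded grid so the re-simulation
  # cannot step outside the domain
  pad <- 15
  gx <- c(min(est$grid) - pad, min(est$grid) - pad / 2,
          est$grid, max(est$grid) + pad / 2, max(est$grid) + pad)
  gu <- c(max(est$U_hat) + 20, max(est$U_hat) + 8, est$U_hat,
          max(est$U_hat) + 8, max(est$U_hat) + 20)
  tab <- tabulated_potential(gx, gu)
  tr2 <- quick_sim(tab, 1e5, seed = 9, x0 = -4)
  est2 <- fit_gp_potential(tr2, 2e-4, 300,
                           gp_config(grid = est$grid))
  visited <- est$n_obs > 100L & est2$n_obs > 100L
  tol <- 2 * pmax(est$sd[visited] + est2$sd[visited], 0.15)
  expect_true(all(abs(est$U_hat[visited] - est2$U_hat[visited]) <= tol))
})
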