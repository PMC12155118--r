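test_that("generator rows sum to zero and reject negative rates", {
  Q <- rate_matrix(matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE))
  expect_lt(max(abs(rowSums(Q$Q))), 1e-12)
  expect_error(rate_matrix(matrix(c(0, -1, 1, 0), 2, 2)), "non-negative")
})

test_that("holding times are Exponential(total escape rate)", {
  Q <- rate_matrix(matrix(c(0, 10, 10, 0), 2, 2))
  jt <- simulate_hmjp(Q, c(0.5, 0.5), t_end = 1100, seed = 2)
  h <- head(jt$holding_times, -1L) # last holding is truncated
  expect_gt(length(h), 1e4)
  ks <- suppressWarnings(stats::ks.test(h[seq_len(1e4)], "pexp", 10))
  expect_gt(ks$p.value, 0.01)
  # mean holding ~ 0.1 s within 3 standard errors
  se <- 0.1 / sqrt(length(h))
  expect_lt(abs(mean(h) - 0.1), 3 * se)
  # symmetric rates: half the time in state 1
  occ1 <- sum(jt$holding_times[jt$states == 1L]) / jt$t_end
  expect_lt(abs(occ1 - 0.5), 0.05)
})

test_that("asymmetric rates give the closed-form stationary occupancy", {
  Q <- rate_matrix(matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE))
  jt <- simulate_hmjp(Q, c(1, 0), t_end = 2000, seed = 3)
  occ1 <- sum(jt$holding_times[jt$states == 1L]) / jt$t_end
  expect_lt(abs(occ1 - 0.25), 0.02) # lambda21/(lambda12+lambda21)
  # consecutive states always differ
  expect_true(all(diff(jt$states) != 0L))
  expect_equal(sum(jt$holding_times), jt$t_end, tolerance = 1e-9)
})

test_that("an absorbing state ends the trajectory with an open holding", {
  Q <- rate_matrix(matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE))
  jt <- simulate_hmjp(Q, c(1, 0), t_end = 100, seed = 4)
  expect_identical(tail(jt$states, 1L), 2L)
  expect_lte(length(jt$states), 2L)
  # from the absorbing state directly: single holding, no jumps
  jt2 <- simulate_hmjp(Q, c(0, 1), t_end = 100, seed = 5)
  expect_identical(jt2$states, 2L)
  expect_equal(jt2$holding_times, 100)
})

test_that("observations reflect the occupied state exactly when noiseless", {
  Q <- rate_matrix(matrix(c(0, 50, 50, 0), 2, 2))
  jt <- simulate_hmjp(Q, c(1, 0), t_end = 1, seed = 6)
  ts <- seq(0, 0.999, by = 1e-3)
  obs <- sample_jump_observations(jt, ts, mu = c(-5, 5), sigma = 0,
                                  seed = 1)
  expect_true(all(obs$w %in% c(-5, 5)))
  expect_identical(obs$w, c(-5, 5)[attr(obs, "true_states")])
  # single-state trajectory: i.i.d. Normal sample
  jts <- simulate_hmjp(rate_matrix(matrix(0, 1, 1)), 1, t_end = 1,
                       seed = 7)
  obs1 <- sample_jump_observations(jts, ts, mu = 2, sigma = 0.5, seed = 8)
  expect_lt(abs(mean(obs1$w) - 2), 3 * 0.5 / sqrt(length(ts)))
  ks <- suppressWarnings(stats::ks.test(obs1$w, "pnorm", 2, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling much faster than the rates clusters states in runs", {
  Q <- rate_matrix(matrix(c(0, 5, 5, 0), 2, 2))
  jt <- simulate_hmjp(Q, c(1, 0), t_end = 10, seed = 9)
  ts <- seq(0, 9.99, by = 1e-3) # 200x faster than the jump rate
  s <- jump_state_at(jt, ts)
  runs <- rle(s)$lengths
  expect_gt(mean(runs), 50)
})

test_that("jump-process likelihood equals the discrete skeleton HMM", {
  Q <- rate_matrix(matrix(c(0, 40, 15, 0), 2, 2, byrow = TRUE))
  dt <- 0.01
  jt <- simulate_hmjp(Q, c(0.5, 0.5), t_end = 6, seed = 10)
  ts <- seq(0, 5.99, by = dt)
  obs <- sample_jump_observations(jt, ts, mu = c(-3, 3), sigma = 1,
                                  seed = 11)
  ll_jump <- hmjp_loglik(Q, c(0.5, 0.5), c(-3, 3), 1, obs)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q$Q * dt)))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  params <- hmm_params(c(0.5, 0.5), P / rowSums(P), c(-3, 3), 1)
  expect_equal(ll_jump, forward_loglik(params, obs$w), tolerance = 1e-9)
})

test_that("zero generator freezes the chain: i.i.d. mixture likelihood", {
  Q <- rate_matrix(matrix(0, 2, 2))
  w <- c(-1.2, 0.4, 0.8)
  rho <- c(0.3, 0.7)
  mu <- c(-1, 1)
  ll <- hmjp_loglik(Q, rho, mu, 1, w, dt = 0.1)
  # states frozen: log sum_m rho_m prod_n g_n(m)
  direct <- log(sum(rho * c(prod(dnorm(w, mu[1], 1)),
                            prod(dnorm(w, mu[2], 1)))))
  expect_equal(ll, direct, tolerance = 1e-12)
})

test_that("fast mixing approaches the i.i.d. stationary-mixture likelihood", {
  # rates large with stationary law (0.25, 0.75) fixed
  lam <- 5e3
  Q <- rate_matrix(matrix(c(0, 3 * lam, lam, 0), 2, 2, byrow = TRUE))
  set.seed(13)
  w <- rnorm(200, sample(c(-4, 4), 200, TRUE, prob = c(0.25, 0.75)), 1)
  ll <- hmjp_loglik(Q, c(0.25, 0.75), c(-4, 4), 1, w, dt = 0.1)
  iid <- sum(log(0.25 * dnorm(w, -4, 1) + 0.75 * dnorm(w, 4, 1)))
  expect_equal(ll, iid, tolerance = 1e-6 * abs(iid))
})

test_that("rate MLE recovers a 2-state generator from dense observations", {
  Q <- rate_matrix(matrix(c(0, 8, 4, 0), 2, 2, byrow = TRUE))
  dt <- 5e-3 # well below mean holdings of 1/8 and 1/4 s
  jt <- simulate_hmjp(Q, c(0.5, 0.5), t_end = 51, seed = 14)
  ts <- seq(0, 50, by = dt)
  obs <- sample_jump_observations(jt, ts, mu = c(-4, 4), sigma = 1,
                                  seed = 15)
  fit <- fit_hmjp_rates(obs, K = 2L, mu = c(-4, 4), sigma = 1,
                        n_starts = 2L, seed = 16)
  expect_false(fit$flagged)
  expect_lt(abs(fit$Q$Q[1, 2] - 8) / 8, 0.2)
  expect_lt(abs(fit$Q$Q[2, 1] - 4) / 4, 0.2)
  # MLE dominance on the sample
  ll_true <- hmjp_loglik(Q, c(0.5, 0.5), c(-4, 4), 1, obs)
  expect_gte(fit$loglik, ll_true - 1e-3)
})

test_that("single-state data drives escape rates toward zero", {
  set.seed(17)
  obs <- basinmirage:::new_observation_series(times = seq(0, 9.99, 0.01),
                                              w = rnorm(1000, 2, 0.5),
                                              dt = 0.01)
  fit <- fit_hmjp_rates(obs, K = 2L, mu = c(2, 30), sigma = 0.5,
                        n_starts = 2L, seed = 18)
  expect_lt(fit$Q$Q[1, 2], 0.5) # escape from the occupied state ~ 0
})
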