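# Independent brute-force oracles and tiny fixture generators.
# These deliberately avoid the package's recursion code paths.

# log P(w | params) by explicit enumeration of all K^N state sequences
enum_loglik <- function(params, w) {
  K <- params$K
  N <- length(w)
  sig <- if (length(params$sigma) == 1L) rep(params$sigma, K) else params$sigma
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- apply(seqs, 1L, function(s) {
    lp <- log(params$rho[s[1L]]) + dnorm(w[1L], params$mu[s[1L]],
                                         sig[s[1L]], log = TRUE)
    if (N > 1L) for (n in 2:N)
      lp <- lp + log(params$Pi[s[n - 1L], s[n]]) +
        dnorm(w[n], params$mu[s[n]], sig[s[n]], log = TRUE)
    lp
  })
  m <- max(logp)
  m + log(sum(exp(logp - m)))
}

# jointly most probable sequence by enumeration (first maximum, which under
# expand.grid's ordering corresponds to the lowest-index tie-break)
enum_viterbi <- function(params, w) {
  K <- params$K
  N <- length(w)
  sig <- if (length(params$sigma) == 1L) rep(params$sigma, K) else params$sigma
  seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  logp <- apply(seqs, 1L, function(s) {
    lp <- log(params$rho[s[1L]]) + dnorm(w[1L], params$mu[s[1L]],
                                         sig[s[1L]], log = TRUE)
    if (N > 1L) for (n in 2:N)
      lp <- lp + log(params$Pi[s[n - 1L], s[n]]) +
        dnorm(w[n], params$mu[s[n]], sig[s[n]], log = TRUE)
    lp
  })
  as.integer(seqs[which.max(logp), ])
}

# random valid HMM parameters (means spread out, moderate persistence)
random_hmm_params <- function(K, seed) {
  set.seed(seed)
  rho <- rgamma(K, 1); rho <- rho / sum(rho)
  Pi <- matrix(rgamma(K * K, 1), K, K)
  Pi <- Pi / rowSums(Pi)
  mu <- sort(runif(K, -10, 10))
  hmm_params(rho, Pi, mu, runif(1L, 0.5, 2))
}

# simulate a state path + Gaussian observations from hmm_params
sim_hmm_data <- function(params, N, seed) {
  set.seed(seed)
  K <- params$K
  sig <- if (length(params$sigma) == 1L) rep(params$sigma, K) else params$sigma
  s <- integer(N)
  s[1L] <- sample.int(K, 1L, prob = params$rho)
  if (N > 1L) for (n in 2:N)
    s[n] <- sample.int(K, 1L, prob = params$Pi[s[n - 1L], ])
  list(states = s, w = params$mu[s] + rnorm(N, 0, sig[s]))
}

# canonical 2-state test system: means +/-10, sigma 1, persistence 0.98
two_state_params <- function(p_stay = 0.98, mu = c(-10, 10), sigma = 1) {
  hmm_params(c(0.5, 0.5),
             matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, 2,
                    byrow = TRUE),
             mu, sigma)
}

# small, fast Langevin runs for module tests
quick_sim <- function(spec, n_steps, seed, x0 = 0) {
  simulate_langevin(spec, sim_config(n_steps = n_steps, seed = seed,
                                     x0 = x0))
}

# small explicit BNP prior used by sampler-correctness diagnostics
geweke_cfg <- function(seed = 1L) {
  bnp_config(K_max = 3L, load_beta_a = 1, load_beta_b = 3, alpha_dir = 1,
             m0 = 0, n0 = 1, a0 = 3, b0 = 2, n_sweeps = 10L, burn_in = 1L,
             seed = seed)
}

# bare trajectory container around given positions (dt = 1 us)
new_traj_for_test <- function(positions, dt = 1e-6) {
  basinmirage:::new_trajectory(times = seq_along(positions) * dt,
                               positions = positions, dt = dt)
}
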