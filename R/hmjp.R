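#' Generator (rate matrix) of a Markov jump process
#'
#' Off-diagonal entries are the jump rates lambda_{j -> k} (1/s); the
#' diagonal is set to minus the row sum so rows of the generator sum to
#' zero. States with zero total escape rate are absorbing.
#'
#' @param lambda K x K matrix of non-negative off-diagonal rates (the
#'   diagonal is ignored and overwritten).
#' @return An object of class `rate_matrix` with fields `K` and `Q`.
#' @examples
#' Q <- rate_matrix(matrix(c(0, 10, 10, 0), 2, 2))
#' @export
rate_matrix <- function(lambda) {
  lambda <- as.matrix(lambda)
  K <- nrow(lambda)
  stopifnot(ncol(lambda) == K, K >= 1L)
  Q <- lambda
  diag(Q) <- 0
  if (any(Q < 0)) stop("off-diagonal rates must be non-negative")
  diag(Q) <- -rowSums(Q)
  structure(list(K = K, Q = Q), class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate_matrix> K =", x$K, "states\n")
  print(signif(x$Q, 5))
  invisible(x)
}

#' Simulate a Markov jump trajectory (Gillespie)
#'
#' Holding times are Exponential with the state's total escape rate; the
#' destination is Categorical with probabilities proportional to the
#' outgoing rates (self-transitions excluded). The trajectory is truncated
#' at `t_end`; reaching an absorbing state ends it with an open final
#' holding.
#'
#' @param Q a [rate_matrix()].
#' @param rho length-K initial probability vector.
#' @param t_end total simulated time, s.
#' @param seed integer RNG seed.
#' @return An object of class `jump_trajectory`: integer `states`
#'   (consecutive entries differ) and positive `holding_times` summing to
#'   `t_end` (last entry truncated/open).
#' @export
simulate_hmjp <- function(Q, rho, t_end, seed = 1L) {
  stopifnot(inherits(Q, "rate_matrix"), length(rho) == Q$K,
            abs(sum(rho) - 1) < 1e-10, t_end > 0)
  set.seed(as.integer(seed))
  esc <- -diag(Q$Q)
  states <- integer(0L)
  holds <- numeric(0L)
  s <- sample.int(Q$K, 1L, prob = rho)
  t <- 0
  repeat {
    states <- c(states, s)
    if (esc[s] <= 0) { # absorbing: open final holding to t_end
      holds <- c(holds, t_end - t)
      break
    }
    h <- rexp(1L, esc[s])
    if (t + h >= t_end) {
      holds <- c(holds, t_end - t)
      break
    }
    holds <- c(holds, h)
    t <- t + h
    p <- Q$Q[s, ]
    p[s] <- 0
    s <- sample.int(Q$K, 1L, prob = p)
  }
  structure(list(states = states, holding_times = holds, t_end = t_end,
                 K = Q$K),
            class = "jump_trajectory")
}

#' @export
print.jump_trajectory <- function(x, ...) {
  cat("<jump_trajectory>", length(x$states), "segments over",
      signif(x$t_end, 5), "s;", x$K, "states\n")
  invisible(x)
}

#' State occupied at given times
#'
#' @param jtraj a [jump_trajectory][simulate_hmjp].
#' @param times query times within `[0, t_end]`.
#' @return Integer state indices.
#' @export
jump_state_at <- function(jtraj, times) {
  stopifnot(all(times >= 0), all(times <= jtraj$t_end + 1e-12))
  bounds <- cumsum(jtraj$holding_times)
  # segment i occupies [bounds[i-1], bounds[i])
  idx <- findInterval(times, c(0, head(bounds, -1L)))
  jtraj$states[pmin(idx, length(jtraj$states))]
}

#' Instantaneous Gaussian observations of a jump trajectory
#'
#' w_n ~ Normal(mu of the state occupied at t_n, sigma).
#'
#' @inheritParams jump_state_at
#' @param sample_times observation times within the trajectory span.
#' @param mu length-K state emission means, nm.
#' @param sigma emission standard deviation, nm (>= 0).
#' @param seed integer RNG seed.
#' @return An `observation_series`.
#' @export
sample_jump_observations <- function(jtraj, sample_times, mu, sigma,
                                     seed = 1L) {
  stopifnot(length(mu) == jtraj$K, sigma >= 0)
  s <- jump_state_at(jtraj, sample_times)
  set.seed(as.integer(seed))
  w <- mu[s] + if (sigma > 0) rnorm(length(s), 0, sigma) else 0
  dts <- diff(sample_times)
  out <- new_observation_series(times = sample_times, w = w,
                                dt = if (length(dts)) median(dts) else NA)
  attr(out, "true_states") <- s
  out
}

.uniform_dt <- function(times) {
  dts <- diff(times)
  if (length(dts) == 0L) stop("need at least two observations")
  if (max(abs(dts - dts[1L])) > 1e-9 * max(abs(dts)))
    stop("observation times must be uniformly spaced")
  dts[1L]
}

#' Likelihood of instantaneous observations under a jump process
#'
#' For uniformly spaced observations the skeleton chain is an exact
#' discrete-time HMM with transition matrix P(dt) = expm(Q dt), so the
#' log-likelihood is the scaled forward recursion with that transition
#' matrix and the Gaussian emission densities.
#'
#' @param Q a [rate_matrix()].
#' @param rho initial probability vector.
#' @param mu,sigma Gaussian emission means and (shared) sd.
#' @param w an `observation_series` with uniform spacing (or a numeric
#'   vector together with `dt`).
#' @param dt observation spacing, s; taken from `w` when available.
#' @return Log-likelihood in nats.
#' @export
hmjp_loglik <- function(Q, rho, mu, sigma, w, dt = NULL) {
  stopifnot(inherits(Q, "rate_matrix"), length(mu) == Q$K, sigma > 0)
  if (inherits(w, "observation_series")) {
    dt <- .uniform_dt(w$times)
    w <- w$w
  }
  if (is.null(dt)) stop("dt required when w is a bare numeric vector")
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q$Q * dt)))
  if (any(!is.finite(P)))
    stop("matrix exponential produced non-finite entries; max |Q| dt = ",
         signif(max(abs(Q$Q)) * dt, 4))
  P[P < 0] <- 0 # clip tiny negative round-off
  P <- P / rowSums(P)
  logB <- matrix(vapply(seq_len(Q$K),
                        function(k) dnorm(w, mu[k], sigma, log = TRUE),
                        numeric(length(w))), nrow = length(w))
  .forward_ll_cpp(logB, P, rho)
}

#' Maximum-likelihood jump rates from discrete observations
#'
#' Numerical maximization of [hmjp_loglik()] over the off-diagonal rates,
#' parameterized in log space for positivity, with seeded multistart
#' (L-BFGS-B on the negative log-likelihood). Emission means and sd are
#' held fixed by default; set `free_emissions = TRUE` to optimize them
#' jointly.
#'
#' @param w an `observation_series` (uniform spacing).
#' @param K number of states.
#' @param mu,sigma emission parameters (initial values when
#'   `free_emissions`).
#' @param rho initial distribution (fixed; default uniform).
#' @param n_starts multistart count.
#' @param seed integer RNG seed.
#' @param free_emissions optimize mu and log(sigma) too.
#' @return list: `Q` (a `rate_matrix`), `loglik`, `mu`, `sigma`,
#'   `converged` (optimizer convergence of the best start), `flagged`
#'   (`TRUE` when no start converged cleanly).
#' @export
fit_hmjp_rates <- function(w, K, mu, sigma, rho = rep(1 / K, K),
                           n_starts = 3L, seed = 1L,
                           free_emissions = FALSE) {
  stopifnot(inherits(w, "observation_series"))
  dt <- .uniform_dt(w$times)
  K <- as.integer(K)
  n_rates <- K * (K - 1L)
  off_idx <- which(row(diag(K)) != col(diag(K)))
  build_Q <- function(log_rates) {
    L <- matrix(0, K, K)
    L[off_idx] <- exp(log_rates)
    rate_matrix(L)
  }
  negll <- function(par) {
    lr <- par[seq_len(n_rates)]
    if (free_emissions) {
      mu_c <- par[n_rates + seq_len(K)]
      sig_c <- exp(par[n_rates + K + 1L])
    } else {
      mu_c <- mu; sig_c <- sigma
    }
    val <- tryCatch(-hmjp_loglik(build_Q(lr), rho, mu_c, sig_c, w$w,
                                 dt = dt),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e12 else val
  }
  # center starts on the scale of one jump per ~20 observation intervals
  base_rate <- 1 / (20 * dt)
  set.seed(as.integer(seed))
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    par0 <- log(base_rate) + rnorm(n_rates, 0, 1)
    if (free_emissions) par0 <- c(par0, mu, log(sigma))
    opt <- optim(par0, negll, method = "L-BFGS-B",
                 lower = c(rep(log(1e-12), n_rates),
                           rep(-Inf, length(par0) - n_rates)),
                 upper = c(rep(log(0.2 / dt), n_rates),
                           rep(Inf, length(par0) - n_rates)),
                 control = list(maxit = 300L))
    if (opt$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- best$par
  mu_h <- if (free_emissions) par[n_rates + seq_len(K)] else mu
  sig_h <- if (free_emissions) exp(par[n_rates + K + 1L]) else sigma
  list(Q = build_Q(par[seq_len(n_rates)]), loglik = -best$value,
       mu = mu_h, sigma = sig_h,
       converged = best$convergence == 0L, flagged = !any_conv)
}
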