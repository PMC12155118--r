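#' Configuration for the Beta-Bernoulli nonparametric HMM
#'
#' The generative model over an overcomplete budget of `K_max` states:
#' \itemize{
#'   \item activation probability q_k ~ Beta(load_beta_a, load_beta_b) and
#'     load b_k | q_k ~ Bernoulli(q_k) for each state (q_k is marginalized
#'     analytically, giving P(b_k = 1) = a/(a+b); the defaults a = 1,
#'     b = K_max keep the expected active count near 1 and favor sparsity);
#'   \item transition rows over the active states ~ Dirichlet(alpha_dir)
#'     (represented internally as full K_max rows, whose restriction to the
#'     active set is Dirichlet by aggregation);
#'   \item emission means mu_k | sigma^2 ~ Normal(m0, sigma^2/n0) and a
#'     shared sigma^2 ~ Inverse-Gamma(a0, b0);
#'   \item hidden states and Gaussian emissions as in the parametric HMM.
#' }
#' At least one state is always active. Emission-prior defaults (`m0`,
#' `b0`) marked `NULL` are resolved from the data scale when the sampler
#' starts: m0 = mean(w), b0 = var(w) (a vague prior centered on the
#' marginal spread).
#'
#' @param K_max overcomplete state budget (>= 2).
#' @param load_beta_a,load_beta_b Beta hyperparameters (> 0);
#'   `load_beta_b = NULL` resolves to `K_max`.
#' @param alpha_dir symmetric Dirichlet concentration for transition and
#'   initial-state rows.
#' @param m0,n0,a0,b0 Normal-Inverse-Gamma emission prior.
#' @param n_sweeps,burn_in,thin MCMC schedule (`n_sweeps > burn_in`).
#' @param seed integer RNG seed.
#' @return An object of class `bnp_config`.
#' @export
bnp_config <- function(K_max = 10L, load_beta_a = 1, load_beta_b = NULL,
                       alpha_dir = 1, m0 = NULL, n0 = 0.01, a0 = 2,
                       b0 = NULL, n_sweeps = 1000L, burn_in = 500L,
                       thin = 1L, seed = 1L) {
  K_max <- as.integer(K_max)
  if (is.null(load_beta_b)) load_beta_b <- K_max
  stopifnot(K_max >= 2L, load_beta_a > 0, load_beta_b > 0, alpha_dir > 0,
            n0 > 0, a0 > 0, n_sweeps > burn_in, burn_in >= 0, thin >= 1)
  structure(list(K_max = K_max, load_beta_a = load_beta_a,
                 load_beta_b = load_beta_b, alpha_dir = alpha_dir,
                 m0 = m0, n0 = n0, a0 = a0, b0 = b0,
                 n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "bnp_config")
}

.resolve_bnp_prior <- function(cfg, w) {
  if (is.null(cfg$m0)) cfg$m0 <- if (length(w)) mean(w) else 0
  if (is.null(cfg$b0)) cfg$b0 <- if (length(w) > 1L) max(var(w), 1e-12) else 1
  cfg
}

.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

# effective transition matrix / initial law over the active set
.eff_Pi <- function(V, active) {
  P <- V[active, active, drop = FALSE]
  P / rowSums(P)
}
.eff_rho <- function(rho_full, active) {
  r <- rho_full[active]
  r / sum(r)
}

.bnp_marg_ll <- function(w, state, active) {
  if (length(w) == 0L) return(0)
  mu <- state$mu[active]
  logB <- vapply(seq_along(active),
                 function(i) dnorm(w, mu[i], state$sigma, log = TRUE),
                 numeric(length(w)))
  logB <- matrix(logB, nrow = length(w))
  .forward_ll_cpp(logB, .eff_Pi(state$V, active),
                  .eff_rho(state$rho_full, active))
}

#' Draw a full sampler state from the prior
#'
#' Forward simulation of the generative model (loads conditioned on at
#' least one active state, full-row Dirichlet bookkeeping, NIG emissions,
#' and a hidden path of length `N`). Used for initialization and for
#' prior-vs-Gibbs sampler diagnostics.
#'
#' @param cfg a [bnp_config()] with explicit `m0` and `b0`.
#' @param N hidden-path length.
#' @return A `bnp_state` list: `loads`, `V`, `rho_full`, `mu`, `sigma`,
#'   `state_seq`.
#' @export
bnp_prior_draw <- function(cfg, N) {
  stopifnot(inherits(cfg, "bnp_config"), !is.null(cfg$m0), !is.null(cfg$b0))
  K <- cfg$K_max
  p1 <- cfg$load_beta_a / (cfg$load_beta_a + cfg$load_beta_b)
  repeat {
    loads <- runif(K) < p1
    if (any(loads)) break
  }
  V <- t(vapply(seq_len(K), function(j) .rdirichlet(rep(cfg$alpha_dir, K)),
                numeric(K)))
  rho_full <- .rdirichlet(rep(cfg$alpha_dir, K))
  sigma2 <- 1 / rgamma(1L, shape = cfg$a0, rate = cfg$b0)
  mu <- rnorm(K, cfg$m0, sqrt(sigma2 / cfg$n0))
  active <- which(loads)
  state_seq <- integer(N)
  if (N > 0L) {
    P <- .eff_Pi(V, active)
    r <- .eff_rho(rho_full, active)
    s <- sample.int(length(active), 1L, prob = r)
    state_seq[1L] <- active[s]
    if (N > 1L) for (n in 2:N) {
      s <- sample.int(length(active), 1L, prob = P[s, ])
      state_seq[n] <- active[s]
    }
  }
  structure(list(loads = loads, V = V, rho_full = rho_full, mu = mu,
                 sigma = sqrt(sigma2), state_seq = state_seq),
            class = "bnp_state")
}

#' Simulate observations from a sampler state
#'
#' w_n ~ Normal(mu at the hidden state, sigma); the emission half of the
#' generative model, used in sampler diagnostics.
#'
#' @param state a `bnp_state`.
#' @return Numeric vector, length of `state$state_seq`.
#' @export
bnp_emit <- function(state) {
  rnorm(length(state$state_seq), state$mu[state$state_seq], state$sigma)
}

#' One Gibbs sweep of the Beta-Bernoulli HMM sampler
#'
#' Update order within a sweep:
#' \enumerate{
#'   \item each load b_k by a Metropolis move targeting its conditional
#'     with the hidden path marginalized out (marginal likelihood from the
#'     forward recursion with b_k toggled; a move deactivating every state
#'     is rejected outright);
#'   \item the hidden path by forward filtering backward sampling over the
#'     active states (drawn immediately after the loads, as partial
#'     collapsing requires);
#'   \item transition rows and the initial law by conjugate Dirichlet
#'     updates from transition counts (active block from its posterior,
#'     inactive block refreshed from the prior via Dirichlet aggregation);
#'   \item emission means and the shared sigma by conjugate
#'     Normal-Inverse-Gamma updates (states with no assigned data fall
#'     back to their conditional prior, so inactive states carry
#'     prior-drawn parameters).
#' }
#' With no observations every update reduces to a prior draw.
#'
#' @param state a `bnp_state` (at least one load active).
#' @param w numeric observations (possibly length 0).
#' @param cfg a [bnp_config()] with resolved `m0`, `b0`.
#' @return The updated `bnp_state`; attribute `"accept"` carries the
#'   count of accepted load toggles out of `K_max` proposed.
#' @export
bnp_gibbs_sweep <- function(state, w, cfg) {
  stopifnot(inherits(state, "bnp_state"), any(state$loads))
  K <- cfg$K_max
  N <- length(w)
  log_prior_odds <- log(cfg$load_beta_a) - log(cfg$load_beta_b)
  ## (1) loads, hidden path marginalized
  ll_cur <- .bnp_marg_ll(w, state, which(state$loads))
  n_acc <- 0L
  for (k in seq_len(K)) {
    loads_prop <- state$loads
    loads_prop[k] <- !loads_prop[k]
    if (!any(loads_prop)) next # deactivating every state: rejected
    ll_prop <- .bnp_marg_ll(w, state, which(loads_prop))
    log_r <- ll_prop - ll_cur +
      if (loads_prop[k]) log_prior_odds else -log_prior_odds
    if (log(runif(1L)) < log_r) {
      state$loads <- loads_prop
      ll_cur <- ll_prop
      n_acc <- n_acc + 1L
    }
  }
  active <- which(state$loads)
  m <- length(active)
  ## (2) hidden path by FFBS
  if (N > 0L) {
    mu_a <- state$mu[active]
    logB <- matrix(vapply(seq_len(m),
                          function(i) dnorm(w, mu_a[i], state$sigma,
                                            log = TRUE),
                          numeric(N)), nrow = N)
    idx <- .ffbs_cpp(logB, .eff_Pi(state$V, active),
                     .eff_rho(state$rho_full, active), runif(N))
    state$state_seq <- active[idx]
  } else {
    state$state_seq <- integer(0L)
  }
  ## (3) transition rows and initial law (Dirichlet aggregation)
  a <- cfg$alpha_dir
  inact <- setdiff(seq_len(K), active)
  counts <- matrix(0, K, K)
  if (N > 1L) {
    from <- state$state_seq[-N]
    to <- state$state_seq[-1L]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  compose_row <- function(cnt_active) {
    wa <- .rdirichlet(a + cnt_active)
    if (length(inact) == 0L) {
      row <- numeric(K)
      row[active] <- wa
      return(row)
    }
    wi <- .rdirichlet(rep(a, length(inact)))
    t_mix <- rbeta(1L, m * a, length(inact) * a)
    row <- numeric(K)
    row[active] <- t_mix * wa
    row[inact] <- (1 - t_mix) * wi
    row
  }
  state$V <- t(vapply(seq_len(K), function(j) compose_row(counts[j, active]),
                      numeric(K)))
  rho_cnt <- numeric(m)
  if (N > 0L) rho_cnt[match(state$state_seq[1L], active)] <- 1
  state$rho_full <- compose_row(rho_cnt)
  ## (4) emissions: shared-sigma Normal-Inverse-Gamma
  nk <- tabulate(state$state_seq, K)
  swk <- numeric(K)
  if (N > 0L) for (k in seq_len(K))
    if (nk[k] > 0L) swk[k] <- sum(w[state$state_seq == k])
  post_prec <- cfg$n0 + nk
  post_mean <- (cfg$n0 * cfg$m0 + swk) / post_prec
  state$mu <- rnorm(K, post_mean, state$sigma / sqrt(post_prec))
  rss <- if (N > 0L) sum((w - state$mu[state$state_seq])^2) else 0
  prior_ss <- cfg$n0 * sum((state$mu - cfg$m0)^2)
  sigma2 <- 1 / rgamma(1L, shape = cfg$a0 + (N + K) / 2,
                       rate = cfg$b0 + 0.5 * rss + 0.5 * prior_ss)
  state$sigma <- sqrt(sigma2)
  attr(state, "accept") <- n_acc
  state
}

#' Run the Beta-Bernoulli nonparametric HMM
#'
#' Seeded Gibbs chain; retains samples after burn-in (thinned) and
#' summarizes the posterior over the number of active states. The
#' representative trajectory is the pointwise most frequent state among
#' retained samples whose active count equals the posterior mode, after
#' aligning labels by sorting each sample's active means.
#'
#' A crude stationarity screen (first vs second half of the active-count
#' trace differing by more than two standard errors) sets
#' `stationarity_warning` rather than failing silently.
#'
#' @param w observations (`observation_series`, `trajectory`, or numeric).
#' @param cfg a [bnp_config()].
#' @return An object of class `bnp_posterior`: `count_hist` (histogram of
#'   active-state counts over retained samples), `modal_count`,
#'   `representative_path` (integer labels 1..modal_count),
#'   `representative_levels` (posterior mean emission level per label),
#'   `mu_samples`, `sigma_samples`, `count_trace`, `accept_rate`,
#'   `stationarity_warning`, `n_retained`.
#' @export
run_bnp <- function(w, cfg = bnp_config()) {
  w <- as_observation_vector(w)
  cfg <- .resolve_bnp_prior(cfg, w)
  N <- length(w)
  set.seed(cfg$seed)
  state <- bnp_prior_draw(cfg, N)
  n_keep <- length(seq.int(cfg$burn_in + 1L, cfg$n_sweeps, by = cfg$thin))
  counts_kept <- integer(n_keep)
  mu_kept <- matrix(NA_real_, n_keep, cfg$K_max)
  sig_kept <- numeric(n_keep)
  loads_kept <- matrix(FALSE, n_keep, cfg$K_max)
  paths <- matrix(NA_integer_, n_keep, N)
  count_trace <- integer(cfg$n_sweeps)
  acc <- 0L
  j <- 0L
  for (sweep in seq_len(cfg$n_sweeps)) {
    state <- bnp_gibbs_sweep(state, w, cfg)
    acc <- acc + attr(state, "accept")
    count_trace[sweep] <- sum(state$loads)
    if (sweep > cfg$burn_in && (sweep - cfg$burn_in - 1L) %% cfg$thin == 0L) {
      j <- j + 1L
      counts_kept[j] <- sum(state$loads)
      mu_kept[j, ] <- state$mu
      sig_kept[j] <- state$sigma
      loads_kept[j, ] <- state$loads
      if (N > 0L) paths[j, ] <- state$state_seq
    }
  }
  hist_tab <- table(factor(counts_kept, levels = seq_len(cfg$K_max)))
  modal <- as.integer(names(hist_tab)[which.max(hist_tab)])
  ## representative path at the modal count, labels aligned by sorting means
  rep_path <- NULL
  rep_levels <- NULL
  sel <- which(counts_kept == modal)
  if (N > 0L && length(sel) > 0L) {
    votes <- matrix(0L, N, modal)
    lvl_sum <- numeric(modal)
    for (i in sel) {
      act <- which(loads_kept[i, ])
      ord <- act[order(mu_kept[i, act])]
      lab <- match(paths[i, ], ord)
      votes[cbind(seq_len(N), lab)] <- votes[cbind(seq_len(N), lab)] + 1L
      lvl_sum <- lvl_sum + mu_kept[i, ord]
    }
    rep_path <- max.col(votes, ties.method = "first")
    rep_levels <- lvl_sum / length(sel)
  }
  ## stationarity screen on the post-burn-in count trace
  tr <- count_trace[(cfg$burn_in + 1L):cfg$n_sweeps]
  h <- length(tr) %/% 2L
  warn <- FALSE
  if (h >= 10L) {
    a1 <- tr[seq_len(h)]; a2 <- tr[(h + 1L):length(tr)]
    se <- sqrt(var(a1) / h + var(a2) / (length(tr) - h))
    warn <- is.finite(se) && se > 0 && abs(mean(a1) - mean(a2)) > 2 * se
  }
  if (warn)
    warning("active-state count trace may not be stationary; ",
            "consider more sweeps or a longer burn-in")
  structure(list(count_hist = hist_tab, modal_count = modal,
                 representative_path = rep_path,
                 representative_levels = rep_levels,
                 mu_samples = mu_kept, sigma_samples = sig_kept,
                 loads_samples = loads_kept,
                 count_trace = count_trace,
                 accept_rate = acc / (cfg$n_sweeps * cfg$K_max),
                 stationarity_warning = warn,
                 n_retained = j, config = cfg),
            class = "bnp_posterior")
}

#' @export
print.bnp_posterior <- function(x, ...) {
  cat("<bnp_posterior> modal active states:", x$modal_count,
      " (", x$n_retained, "retained samples )\n")
  nz <- x$count_hist[x$count_hist > 0]
  cat("  count posterior:",
      paste(names(nz), "->", as.integer(nz), collapse = ", "), "\n")
  cat("  load-move acceptance rate:", signif(x$accept_rate, 3), "\n")
  if (x$stationarity_warning) cat("  [stationarity warning]\n")
  invisible(x)
}
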