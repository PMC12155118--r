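#' Parameters of a Gaussian-emission hidden Markov model
#'
#' The canonical parameter container: initial distribution `rho`, row-
#' stochastic transition matrix `Pi`, per-state emission means `mu` (nm)
#' and emission standard deviation `sigma` (shared scalar by default; a
#' length-K vector for per-state variances). States are kept in ascending
#' order of `mu` (the canonical label order used everywhere in the
#' package).
#'
#' @param rho length-K probability vector (sums to 1 within 1e-10).
#' @param Pi K x K transition matrix, rows summing to 1 within 1e-10.
#' @param mu length-K emission means, nm.
#' @param sigma positive scalar or length-K vector, nm.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(rho, Pi, mu, sigma) {
  K <- length(mu)
  Pi <- as.matrix(Pi)
  stopifnot(length(rho) == K, nrow(Pi) == K, ncol(Pi) == K,
            all(rho >= 0), all(Pi >= 0), all(sigma > 0),
            length(sigma) %in% c(1L, K))
  if (abs(sum(rho) - 1) > 1e-10) stop("rho must sum to 1")
  if (any(abs(rowSums(Pi) - 1) > 1e-10))
    stop("every row of Pi must sum to 1")
  structure(list(K = K, rho = as.numeric(rho), Pi = unname(Pi),
                 mu = as.numeric(mu), sigma = as.numeric(sigma)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> K =", x$K, "\n")
  cat("  mu:    ", paste(signif(x$mu, 5), collapse = " "), "\n")
  cat("  sigma: ", paste(signif(x$sigma, 5), collapse = " "), "\n")
  cat("  diag(Pi):", paste(signif(diag(x$Pi), 4), collapse = " "), "\n")
  invisible(x)
}

.sigma_vec <- function(params) {
  if (length(params$sigma) == 1L) rep(params$sigma, params$K)
  else params$sigma
}

.log_emissions <- function(params, w) {
  sig <- .sigma_vec(params)
  vapply(seq_len(params$K),
         function(k) dnorm(w, params$mu[k], sig[k], log = TRUE),
         numeric(length(w)))
}

#' Log-likelihood of an observation series under an HMM
#'
#' Computed with the scaled forward recursion.
#'
#' @param params an [hmm_params()].
#' @param w an `observation_series`, `trajectory`, or numeric vector (nm).
#' @return log P(w | params) in nats.
#' @export
forward_loglik <- function(params, w) {
  stopifnot(inherits(params, "hmm_params"))
  w <- as_observation_vector(w)
  if (length(w) < 1L) stop("need at least one observation")
  logB <- matrix(.log_emissions(params, w), nrow = length(w))
  .forward_ll_cpp(logB, params$Pi, params$rho)
}

#' Most probable state path (Viterbi decoding)
#'
#' Deterministic; ties resolved toward the lower state index.
#'
#' @inheritParams forward_loglik
#' @return Integer vector of 1-based state indices.
#' @export
viterbi <- function(params, w) {
  stopifnot(inherits(params, "hmm_params"))
  w <- as_observation_vector(w)
  logB <- matrix(.log_emissions(params, w), nrow = length(w))
  as.integer(.viterbi_cpp(logB, params$Pi, params$rho))
}

#' Number of free parameters of a K-state Gaussian HMM
#'
#' (K-1) free initial probabilities + K(K-1) free transition entries + K
#' means + 1 shared standard deviation (K if per-state). This is the count
#' the BIC penalty uses; it is recorded with every fit.
#'
#' @param K state count.
#' @param per_state_sigma logical.
#' @return Integer parameter count.
#' @export
n_hmm_params <- function(K, per_state_sigma = FALSE) {
  as.integer((K - 1) + K * (K - 1) + K + if (per_state_sigma) K else 1L)
}

#' Bayesian information criterion
#'
#' bic = n_params * ln(N) - 2 * loglik (nats); smaller is better.
#'
#' @param loglik log-likelihood in nats.
#' @param n_params free-parameter count.
#' @param N number of observations.
#' @return BIC in nats.
#' @export
bic_score <- function(loglik, n_params, N) {
  stopifnot(N >= 1)
  n_params * log(N) - 2 * loglik
}

# quantile-based initialization: scale-free and reproducible
.em_init <- function(w, K, jitter_sd = 0) {
  probs <- (seq_len(K) - 0.5) / K
  mu <- as.numeric(quantile(w, probs, names = FALSE))
  if (jitter_sd > 0) mu <- mu + rnorm(K, 0, jitter_sd)
  mu <- sort(mu)
  # pooled within-quantile-slice sd
  cuts <- as.numeric(quantile(w, seq(0, 1, length.out = K + 1L),
                              names = FALSE))
  grp <- findInterval(w, cuts, all.inside = TRUE)
  dev <- w - mu[grp]
  sigma <- sqrt(mean(dev^2))
  if (!is.finite(sigma) || sigma <= 0) sigma <- sd(w) / K + 1e-8
  Pi <- matrix(0.1 / (K - 1 + (K == 1)), K, K)
  diag(Pi) <- if (K == 1) 1 else 0.9
  list(rho = rep(1 / K, K), Pi = Pi, mu = mu, sigma = sigma)
}

# sort states by mean, permuting rho/Pi consistently
.sort_params <- function(rho, Pi, mu, sigma) {
  o <- order(mu)
  list(rho = rho[o], Pi = Pi[o, o, drop = FALSE], mu = mu[o],
       sigma = if (length(sigma) > 1L) sigma[o] else sigma)
}

#' Fit a Gaussian-emission HMM by Baum-Welch EM
#'
#' Multi-restart EM point estimation. The first restart initializes the
#' emission means at K evenly spaced quantiles of the data; further
#' restarts jitter the means. Restarts that collapse (a state's
#' responsibility mass vanishing) are discarded; if every restart
#' collapses the best fit is returned with `degenerate = TRUE`.
#'
#' @param w observations (`observation_series`, `trajectory`, or numeric).
#' @param K number of states (N > K required).
#' @param n_restarts EM restarts (default 5).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed controlling the restart jitter.
#' @param per_state_sigma if `TRUE`, each state gets its own emission sd
#'   (the BIC parameter count adjusts).
#' @param init optional `hmm_params` used as one additional restart
#'   (e.g. a smaller model embedded into K states).
#' @return An object of class `hmm_fit` with elements `params`, `loglik`,
#'   `n_params`, `bic`, `viterbi_path`, `converged`, `n_iter`,
#'   `n_restarts_used`, `degenerate`, `loglik_trace`.
#' @export
fit_hmm_em <- function(w, K, n_restarts = 5L, tol = 1e-8, max_iter = 500L,
                       seed = 1L, per_state_sigma = FALSE, init = NULL) {
  w <- as_observation_vector(w)
  N <- length(w)
  K <- as.integer(K)
  if (N <= K) stop("need more observations than states (N > K)")
  sigma_floor <- 1e-8 * max(sd(w), 1e-12)
  set.seed(as.integer(seed))
  jitters <- c(0, abs(rnorm(max(n_restarts - 1L, 0L), 0, sd(w) / K)))
  starts <- lapply(seq_len(n_restarts), function(r)
    .em_init(w, K, jitter_sd = jitters[r]))
  if (!is.null(init)) {
    stopifnot(inherits(init, "hmm_params"), init$K == K)
    starts <- c(starts, list(list(rho = init$rho, Pi = init$Pi,
                                  mu = init$mu,
                                  sigma = mean(.sigma_vec(init)))))
  }
  best <- NULL
  for (st in starts) {
    sig0 <- rep(if (length(st$sigma) == 1L) st$sigma else st$sigma, K)[1:K]
    res <- .em_cpp(w, st$rho, st$Pi, st$mu, sig0,
                   shared_sigma = !per_state_sigma, tol = tol,
                   max_iter = as.integer(max_iter),
                   sigma_floor = sigma_floor)
    if (res$degenerate && !is.null(best) && !best$degenerate) next
    ll <- tail(res$loglik_trace, 1L)
    if (is.null(best) ||
        (best$degenerate && !res$degenerate) ||
        (best$degenerate == res$degenerate && ll > best$ll)) {
      best <- list(res = res, ll = ll, degenerate = res$degenerate)
    }
  }
  res <- best$res
  srt <- .sort_params(res$rho, res$Pi, res$mu,
                      if (per_state_sigma) res$sigma else res$sigma[1L])
  params <- hmm_params(srt$rho, srt$Pi, srt$mu, srt$sigma)
  loglik <- forward_loglik(params, w)
  np <- n_hmm_params(K, per_state_sigma)
  structure(list(params = params, loglik = loglik, n_params = np,
                 bic = bic_score(loglik, np, N),
                 viterbi_path = viterbi(params, w),
                 converged = isTRUE(res$converged),
                 degenerate = isTRUE(best$degenerate),
                 n_iter = res$n_iter,
                 n_restarts_used = length(starts),
                 loglik_trace = res$loglik_trace, N = N),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit> K =", x$params$K, " loglik =", signif(x$loglik, 8),
      " BIC =", signif(x$bic, 8), "\n")
  cat("  converged:", x$converged, " iterations:", x$n_iter,
      if (x$degenerate) " [degenerate]" else "", "\n")
  print(x$params)
  invisible(x)
}

# embed a K-state fit into K+1 states: the new state duplicates the last
# mean (slightly offset) and is entered with negligible probability, so the
# embedded start scores essentially the old loglik and EM can only improve
.embed_params <- function(params, w) {
  K <- params$K
  eps <- 1e-6
  mu_new <- params$mu[K] + 1e-3 * max(sd(w), 1e-6)
  rho <- c(params$rho * (1 - eps), eps)
  Pi <- cbind(params$Pi * (1 - eps), rep(eps, K))
  Pi <- rbind(Pi, c(rep((1 - eps) / K, K), eps))
  hmm_params(rho / sum(rho), Pi / rowSums(Pi), c(params$mu, mu_new),
             mean(.sigma_vec(params)))
}

#' Select the number of HMM states by BIC
#'
#' Fits every candidate state count by [fit_hmm_em()] and returns the
#' candidate minimizing BIC (ties broken toward the smaller K —
#' parsimony). Each candidate K > min(candidates) receives one extra
#' restart initialized by embedding the previous candidate's fit, which
#' enforces the nested-model property loglik(K+1) >= loglik(K).
#'
#' @inheritParams fit_hmm_em
#' @param candidate_Ks integer vector of state counts to try (default 2:5).
#' @return An object of class `model_selection`: `candidate_Ks`, `fits`
#'   (one `hmm_fit` per candidate), `selected_K`, `selected_fit`.
#' @export
select_by_bic <- function(w, candidate_Ks = 2:5, n_restarts = 5L,
                          tol = 1e-8, max_iter = 500L, seed = 1L,
                          per_state_sigma = FALSE) {
  w <- as_observation_vector(w)
  candidate_Ks <- sort(unique(as.integer(candidate_Ks)))
  stopifnot(length(candidate_Ks) >= 1L, all(candidate_Ks < length(w)))
  fits <- vector("list", length(candidate_Ks))
  prev <- NULL
  for (i in seq_along(candidate_Ks)) {
    K <- candidate_Ks[i]
    init <- if (!is.null(prev) && prev$params$K == K - 1L)
      .embed_params(prev$params, w) else NULL
    fits[[i]] <- fit_hmm_em(w, K, n_restarts = n_restarts, tol = tol,
                            max_iter = max_iter, seed = seed + K,
                            per_state_sigma = per_state_sigma, init = init)
    prev <- fits[[i]]
  }
  bics <- vapply(fits, `[[`, numeric(1L), "bic")
  sel <- which(bics == min(bics))[1L] # ties toward smaller K (sorted)
  structure(list(candidate_Ks = candidate_Ks, fits = fits,
                 selected_K = candidate_Ks[sel],
                 selected_fit = fits[[sel]]),
            class = "model_selection")
}

#' Read and write HMM fits as structured text
#'
#' Fits serialize to JSON: parameters, log-likelihood, parameter count,
#' BIC, convergence flags, and the Viterbi path stored run-length encoded
#' (`path_values`/`path_lengths`).
#'
#' @param fit an `hmm_fit`.
#' @param path file path.
#' @return `read_hmm_fit` returns the `hmm_fit`; the writer returns
#'   `path` invisibly.
#' @export
write_hmm_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hmm_fit"))
  r <- rle(fit$viterbi_path)
  obj <- list(K = fit$params$K, rho = fit$params$rho, Pi = fit$params$Pi,
              mu = fit$params$mu, sigma = fit$params$sigma,
              loglik = fit$loglik, n_params = fit$n_params,
              bic = fit$bic, converged = fit$converged,
              degenerate = fit$degenerate, n_iter = fit$n_iter,
              n_restarts_used = fit$n_restarts_used, N = fit$N,
              path_values = r$values, path_lengths = r$lengths)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_fit
#' @export
read_hmm_fit <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(params = hmm_params(o$rho, matrix(unlist(o$Pi), o$K, o$K),
                                     o$mu, o$sigma),
                 loglik = o$loglik, n_params = as.integer(o$n_params),
                 bic = o$bic,
                 viterbi_path = inverse.rle(structure(
                   list(lengths = as.integer(o$path_lengths),
                        values = as.integer(o$path_values)),
                   class = "rle")),
                 converged = o$converged, degenerate = o$degenerate,
                 n_iter = as.integer(o$n_iter),
                 n_restarts_used = as.integer(o$n_restarts_used),
                 N = as.integer(o$N)),
            class = "hmm_fit")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> candidates:",
      paste(x$candidate_Ks, collapse = " "), "\n")
  bics <- vapply(x$fits, `[[`, numeric(1L), "bic")
  lls <- vapply(x$fits, `[[`, numeric(1L), "loglik")
  for (i in seq_along(x$candidate_Ks))
    cat(sprintf("  K = %d  loglik = %.2f  BIC = %.2f%s\n",
                x$candidate_Ks[i], lls[i], bics[i],
                if (x$candidate_Ks[i] == x$selected_K) "  <- selected"
                else ""))
  invisible(x)
}
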