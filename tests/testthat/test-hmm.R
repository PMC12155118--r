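test_that("forward log-likelihood matches brute-force enumeration", {
  # random parameter draws, N <= 8, K <= 3
  cases <- expand.grid(K = 2:3, rep = 1:10)
  for (i in seq_len(nrow(cases))) {
    K <- cases$K[i]
    params <- random_hmm_params(K, seed = 100 + i)
    w <- sim_hmm_data(params, N = 6L + (i %% 3L), seed = 200 + i)$w
    expect_equal(forward_loglik(params, w), enum_loglik(params, w),
                 tolerance = 1e-9)
  }
})

test_that("K = 1 likelihood is the sum of log Normal densities", {
  params <- hmm_params(1, matrix(1), 0.3, 1.2)
  w <- rnorm(50)
  expect_equal(forward_loglik(params, w),
               sum(dnorm(w, 0.3, 1.2, log = TRUE)), tolerance = 1e-10)
  expect_equal(viterbi(params, w), rep(1L, 50L))
})

test_that("log-likelihood is invariant under state relabeling", {
  params <- random_hmm_params(3, seed = 7)
  w <- sim_hmm_data(params, 40L, seed = 8)$w
  ll <- forward_loglik(params, w)
  perm <- c(3L, 1L, 2L)
  permuted <- hmm_params(params$rho[perm], params$Pi[perm, perm],
                         params$mu[perm], params$sigma)
  expect_equal(forward_loglik(permuted, w), ll, tolerance = 1e-12)
})

test_that("filtered distributions are proper at every step", {
  params <- random_hmm_params(3, seed = 3)
  w <- sim_hmm_data(params, 500L, seed = 4)$w
  logB <- sapply(1:3, function(k) dnorm(w, params$mu[k], params$sigma,
                                        log = TRUE))
  fb <- basinmirage:::.fb_cpp(logB, params$Pi, params$rho)
  expect_lt(max(abs(rowSums(fb$filtered) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-10)
})

test_that("viterbi matches enumeration and breaks ties to lower indices", {
  for (i in 1:10) {
    K <- 2L + (i %% 2L)
    params <- random_hmm_params(K, seed = 300 + i)
    w <- sim_hmm_data(params, 6L, seed = 400 + i)$w
    expect_identical(viterbi(params, w), enum_viterbi(params, w))
  }
  # exact tie: two identical states; lower index must win everywhere
  tied <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), c(0, 0), 1)
  expect_identical(viterbi(tied, rnorm(20)), rep(1L, 20L))
})

test_that("viterbi on well-separated 2-state data is near a threshold rule", {
  params <- two_state_params(p_stay = 0.97)
  dat <- sim_hmm_data(params, 4000L, seed = 17)
  path <- viterbi(params, dat$w)
  thresh <- ifelse(dat$w > 0, 2L, 1L)
  expect_lt(mean(path != thresh), 0.01)
})

test_that("EM recovers 2-state parameters and is monotone in loglik", {
  params <- two_state_params(p_stay = 0.98)
  dat <- sim_hmm_data(params, 5000L, seed = 23)
  fit <- fit_hmm_em(dat$w, K = 2L, n_restarts = 3L, seed = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$mu - c(-10, 10))), 0.3)
  expect_lt(max(abs(diag(fit$params$Pi) - 0.98)), 0.02)
  expect_equal(fit$params$sigma, 1, tolerance = 0.1)
  # EM ascent property on the restart's trace
  expect_true(all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik)))
  # means reported ascending
  expect_identical(fit$params$mu, sort(fit$params$mu))
})

test_that("K = 1 EM reduces to the closed-form Gaussian MLE", {
  set.seed(5)
  w <- rnorm(400, 3, 2)
  fit <- fit_hmm_em(w, K = 1L, n_restarts = 1L)
  expect_equal(fit$params$mu, mean(w), tolerance = 1e-6)
  expect_equal(fit$params$sigma, sqrt(mean((w - mean(w))^2)),
               tolerance = 1e-6) # divisor-N MLE, not sd()
  expect_equal(fit$bic, bic_score(fit$loglik, n_hmm_params(1L), 400L))
})

test_that("BIC bookkeeping matches its definition", {
  expect_identical(n_hmm_params(2L), 6L)
  expect_identical(n_hmm_params(3L), 12L)
  expect_identical(n_hmm_params(2L, per_state_sigma = TRUE), 7L)
  expect_equal(bic_score(-500, 6L, 100L), 6 * log(100) + 1000)
  fit <- fit_hmm_em(rnorm(100), K = 2L, n_restarts = 1L, seed = 2)
  expect_equal(fit$bic, fit$n_params * log(100) - 2 * fit$loglik)
})

test_that("model selection is nested-consistent and picks the truth", {
  params <- two_state_params(p_stay = 0.98)
  dat <- sim_hmm_data(params, 3000L, seed = 31)
  sel <- select_by_bic(dat$w, candidate_Ks = 2:4, n_restarts = 2L,
                       seed = 3)
  expect_identical(sel$selected_K, 2L)
  # containment: larger families never fit worse (embedded restarts)
  lls <- vapply(sel$fits, `[[`, numeric(1), "loglik")
  expect_true(all(diff(lls) >= -1e-6))
  # single candidate: returned as-is
  sel1 <- select_by_bic(dat$w, candidate_Ks = 3L, n_restarts = 1L,
                        seed = 1)
  expect_identical(sel1$selected_K, 3L)
})

test_that("loglik agrees with an independent HMM implementation", {
  # cross-check against hmmlearn (Python) on identical fixed parameters
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  params <- two_state_params(p_stay = 0.95, mu = c(-2, 3), sigma = 1.5)
  dat <- sim_hmm_data(params, 300L, seed = 41)
  wfile <- tempfile(fileext = ".txt")
  writeLines(format(dat$w, digits = 17), wfile)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import numpy as np",
    "from hmmlearn.hmm import GaussianHMM",
    sprintf("w = np.loadtxt(r'%s').reshape(-1, 1)", wfile),
    "m = GaussianHMM(n_components=2, covariance_type='diag', init_params='')",
    "m.startprob_ = np.array([0.5, 0.5])",
    "m.transmat_ = np.array([[0.95, 0.05], [0.05, 0.95]])",
    "m.means_ = np.array([[-2.0], [3.0]])",
    "m.covars_ = np.array([[1.5**2], [1.5**2]])",
    "print(repr(m.score(w)))"), script)
  out <- suppressWarnings(system2(py, script, stdout = TRUE, stderr = TRUE))
  ref <- suppressWarnings(as.numeric(tail(out, 1)))
  skip_if(is.na(ref), "hmmlearn unavailable")
  ll <- forward_loglik(params, dat$w)
  expect_equal(ll, ref, tolerance = 1e-6 * abs(ref))
  unlink(c(wfile, script))
})

test_that("fits round-trip through JSON with an RLE-coded path", {
  dat <- sim_hmm_data(two_state_params(), 500L, seed = 71)
  fit <- fit_hmm_em(dat$w, K = 2L, n_restarts = 1L, seed = 1)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_hmm_fit(fit, path)
  back <- read_hmm_fit(path)
  expect_equal(back$params$mu, fit$params$mu, tolerance = 1e-12)
  expect_equal(back$params$Pi, fit$params$Pi, tolerance = 1e-12)
  expect_identical(back$viterbi_path, fit$viterbi_path)
  expect_equal(back$bic, fit$bic, tolerance = 1e-9)
})

test_that("per-state variance flag adjusts the fit and the BIC count", {
  set.seed(61)
  params <- hmm_params(c(0.5, 0.5),
                       matrix(c(0.97, 0.03, 0.03, 0.97), 2, 2), c(-8, 8), 1)
  s <- sim_hmm_data(params, 4000L, seed = 62)$states
  w <- c(-8, 8)[s] + rnorm(4000L, 0, c(0.5, 2)[s])
  fit <- fit_hmm_em(w, K = 2L, n_restarts = 3L, seed = 1,
                    per_state_sigma = TRUE)
  expect_length(fit$params$sigma, 2L)
  expect_equal(fit$params$sigma, c(0.5, 2), tolerance = 0.15)
  expect_identical(fit$n_params, n_hmm_params(2L, TRUE))
})
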