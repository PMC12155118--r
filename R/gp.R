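#' Gaussian-process prior configuration for potentials
#'
#' A squared-exponential prior over the potential U(x):
#' cov(U(x), U(x')) = amplitude^2 exp(-(x-x')^2 / (2 length_scale^2)).
#' The force f = -dU/dx inherits a GP prior with the derivative kernel
#' cov(f(x), f(x')) = (amplitude/length_scale)^2 (1 - r^2/length_scale^2)
#' exp(-r^2 / (2 length_scale^2)), r = x - x', which is what the drift
#' regression in [fit_gp_potential()] uses.
#'
#' @param amplitude prior sd of U, kT (> 0).
#' @param length_scale smoothness scale, nm (> 0); `NULL` resolves at fit
#'   time to 1/5 of the explored range.
#' @param grid strictly increasing nm grid for representation; `NULL`
#'   resolves at fit time to 101 points over the data range.
#' @param jitter relative diagonal regularizer (multiplied by
#'   amplitude^2).
#' @return An object of class `gp_config`.
#' @export
gp_config <- function(amplitude = 2, length_scale = NULL, grid = NULL,
                      jitter = 1e-8) {
  stopifnot(amplitude > 0, jitter > 0,
            is.null(length_scale) || length_scale > 0,
            is.null(grid) || all(diff(grid) > 0))
  structure(list(amplitude = amplitude, length_scale = length_scale,
                 grid = grid, jitter = jitter),
            class = "gp_config")
}

.k_U <- function(x1, x2, A, ell) {
  d <- outer(x1, x2, "-")
  A^2 * exp(-d^2 / (2 * ell^2))
}

.k_force <- function(x1, x2, A, ell) {
  d <- outer(x1, x2, "-")
  (A / ell)^2 * (1 - d^2 / ell^2) * exp(-d^2 / (2 * ell^2))
}

#' Sample a smooth potential from the GP prior
#'
#' One zero-mean draw of U on the configured grid, returned as a
#' [tabulated_potential()] directly usable by [simulate_langevin()].
#'
#' @param cfg a [gp_config()] with explicit `grid` and `length_scale`.
#' @param seed integer RNG seed.
#' @return A tabulated `potential_spec` (kT on the grid).
#' @export
sample_gp_potential <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "gp_config"), !is.null(cfg$grid),
            !is.null(cfg$length_scale))
  Km <- .k_U(cfg$grid, cfg$grid, cfg$amplitude, cfg$length_scale)
  diag(Km) <- diag(Km) + cfg$jitter * cfg$amplitude^2
  L <- tryCatch(chol(Km), error = function(e)
    stop("GP covariance not positive definite after jitter; ",
         "increase jitter or shorten the grid"))
  set.seed(as.integer(seed))
  u <- drop(crossprod(L, rnorm(length(cfg$grid))))
  tabulated_potential(cfg$grid, u)
}

#' Drift observations from a trajectory
#'
#' Under Euler-Maruyama dynamics, y_n = zeta (x_{n+1} - x_n) / dt is an
#' unbiased observation of the force f(x_n) in dynamical units
#' (g nm/s^2), with exactly known variance 2 kT zeta / dt.
#'
#' @param traj a [trajectory][simulate_langevin] with uniform spacing.
#' @param zeta friction, g/s.
#' @param temperature kelvin.
#' @return data.frame with columns `x` (nm) and `y` (force, g nm/s^2);
#'   attribute `noise_var` carries the per-observation variance
#'   2 kT zeta / dt.
#' @export
drift_observations <- function(traj, zeta, temperature) {
  dt <- .uniform_dt(traj$times)
  x <- traj$positions
  y <- zeta * diff(x) / dt
  out <- data.frame(x = head(x, -1L), y = y)
  attr(out, "noise_var") <- 2 * thermal_energy(temperature) * zeta / dt
  attr(out, "dt") <- dt
  out
}

#' Reconstruct a potential from trajectory drift by GP regression
#'
#' The force field is inferred by GP regression of the drift observations
#' (binned to the representation grid; a bin of n raw increments carries
#' noise variance 2 kT zeta / (dt n), known exactly from the dynamics),
#' using the derivative kernel implied by the squared-exponential prior on
#' U. The potential estimate is the trapezoidal integral of the negative
#' posterior-mean force along the grid, anchored so its minimum is zero.
#' Pointwise uncertainty on U is propagated from the force posterior
#' variance under an independent-increment approximation, accumulated
#' outward from the anchoring minimum. Grid regions the trajectory never
#' visited receive no observations, so their force posterior reverts to
#' the prior and the reported sd is large there — no extrapolation is
#' claimed.
#'
#' The estimator assumes the positions are observed without readout noise
#' (the no-binning, no-noise regime); with readout noise present the
#' drift observations are biased and this estimator is not validated.
#'
#' @param traj a [trajectory][simulate_langevin].
#' @param zeta friction, g/s.
#' @param temperature kelvin.
#' @param cfg a [gp_config()]; `NULL` fields resolve from the data.
#' @return An object of class `potential_estimate`: `grid` (nm), `U_hat`
#'   (kT, min 0), `sd` (kT), `f_hat`/`f_sd` (kT/nm), `n_obs` per grid
#'   cell.
#' @export
fit_gp_potential <- function(traj, zeta, temperature, cfg = gp_config()) {
  obs <- drift_observations(traj, zeta, temperature)
  kT <- thermal_energy(temperature)
  y <- obs$y / kT                      # force in kT/nm
  v <- attr(obs, "noise_var") / kT^2   # per-observation variance
  rng <- range(obs$x)
  grid <- cfg$grid
  if (is.null(grid)) grid <- seq(rng[1L], rng[2L], length.out = 101L)
  ell <- cfg$length_scale
  if (is.null(ell)) ell <- diff(range(grid)) / 5
  A <- cfg$amplitude
  ## bin increments to nearest grid point; exact known noise per bin mean
  edges <- c(grid[1L] - Inf, (head(grid, -1L) + tail(grid, -1L)) / 2, Inf)
  cell <- findInterval(obs$x, edges, all.inside = TRUE)
  n_obs <- tabulate(cell, length(grid))
  used <- which(n_obs > 0L)
  ybar <- vapply(used, function(i) mean(y[cell == i]), numeric(1L))
  vbar <- v / n_obs[used]
  xo <- grid[used]
  ## GP regression of the force with the derivative kernel
  Koo <- .k_force(xo, xo, A, ell)
  diag(Koo) <- diag(Koo) + vbar + cfg$jitter * (A / ell)^2
  Kgo <- .k_force(grid, xo, A, ell)
  ch <- chol(Koo)
  alpha <- backsolve(ch, forwardsolve(t(ch), ybar))
  f_hat <- drop(Kgo %*% alpha)
  Vt <- forwardsolve(t(ch), t(Kgo))
  f_var <- pmax((A / ell)^2 - colSums(Vt^2), 0)
  ## integrate -f along the grid; anchor at the minimum
  dx <- diff(grid)
  incr <- -dx * (head(f_hat, -1L) + tail(f_hat, -1L)) / 2
  U <- c(0, cumsum(incr))
  U <- U - min(U)
  anchor <- which.min(U)
  incr_var <- dx^2 * (head(f_var, -1L) + tail(f_var, -1L)) / 4
  var_U <- numeric(length(grid))
  if (anchor > 1L)
    var_U[(anchor - 1L):1L] <- cumsum(incr_var[(anchor - 1L):1L])
  if (anchor < length(grid))
    var_U[(anchor + 1L):length(grid)] <- cumsum(incr_var[anchor:(length(grid) - 1L)])
  structure(list(grid = grid, U_hat = U, sd = sqrt(var_U),
                 f_hat = f_hat, f_sd = sqrt(f_var), n_obs = n_obs,
                 amplitude = A, length_scale = ell),
            class = "potential_estimate")
}

#' @export
print.potential_estimate <- function(x, ...) {
  cat("<potential_estimate> grid of", length(x$grid), "points,",
      signif(x$grid[1L], 4), "..", signif(x$grid[length(x$grid)], 4),
      "nm\n")
  cat("  U_hat range:", signif(max(x$U_hat), 4), "kT; length scale",
      signif(x$length_scale, 4), "nm\n")
  cat("  visited cells:", sum(x$n_obs > 0L), "/", length(x$grid), "\n")
  invisible(x)
}

#' Write a potential estimate as three-column text
#'
#' Columns: x (nm), U_hat (kT), sd (kT).
#' @param est a `potential_estimate`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_potential_estimate <- function(est, path) {
  utils::write.table(
    data.frame(x_nm = est$grid, U_kT = est$U_hat, sd_kT = est$sd),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
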