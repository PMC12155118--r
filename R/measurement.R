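#' Measurement configuration
#'
#' The measurement chain applied to a latent trajectory: boxcar averaging
#' over `bin_factor` consecutive samples (emulating a reduced acquisition
#' rate), then i.i.d. Gaussian readout noise of standard deviation
#' `sigma_read` added per *binned* point — averaging first, noising second.
#'
#' @param bin_factor integer >= 1.
#' @param sigma_read nm, >= 0.
#' @param seed integer RNG seed for the readout noise.
#' @return An object of class `measurement_config`.
#' @export
measurement_config <- function(bin_factor = 1L, sigma_read = 0, seed = 1L) {
  bin_factor <- as.integer(bin_factor)
  stopifnot(bin_factor >= 1L, sigma_read >= 0)
  structure(list(bin_factor = bin_factor, sigma_read = sigma_read,
                 seed = as.integer(seed)),
            class = "measurement_config")
}

#' Boxcar-average a trajectory
#'
#' Non-overlapping blocks of `B` consecutive samples are replaced by their
#' arithmetic mean. A trailing partial block is dropped. The time stamp of
#' a block is the time of its last constituent sample, so each binned point
#' stands for the (smoothed) state attained by its measurement time.
#'
#' @param traj a [trajectory][simulate_langevin].
#' @param B integer block size >= 1.
#' @return A `trajectory` with spacing `B * dt`.
#' @export
boxcar_bin <- function(traj, B) {
  B <- as.integer(B)
  n <- length(traj$positions)
  if (B < 1L) stop("B must be >= 1")
  if (B > n) stop("bin factor B = ", B, " exceeds trajectory length ", n)
  if (B == 1L) return(traj)
  m <- n %/% B
  idx <- seq_len(m * B)
  xm <- colMeans(matrix(traj$positions[idx], nrow = B))
  tm <- traj$times[idx][seq(B, m * B, by = B)]
  new_trajectory(times = tm, positions = xm, dt = traj$dt * B,
                 config = traj$config)
}

#' Add Gaussian readout noise
#'
#' w_n = x_n + eps_n with eps_n i.i.d. Normal(0, sigma_read^2).
#'
#' @param traj a trajectory (typically already binned).
#' @param sigma_read nm >= 0.
#' @param seed integer RNG seed.
#' @return An object of class `observation_series` with fields `times`,
#'   `w`, `dt`.
#' @export
add_readout_noise <- function(traj, sigma_read, seed = 1L) {
  stopifnot(sigma_read >= 0)
  set.seed(as.integer(seed))
  w <- traj$positions + if (sigma_read > 0)
    rnorm(length(traj$positions), 0, sigma_read) else 0
  new_observation_series(times = traj$times, w = w, dt = traj$dt,
                         sigma_read = sigma_read)
}

new_observation_series <- function(times, w, dt, sigma_read = NA_real_,
                                   bin_factor = NA_integer_) {
  stopifnot(length(times) == length(w))
  structure(list(times = times, w = w, dt = dt, sigma_read = sigma_read,
                 bin_factor = bin_factor),
            class = "observation_series")
}

#' @export
print.observation_series <- function(x, ...) {
  cat("<observation_series> ", length(x$w), " points, dt = ", x$dt, " s",
      sep = "")
  if (!is.na(x$sigma_read)) cat(", sigma_read = ", x$sigma_read, " nm",
                                sep = "")
  cat("\n")
  invisible(x)
}

#' Apply the full measurement chain
#'
#' Boxcar binning followed by readout noise, in that order.
#'
#' @param traj a [trajectory][simulate_langevin].
#' @param cfg a [measurement_config()].
#' @return An `observation_series`.
#' @export
observe <- function(traj, cfg) {
  stopifnot(inherits(cfg, "measurement_config"))
  binned <- boxcar_bin(traj, cfg$bin_factor)
  out <- add_readout_noise(binned, cfg$sigma_read, cfg$seed)
  out$bin_factor <- cfg$bin_factor
  out
}

# accept observation_series, trajectory, or bare numeric in analysis code
as_observation_vector <- function(w) {
  if (inherits(w, "observation_series")) return(w$w)
  if (inherits(w, "trajectory")) return(w$positions)
  if (is.numeric(w)) return(as.numeric(w))
  stop("cannot interpret input of class ", paste(class(w), collapse = "/"),
       " as observations")
}
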