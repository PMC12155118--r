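#' One-dimensional effective potentials
#'
#' Constructors for the potential families used throughout the package.
#' Energies are stored in kT units (the dynamical conversion happens in the
#' Langevin integrator), positions in nm.
#'
#' Available forms:
#' \describe{
#'   \item{harmonic}{U(x) = k x^2 / 2, stiffness `k` in kT/nm^2.}
#'   \item{double_well}{U(x) = dE ((x/a)^2 - 1)^2: a symmetric quartic
#'     double well with barrier height `dE` (kT) at x = 0 and minima at
#'     x = +/- a (nm). Barrier height and well separation tune
#'     independently.}
#'   \item{flat_well}{U(x) = H (x/L)^p with even wall exponent p >= 4:
#'     a single well with a broad flat bottom of halfwidth ~L and soft
#'     walls of height H (kT) at |x| = L.}
#'   \item{tabulated}{U sampled on a grid, interpolated with a natural
#'     cubic spline; the force comes from the spline derivative. Used for
#'     Gaussian-process potential draws and estimates.}
#' }
#'
#' @param stiffness kT/nm^2, > 0.
#' @param barrier_height kT, > 0.
#' @param half_separation nm, > 0; distance from the barrier top to each
#'   minimum.
#' @param wall_height kT, > 0; potential at |x| = `halfwidth`.
#' @param halfwidth nm, > 0.
#' @param wall_exponent even integer >= 4.
#' @param grid_x strictly increasing nm grid.
#' @param grid_U energies (kT) on `grid_x`.
#' @return An object of class `potential_spec`.
#' @examples
#' dw <- double_well_potential(barrier_height = 2, half_separation = 5)
#' evaluate_potential(dw, 0)    # 2 kT at the barrier top
#' evaluate_force(dw, 5)        # 0 at a minimum
#' @name potentials
NULL

new_potential_spec <- function(form, params) {
  spec <- c(list(form = form), params)
  class(spec) <- "potential_spec"
  spec
}

#' @rdname potentials
#' @export
harmonic_potential <- function(stiffness) {
  stopifnot(is.numeric(stiffness), length(stiffness) == 1L, stiffness > 0)
  new_potential_spec("harmonic", list(stiffness = stiffness))
}

#' @rdname potentials
#' @export
double_well_potential <- function(barrier_height, half_separation) {
  stopifnot(barrier_height > 0, half_separation > 0)
  new_potential_spec("double_well",
                     list(barrier_height = barrier_height,
                          half_separation = half_separation))
}

#' @rdname potentials
#' @export
flat_well_potential <- function(wall_height, halfwidth, wall_exponent = 4L) {
  stopifnot(wall_height > 0, halfwidth > 0)
  wall_exponent <- as.integer(wall_exponent)
  if (wall_exponent < 4L || wall_exponent %% 2L != 0L)
    stop("wall_exponent must be an even integer >= 4")
  new_potential_spec("flat_well",
                     list(wall_height = wall_height, halfwidth = halfwidth,
                          wall_exponent = wall_exponent))
}

#' @rdname potentials
#' @export
tabulated_potential <- function(grid_x, grid_U) {
  stopifnot(length(grid_x) == length(grid_U), length(grid_x) >= 4L,
            all(diff(grid_x) > 0), all(is.finite(grid_U)))
  spec <- new_potential_spec("tabulated",
                             list(grid_x = as.numeric(grid_x),
                                  grid_U = as.numeric(grid_U)))
  # natural boundary => second derivative 0 at the ends, smooth interior
  spec$.spline <- splinefun(grid_x, grid_U, method = "natural")
  spec
}

.check_tab_domain <- function(spec, x) {
  if (any(x < spec$grid_x[1L] | x > spec$grid_x[length(spec$grid_x)]))
    stop("position outside the tabulated potential's domain [",
         spec$grid_x[1L], ", ", spec$grid_x[length(spec$grid_x)], "] nm")
}

#' Evaluate a potential
#'
#' @param spec a [potential_spec][potentials].
#' @param x positions, nm (vectorized).
#' @return Energies in kT.
#' @export
evaluate_potential <- function(spec, x) {
  stopifnot(inherits(spec, "potential_spec"), is.numeric(x))
  switch(spec$form,
    harmonic = 0.5 * spec$stiffness * x^2,
    double_well = spec$barrier_height *
      ((x / spec$half_separation)^2 - 1)^2,
    flat_well = spec$wall_height * (x / spec$halfwidth)^spec$wall_exponent,
    tabulated = {
      .check_tab_domain(spec, x)
      spec$.spline(x)
    },
    stop("unknown potential form: ", spec$form))
}

#' Evaluate the force -dU/dx
#'
#' @inheritParams evaluate_potential
#' @return Forces in kT/nm.
#' @export
evaluate_force <- function(spec, x) {
  stopifnot(inherits(spec, "potential_spec"), is.numeric(x))
  switch(spec$form,
    harmonic = -spec$stiffness * x,
    double_well = {
      a <- spec$half_separation
      -4 * spec$barrier_height * x * ((x / a)^2 - 1) / a^2
    },
    flat_well = {
      p <- spec$wall_exponent
      -spec$wall_height * p * x^(p - 1L) / spec$halfwidth^p
    },
    tabulated = {
      .check_tab_domain(spec, x)
      -spec$.spline(x, deriv = 1L)
    },
    stop("unknown potential form: ", spec$form))
}

#' Boltzmann density of a potential on a grid
#'
#' Normalized equilibrium density p(x) proportional to exp(-U(x)) (U in kT),
#' normalized by the trapezoid rule over `grid`. A warning is issued when
#' the grid truncates non-negligible probability mass (boundary density
#' above 1e-6 of the maximum).
#'
#' @inheritParams evaluate_potential
#' @param grid strictly increasing nm grid covering the relevant region.
#' @return Numeric vector of densities (1/nm) on `grid`.
#' @export
boltzmann_density <- function(spec, grid) {
  stopifnot(is.numeric(grid), length(grid) >= 3L, all(diff(grid) > 0))
  u <- evaluate_potential(spec, grid)
  p <- exp(-(u - min(u)))
  z <- trapz(grid, p)
  p <- p / z
  if (max(p[c(1L, length(p))]) > 1e-6 * max(p))
    warning("grid may be too narrow: boundary density exceeds 1e-6 of the mode")
  p
}

# trapezoid rule; used for densities and for integrating forces
trapz <- function(x, y) sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec>", x$form, "\n")
  flds <- setdiff(names(x), c("form", ".spline"))
  for (f in flds) {
    v <- x[[f]]
    if (length(v) > 6L)
      cat("  ", f, ": [", length(v), " values, ",
          signif(min(v), 4), " .. ", signif(max(v), 4), "]\n", sep = "")
    else cat("  ", f, ": ", paste(signif(v, 6), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Named potential presets
#'
#' A small frozen library of regimes used by the scripted experiments:
#' \describe{
#'   \item{doublewell_2kT}{barrier 2 kT, minima at +/- 5 nm; the default
#'     double-well regime for the acquisition-rate/noise sweeps.}
#'   \item{doublewell_high_narrow}{barrier 4 kT, minima at +/- 4 nm: fast
#'     in-well fluctuations, infrequent crossings.}
#'   \item{doublewell_low}{barrier 2 kT, minima at +/- 4 nm: lowered
#'     barrier, frequent crossings.}
#'   \item{doublewell_wide}{barrier 4 kT, minima at +/- 8 nm: high but
#'     widened barrier, slow continuous transitions.}
#'   \item{doublewell_shallow}{barrier 1 kT, minima at +/- 3 nm: barely
#'     distinct basins.}
#'   \item{singlewell_flat}{a single broad flat-bottomed well (soft quartic
#'     walls); the regime in which discrete-state analyses report
#'     fictitious intermediates.}
#' }
#'
#' @param name preset name; omit to list available names.
#' @return A `potential_spec` (or character vector of names).
#' @export
potential_preset <- function(name) {
  path <- system.file("extdata", "potential_presets.yaml",
                      package = "basinmirage", mustWork = TRUE)
  lib <- yaml::read_yaml(path)
  if (missing(name)) return(names(lib))
  if (!name %in% names(lib))
    stop("unknown preset '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  potential_from_list(lib[[name]])
}

potential_from_list <- function(lst) {
  switch(lst$form,
    harmonic = harmonic_potential(lst$stiffness),
    double_well = double_well_potential(lst$barrier_height,
                                        lst$half_separation),
    flat_well = flat_well_potential(lst$wall_height, lst$halfwidth,
                                    lst$wall_exponent),
    tabulated = tabulated_potential(unlist(lst$grid_x), unlist(lst$grid_U)),
    stop("unknown potential form in config: ", lst$form))
}

potential_to_list <- function(spec) {
  spec[setdiff(names(spec), ".spline")]
}

#' Read and write potential configurations
#'
#' Potentials serialize to a YAML file holding one block per named
#' potential (the same format as the shipped preset library).
#'
#' @param specs named list of `potential_spec` objects.
#' @param path file path.
#' @return `read_potential_config` returns a named list of
#'   `potential_spec`s; `write_potential_config` returns `path` invisibly.
#' @export
write_potential_config <- function(specs, path) {
  stopifnot(is.list(specs), !is.null(names(specs)))
  yaml::write_yaml(lapply(specs, potential_to_list), path)
  invisible(path)
}

#' @rdname write_potential_config
#' @export
read_potential_config <- function(path) {
  lapply(yaml::read_yaml(path), potential_from_list)
}
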