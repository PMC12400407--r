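#' Thermal expansion coefficient from a density series
#'
#' alpha = -(d ln rho / dT) at constant pressure, estimated as minus the
#' slope of a (weighted) linear fit of ln(rho) against T. Exact for
#' exponential density curves rho(T) = rho0 exp(-alpha T).
#'
#' @param series Data frame with columns `temperature` (K) and `density`
#'   (any consistent unit), optionally `sd` (density standard deviations used
#'   as weights).
#' @return List with `alpha` (1/K), `se`, `fit` (the `lm` object).
#' @examples
#' thermal_expansion(gen_density_series(7e-4))$alpha # 7e-4
#' @export
thermal_expansion <- function(series) {
  if (nrow(series) < 2) stop("at least 2 temperatures required")
  if (any(series$density <= 0)) stop("densities must be positive")
  w <- if (!is.null(series$sd) && all(series$sd > 0)) {
    (series$density / series$sd)^2 # delta ln rho = sd/rho
  } else NULL
  fit <- stats::lm(log(density) ~ temperature, data = series, weights = w)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(alpha = -stats::coef(fit)[["temperature"]],
       se = sm["temperature", "Std. Error"],
       fit = fit)
}

#' Fit the cosine velocity-profile amplitude
#'
#' Projects particle x-velocities onto the cos(k z) mode with k = 2 pi / Lz
#' (mass-weighted least squares), per frame, and averages over
#' post-transient frames. This is the measured response of the periodic
#' perturbation method; a uniform velocity offset is orthogonal to the mode
#' and contributes nothing.
#'
#' @param traj A `trajectory` with velocities (e.g. a cosine-flow run of the
#'   toy simulator, or [gen_cosine_flow()] output).
#' @param axis Flow axis (default 1 = x); the modulation is along z.
#' @param discard Fraction of initial frames discarded as transient
#'   (default 1/3).
#' @param mass Per-particle masses; default: uniform (amplitude is then
#'   mass-independent).
#' @return List with `V` (amplitude, nm/ps), `se` (SEM over frames),
#'   `per_frame` (vector) and `k` (1/nm).
#' @export
fit_velocity_profile <- function(traj, axis = 1, discard = 1 / 3, mass = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$velocities)) stop("trajectory has no velocities")
  nf <- n_frames(traj)
  keep <- which(seq_len(nf) > floor(discard * nf))
  if (length(keep) == 0) stop("all frames discarded")
  kz <- 2 * pi / traj$box$L[3]
  n <- dim(traj$coords)[1]
  m <- mass %||% rep(1, n)
  amps <- vapply(keep, function(f) {
    z <- traj$coords[, 3, f]
    vx <- traj$velocities[, axis, f]
    cz <- cos(kz * z)
    # weighted LS on [1, cos(kz)]: the offset term makes the amplitude
    # exactly invariant under a uniform (Galilean) velocity shift
    s0 <- sum(m); s1 <- sum(m * cz); s2 <- sum(m * cz^2)
    b0 <- sum(m * vx); b1 <- sum(m * vx * cz)
    (s0 * b1 - s1 * b0) / (s0 * s2 - s1^2)
  }, numeric(1))
  list(V = mean(amps),
       se = if (length(amps) > 1) stats::sd(amps) / sqrt(length(amps)) else NA_real_,
       per_frame = amps, k = kz)
}

# amu/(nm ps) -> mPa s
VISC_UNIT <- 1.66053906660e-3

#' Shear viscosity via the periodic perturbation method
#'
#' For a steady cosine acceleration field a_x(z) = A cos(k z) acting on a
#' fluid of mass density rho, the Navier-Stokes steady state is a cosine
#' velocity profile of amplitude V = rho A / (eta k^2), so each run yields
#' eta = rho A / (V k^2) with k = 2 pi / Lz. Runs over several acceleration
#' rates (and replicas) are averaged and the straight-line quality of V
#' against A is reported as a linearity diagnostic.
#'
#' @param runs Data frame with columns `acceleration` (nm/ps^2) and `V`
#'   (fitted amplitude, nm/ps); one row per run.
#' @param density Mass density. Interpreted according to `density_unit`.
#' @param Lz Box length along the modulation axis (nm).
#' @param density_unit `"kg/m3"` (default) or `"amu/nm3"`.
#' @return Object of class `viscosity_result`: `eta` (mPa s), `sem`,
#'   `per_run` (data frame with per-run eta), `linearity_r2`, `n_runs`.
#' @export
viscosity_periodic_perturbation <- function(runs, density, Lz,
                                            density_unit = c("kg/m3", "amu/nm3")) {
  density_unit <- match.arg(density_unit)
  if (!all(c("acceleration", "V") %in% names(runs))) {
    stop("runs must have columns 'acceleration' and 'V'")
  }
  bad <- runs$V <= 0 | !is.finite(runs$V)
  if (any(bad)) {
    warning(sum(bad), " run(s) with non-positive fitted amplitude excluded")
    runs <- runs[!bad, , drop = FALSE]
  }
  if (nrow(runs) == 0) stop("no usable runs: all fitted amplitudes non-positive")
  rho_amu <- if (density_unit == "kg/m3") density / 1.66053906660 else density
  k <- 2 * pi / Lz
  eta_internal <- rho_amu * runs$acceleration / (runs$V * k^2) # amu/(nm ps)
  eta <- eta_internal * VISC_UNIT # mPa s
  r2 <- if (length(unique(runs$acceleration)) > 1) {
    suppressWarnings(summary(stats::lm(V ~ acceleration, data = runs)))$r.squared
  } else NA_real_
  sem <- if (length(eta) > 1) stats::sd(eta) / sqrt(length(eta)) else NA_real_
  if (length(eta) == 1) {
    message("single run: standard error of the mean undefined")
  }
  structure(list(
    eta = mean(eta), sem = sem,
    per_run = data.frame(acceleration = runs$acceleration, V = runs$V, eta = eta),
    linearity_r2 = r2, n_runs = length(eta)
  ), class = "viscosity_result")
}

#' @export
print.viscosity_result <- function(x, ...) {
  cat(sprintf("<viscosity_result> eta = %.4g mPa s (SEM %.2g, %d runs, linearity R^2 = %.4f)\n",
              x$eta, x$sem, x$n_runs, x$linearity_r2))
  invisible(x)
}

#' End-to-end viscosity estimate from cosine-flow trajectories
#'
#' Convenience wrapper: fits the velocity-profile amplitude of each
#' trajectory ([fit_velocity_profile()]) and combines them with
#' [viscosity_periodic_perturbation()], deriving the mass density from the
#' trajectory contents.
#'
#' @param trajs List of `trajectory` objects from cosine-flow runs; each
#'   must record its acceleration amplitude in `metadata$cosine_accel`.
#' @param ff The [toy_forcefield()] used (for particle masses).
#' @param discard Transient fraction discarded per run.
#' @return A `viscosity_result`.
#' @export
viscosity_from_trajectories <- function(trajs, ff, discard = 1 / 3) {
  runs <- do.call(rbind, lapply(trajs, function(tr) {
    m <- unname(ff$mass[match(tr$species, ff$species)])
    fit <- fit_velocity_profile(tr, discard = discard, mass = m)
    data.frame(acceleration = tr$metadata$cosine_accel, V = fit$V,
               mass_total = sum(m), vol = prod(tr$box$L))
  }))
  rho_amu <- mean(runs$mass_total / runs$vol)
  viscosity_periodic_perturbation(runs[, c("acceleration", "V")],
                                  density = rho_amu, Lz = trajs[[1]]$box$L[3],
                                  density_unit = "amu/nm3")
}
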