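#' Toy soft-sphere force field
#'
#' Pair interaction used by the Langevin mixture simulator: a harmonic
#' repulsive core of radius `sigma` plus a finite attractive well of depth
#' `eps_ii` reaching zero (with zero slope) at `cutoff`. Unlike-species well
#' depths follow a geometric mean scaled by the cross-interaction factor
#' `kappa`: eps_ij = kappa * sqrt(eps_ii * eps_jj). Lowering `kappa` below 1
#' penalises unlike contacts and drives demixing, the toy analogue of
#' self- vs cross-affinity in coarse-grained force fields.
#'
#' @param species Character vector of species names.
#' @param eps Self well depths (kJ/mol), recycled over species.
#' @param kappa Cross-interaction scaling for unlike pairs (dimensionless).
#' @param sigma Core radius (nm).
#' @param cutoff Interaction cutoff (nm).
#' @param a_rep Core stiffness (kJ/mol at full overlap).
#' @param mass Particle masses (amu), recycled.
#' @return An object of class `toy_forcefield` holding the symmetric
#'   well-depth matrix.
#' @export
toy_forcefield <- function(species, eps = 3, kappa = 1, sigma = 0.47,
                           cutoff = 1.1, a_rep = 200, mass = 72) {
  ns <- length(species)
  eps <- rep_len(eps, ns)
  mass <- rep_len(mass, ns)
  if (cutoff <= sigma) stop("cutoff must exceed the core radius sigma")
  emat <- sqrt(outer(eps, eps))
  off <- row(emat) != col(emat)
  emat[off] <- kappa * emat[off]
  dimnames(emat) <- list(species, species)
  structure(list(species = species, eps = emat, sigma = sigma,
                 cutoff = cutoff, a_rep = a_rep,
                 mass = stats::setNames(mass, species), kappa = kappa),
            class = "toy_forcefield")
}

# Largest-remainder apportionment of n particles to the mole fractions.
species_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Random mixed starting configuration
#'
#' Places particles uniformly in a periodic box at the requested composition
#' (largest-remainder rounding of mole fractions to counts), enforcing a
#' minimum insertion distance by rejection.
#'
#' @param comp A [make_composition()] object, or a named numeric vector of
#'   mole fractions.
#' @param n_particles Total particle count.
#' @param density Number density (particles/nm^3); sets the cubic box edge.
#' @param box Optional explicit [box_geometry()] (overrides `density`).
#' @param min_dist Minimum insertion distance (nm); 0 disables the check.
#' @param seed RNG seed.
#' @param max_tries Insertion attempts per particle before giving up.
#' @return A `frame`.
#' @export
build_random_config <- function(comp, n_particles, density = 4.5, box = NULL,
                                min_dist = 0.3, seed = 1, max_tries = 2000) {
  fr <- if (inherits(comp, "composition")) comp$fractions else comp
  fr <- fr[fr > 0]
  if (n_particles < 1) stop("n_particles must be at least 1")
  if (is.null(box)) {
    if (density <= 0) stop("density must be positive")
    box <- box_geometry((n_particles / density)^(1 / 3))
  }
  counts <- species_counts(fr, n_particles)
  species <- rep(names(counts), counts)
  set.seed(seed)
  coords <- matrix(NA_real_, n_particles, 3)
  md2 <- min_dist^2
  for (i in seq_len(n_particles)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3) * box$L
      if (min_dist <= 0 || i == 1) { placed <- TRUE } else {
        d <- minimum_image(sweep(coords[seq_len(i - 1), , drop = FALSE], 2, p), box)
        placed <- all(rowSums(d^2) >= md2)
      }
      if (placed) { coords[i, ] <- p; break }
    }
    if (!placed) {
      stop("could not place particle ", i, " at min_dist = ", min_dist,
           "; density too high")
    }
  }
  make_frame(coords, species, box)
}

#' Slab-demixed starting configuration
#'
#' Builds a demixed fixture: designated species are confined to a contiguous
#' slab along one axis, all others fill the remaining volume. Optionally a
#' fraction of the slab species is deliberately misplaced outside its slab,
#' giving a configuration with a known pollutant fraction.
#'
#' @param comp Composition (as in [build_random_config()]).
#' @param n_particles Total particle count.
#' @param box A [box_geometry()].
#' @param slab_species Character vector of species confined to the slab.
#' @param slab_fraction Fraction of the axis length occupied by the slab.
#' @param interface_axis Axis normal to the interfaces: 1, 2 or 3 (z).
#' @param misplaced_fraction Fraction of slab-species particles placed
#'   uniformly outside the slab (ground-truth pollutants).
#' @param min_dist Minimum insertion distance (nm).
#' @param seed RNG seed.
#' @return A `frame` with attributes `slab_bounds` (lo, hi along the axis)
#'   and `slab_species`.
#' @export
build_slab_config <- function(comp, n_particles, box, slab_species,
                              slab_fraction = 0.5, interface_axis = 3,
                              misplaced_fraction = 0, min_dist = 0.25,
                              seed = 1, max_tries = 2000) {
  fr <- if (inherits(comp, "composition")) comp$fractions else comp
  fr <- fr[fr > 0]
  if (length(fr) < 2) stop("a slab configuration needs at least two species")
  counts <- species_counts(fr, n_particles)
  ax <- interface_axis
  lo <- 0
  hi <- slab_fraction * box$L[ax]
  n_in_raw <- sum(counts[slab_species])
  n_out_of_slab <- round(misplaced_fraction * n_in_raw)
  vol <- prod(box$L)
  slab_vol <- vol * slab_fraction
  # crude capacity check against the insertion-sphere volume
  if (min_dist > 0 &&
      (n_in_raw - n_out_of_slab) * (4 / 3) * pi * min_dist^3 > 2 * slab_vol) {
    stop("slab volume insufficient for requested counts at min_dist = ", min_dist)
  }
  set.seed(seed)
  species <- rep(names(counts), counts)
  in_slab_target <- species %in% slab_species
  if (n_out_of_slab > 0) {
    mis <- sample(which(in_slab_target), n_out_of_slab)
    in_slab_target[mis] <- FALSE
    attr_mis <- mis
  } else attr_mis <- integer(0)
  n <- length(species)
  coords <- matrix(NA_real_, n, 3)
  md2 <- min_dist^2
  slab_sp <- species %in% slab_species
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3) * box$L
      if (slab_fraction < 1) {
        if (in_slab_target[i]) {
          p[ax] <- stats::runif(1, lo, hi)
        } else if (slab_sp[i]) {
          p[ax] <- stats::runif(1, hi, box$L[ax]) # misplaced pollutant
        } else {
          p[ax] <- stats::runif(1, hi, box$L[ax])
        }
      }
      if (min_dist <= 0 || i == 1) { placed <- TRUE } else {
        d <- minimum_image(sweep(coords[seq_len(i - 1), , drop = FALSE], 2, p), box)
        placed <- all(rowSums(d^2) >= md2)
      }
      if (placed) { coords[i, ] <- p; break }
    }
    if (!placed) stop("slab placement failed for particle ", i)
  }
  out <- make_frame(coords, species, box)
  attr(out, "slab_bounds") <- c(lo, hi)
  attr(out, "slab_species") <- slab_species
  attr(out, "misplaced") <- attr_mis
  out
}

#' Langevin dynamics of a toy soft-sphere mixture
#'
#' Integrates the mixture with the BAOAB splitting of Langevin dynamics
#' (velocity Verlet when the thermostat is off). An optional external cosine
#' acceleration field a_x(z) = A cos(2 pi z / Lz) drives the periodic
#' perturbation used for viscometry; in that mode the thermostat acts on
#' peculiar velocities so the friction does not damp the flow mode. An
#' optional isotropic weak-coupling barostat is available. Exact unwrapped
#' coordinates are stored alongside wrapped ones.
#'
#' A conservative stability bound on the time step is
#' dt < 0.1 * sigma * sqrt(m / (2 a_rep)); the default force field
#' (sigma 0.47 nm, a_rep 200 kJ/mol, m 72 amu) admits dt of about 0.02 ps.
#'
#' @param start A `frame` (e.g. from [build_random_config()]).
#' @param ff A [toy_forcefield()] covering every species in `start`.
#' @param temperature Thermostat temperature (K).
#' @param dt Time step (ps).
#' @param n_steps Number of steps.
#' @param sample_every Store every k-th step (frame 0 is always stored).
#' @param gamma Langevin friction (1/ps).
#' @param thermostat,barostat Logical switches.
#' @param pressure0 Barostat set point (bar).
#' @param tau_p Barostat time constant (ps).
#' @param compressibility Barostat compressibility (1/bar).
#' @param cosine_accel Amplitude A of the cosine acceleration (nm/ps^2), 0
#'   for none.
#' @param seed RNG seed (integer).
#' @return A `trajectory` with `metadata$energy` (data frame of time,
#'   kinetic, potential, instantaneous temperature, volume and cosine-mode
#'   velocity amplitude per stored frame).
#' @export
run_langevin <- function(start, ff, temperature = 300, dt = 0.02,
                         n_steps = 1000, sample_every = 10, gamma = 2,
                         thermostat = TRUE, barostat = FALSE,
                         pressure0 = 1, tau_p = 5, compressibility = 3e-4,
                         cosine_accel = 0, seed = 1) {
  stopifnot(inherits(start, "frame"), inherits(ff, "toy_forcefield"))
  if (ff$cutoff > min(start$box$L) / 2) {
    stop("cutoff exceeds half the shortest box edge")
  }
  sp_idx <- match(start$species, ff$species)
  if (anyNA(sp_idx)) stop("force field does not cover all species present")
  n <- nrow(start$coords)
  v0 <- start$velocities
  if (is.null(v0)) {
    # Maxwell-Boltzmann draw, deterministic in `seed`
    set.seed(seed)
    sd_v <- sqrt(kB * temperature / ff$mass[sp_idx])
    v0 <- matrix(stats::rnorm(3 * n, sd = rep(sd_v, 3)), n, 3)
  }
  res <- run_langevin_cpp(
    start$coords, v0, sp_idx - 1L, unname(ff$mass), ff$eps, ff$sigma,
    ff$a_rep, ff$cutoff, start$box$L, dt, as.integer(n_steps),
    as.integer(sample_every), temperature, gamma, thermostat, barostat,
    pressure0, tau_p, compressibility, cosine_accel, as.double(seed)
  )
  ndof <- 3 * n
  energy <- data.frame(
    time = res$times, kinetic = res$kinetic, potential = res$potential,
    temperature = 2 * res$kinetic / (ndof * kB), volume = res$volume,
    cosine_amp = res$cosine_amp
  )
  final_L <- res$box[, ncol(res$box)]
  box <- box_geometry(final_L[1], final_L[2], final_L[3])
  make_trajectory(
    res$coords, res$times, start$species, box,
    unwrapped = res$unwrapped, velocities = res$velocities,
    mol_id = start$mol_id,
    metadata = list(temperature = temperature, seed = seed, dt = dt,
                    gamma = gamma, cosine_accel = cosine_accel,
                    energy = energy, box_history = res$box)
  )
}

#' Brownian walker ensembles with known diffusivities
#'
#' Direct stochastic generator for diffusion fixtures: per-axis Gaussian
#' displacements with variance 2 D dt give walkers whose true diffusion
#' coefficient is exactly `D_true`. In compartment mode each walker carries a
#' latent compartment label with a per-compartment D; labels swap between the
#' two compartments as a Poisson process of the given exchange rate
#' (rate 0 = impermeable compartments).
#'
#' @param n_walkers Walkers per species.
#' @param D_true Named vector of diffusion coefficients (nm^2/ps), one entry
#'   per species.
#' @param dt Frame spacing (ps).
#' @param n_steps Number of steps (frames stored at every step).
#' @param box A [box_geometry()] used for wrapping (default 20 nm cube).
#' @param seed RNG seed.
#' @param compartments Optional list with `D` (numeric vector of
#'   per-compartment diffusivities), `fractions` (initial occupancy) and
#'   `rate` (exchange rate, 1/ps). When given, per-species `D_true` is
#'   ignored and all walkers follow the compartment process.
#' @return A `trajectory` with exact unwrapped coordinates; in compartment
#'   mode `metadata$compartment` is an N x (n_steps+1) matrix of labels.
#' @export
gen_brownian_ensemble <- function(n_walkers, D_true = c(A = 0.05), dt = 1,
                                  n_steps = 100, box = box_geometry(20),
                                  seed = 1, compartments = NULL) {
  if (any(D_true < 0)) stop("diffusion coefficients must be non-negative")
  set.seed(seed)
  if (is.null(compartments)) {
    ns <- length(D_true)
    n <- n_walkers * ns
    species <- rep(names(D_true), each = n_walkers)
    sds <- rep(sqrt(2 * D_true * dt), each = n_walkers)
    un <- array(0, c(n, 3, n_steps + 1))
    un[, , 1] <- matrix(stats::runif(3 * n), n, 3) %*% diag(box$L)
    for (f in seq_len(n_steps)) {
      un[, , f + 1] <- un[, , f] + matrix(stats::rnorm(3 * n, sd = rep(sds, 3)), n, 3)
    }
    comp_lab <- NULL
  } else {
    if (any(compartments$D < 0)) stop("diffusion coefficients must be non-negative")
    n <- n_walkers
    species <- rep(names(D_true)[1], n)
    ncomp <- length(compartments$D)
    fracs <- compartments$fractions %||% rep(1 / ncomp, ncomp)
    rate <- compartments$rate %||% 0
    lab <- sample.int(ncomp, n, replace = TRUE, prob = fracs)
    comp_lab <- matrix(0L, n, n_steps + 1)
    comp_lab[, 1] <- lab
    un <- array(0, c(n, 3, n_steps + 1))
    un[, , 1] <- matrix(stats::runif(3 * n), n, 3) %*% diag(box$L)
    p_swap <- 1 - exp(-rate * dt)
    for (f in seq_len(n_steps)) {
      sds <- sqrt(2 * compartments$D[lab] * dt)
      un[, , f + 1] <- un[, , f] + matrix(stats::rnorm(3 * n, sd = rep(sds, 3)), n, 3)
      if (p_swap > 0 && ncomp == 2) {
        swap <- stats::runif(n) < p_swap
        lab[swap] <- 3L - lab[swap]
      }
      comp_lab[, f + 1] <- lab
    }
  }
  wrapped <- un
  for (k in 1:3) {
    wrapped[, k, ] <- wrapped[, k, ] - box$L[k] * floor(wrapped[, k, ] / box$L[k])
  }
  make_trajectory(wrapped, seq(0, by = dt, length.out = n_steps + 1), species,
                  box, unwrapped = un,
                  metadata = c(list(seed = seed, D_true = D_true),
                               if (!is.null(comp_lab)) list(
                                 compartment = comp_lab,
                                 compartments = compartments)))
}

#' Density-vs-temperature series with known expansion coefficient
#'
#' Generates rho(T) = rho0 * exp(-alpha_true * T), optionally with relative
#' Gaussian noise, as input for [thermal_expansion()].
#'
#' @param alpha_true Thermal expansion coefficient (1/K).
#' @param rho0 Density prefactor (kg/m^3 at T = 0 on the extrapolated curve).
#' @param temperatures Temperature grid (K).
#' @param noise_sd Relative noise level (e.g. 0.001 = 0.1%).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return A data frame with columns `temperature`, `density`, `sd`.
#' @export
gen_density_series <- function(alpha_true = 7e-4, rho0 = 1100,
                               temperatures = seq(270, 330, by = 10),
                               noise_sd = 0, seed = 1) {
  if (length(temperatures) == 0) stop("temperatures must be non-empty")
  rho <- rho0 * exp(-alpha_true * temperatures)
  if (noise_sd > 0) {
    set.seed(seed)
    rho <- rho * (1 + stats::rnorm(length(rho), sd = noise_sd))
  }
  data.frame(temperature = temperatures, density = rho,
             sd = noise_sd * rho0 * exp(-alpha_true * temperatures))
}

#' Steady cosine shear-flow frames with known profile amplitude
#'
#' Generates velocity-bearing frames whose x-velocity field is
#' u(z) = V cos(2 pi z / Lz) plus Gaussian thermal noise — the steady state
#' probed by the periodic perturbation viscometry protocol.
#'
#' @param n_particles Particles per frame.
#' @param box A [box_geometry()]; conventionally 1:1:3 elongated.
#' @param V True profile amplitude (nm/ps).
#' @param noise_sd Thermal velocity noise per component (nm/ps).
#' @param n_frames Number of frames.
#' @param mass Particle mass (amu).
#' @param seed RNG seed.
#' @return A `trajectory` with velocities and uniform particle positions.
#' @export
gen_cosine_flow <- function(n_particles, box = box_geometry(5, 5, 15),
                            V = 0.01, noise_sd = 0.001, n_frames = 5,
                            mass = 72, seed = 1) {
  set.seed(seed)
  n <- n_particles
  kz <- 2 * pi / box$L[3]
  coords <- array(0, c(n, 3, n_frames))
  vel <- array(0, c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    p <- matrix(stats::runif(3 * n), n, 3) %*% diag(box$L)
    coords[, , f] <- p
    vel[, , f] <- matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    vel[, 1, f] <- vel[, 1, f] + V * cos(kz * p[, 3])
  }
  make_trajectory(coords, seq(0, by = 1, length.out = n_frames),
                  rep("A", n), box, velocities = vel,
                  metadata = list(V_true = V, mass = mass, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
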