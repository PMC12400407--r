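#' Partial density profiles along a box axis
#'
#' Time-averaged per-species number-density histograms along one axis, with
#' optional per-frame re-centring to stop slab drift from washing the
#' profile out. Re-centring (`align`) shifts each frame so that the circular
#' mean of a reference species' coordinates along the axis sits at the box
#' centre — the standard drift correction for periodic slabs.
#'
#' @param traj A `trajectory` (a single `frame` is also accepted).
#' @param axis Profile axis (default 3 = z).
#' @param bin_width Bin width (nm); default 0.1.
#' @param align `FALSE` (default) or the name of the reference species to
#'   centre on each frame.
#' @return Object of class `density_profile`: data frame with `center`
#'   (bin centre, nm), one raw number-density column per species
#'   (molecules/nm^3) and matching `<species>_norm` columns normalised to
#'   each species' peak; attribute `counts` holds the raw summed counts.
#' @export
partial_density_profile <- function(traj, axis = 3, bin_width = 0.1,
                                    align = FALSE) {
  if (inherits(traj, "frame")) {
    traj <- make_trajectory(array(traj$coords, c(nrow(traj$coords), 3, 1)),
                            0, traj$species, traj$box, mol_id = traj$mol_id)
  }
  L <- traj$box$L[axis]
  if (bin_width <= 0) stop("bin_width must be positive")
  if (bin_width > L) stop("bin width exceeds the box edge")
  nb <- max(1L, round(L / bin_width))
  edges <- seq(0, L, length.out = nb + 1)
  width <- L / nb
  sp_levels <- sort(unique(traj$species))
  counts <- matrix(0, nb, length(sp_levels), dimnames = list(NULL, sp_levels))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    cen <- molecule_centers(fr)
    x <- cen$centers[, axis]
    if (!isFALSE(align)) {
      ref <- x[cen$species %in% align]
      if (length(ref) == 0) stop("no molecules of align species '", align, "'")
      ang <- ref / L * 2 * pi
      shift <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * L
      x <- (x - shift + L / 2) %% L
    }
    bins <- pmin(nb, floor(x / width) + 1L) # half-open [lo, hi)
    for (s in seq_along(sp_levels)) {
      sel <- bins[cen$species == sp_levels[s]]
      if (length(sel) > 0) counts[, s] <- counts[, s] + tabulate(sel, nb)
    }
  }
  area <- prod(traj$box$L[-axis])
  dens <- counts / (nf * width * area)
  out <- data.frame(center = (edges[-1] + edges[-(nb + 1)]) / 2)
  for (s in sp_levels) out[[s]] <- dens[, s]
  for (s in sp_levels) {
    pk <- max(dens[, s])
    out[[paste0(s, "_norm")]] <- if (pk > 0) dens[, s] / pk else dens[, s]
  }
  attr(out, "counts") <- counts
  attr(out, "bin_width") <- width
  attr(out, "axis") <- axis
  attr(out, "n_frames") <- nf
  class(out) <- c("density_profile", class(out))
  out
}

#' Radial distribution function between species
#'
#' Standard pair-correlation g(r): minimum-image pair distances between
#' molecule centres (beads optional) histogrammed and normalised by the
#' ideal-gas shell count, averaged over frames. For a homogeneous fluid
#' g(r) tends to 1 at large r.
#'
#' @param traj A `trajectory` or `frame`.
#' @param pair Character vector of length 2: the species pair (identical
#'   entries give the self-RDF).
#' @param r_max Histogram range (nm); must not exceed half the shortest box
#'   edge (default: exactly that).
#' @param dr Bin width (nm); default 0.02.
#' @param use_beads If TRUE, use beads rather than molecule centres.
#' @return Object of class `rdf_series`: data frame with `r` (bin centre)
#'   and `g`; attribute `counts` has the raw pair counts.
#' @export
compute_rdf <- function(traj, pair, r_max = NULL, dr = 0.02,
                        use_beads = FALSE) {
  if (inherits(traj, "frame")) {
    traj <- make_trajectory(array(traj$coords, c(nrow(traj$coords), 3, 1)),
                            0, traj$species, traj$box, mol_id = traj$mol_id)
  }
  half <- min(traj$box$L) / 2
  r_max <- r_max %||% half
  if (r_max > half + 1e-9) stop("r_max exceeds half the shortest box edge")
  nb <- floor(r_max / dr + 1e-9) # complete bins only
  if (nb < 1) stop("r_max smaller than one bin")
  r_max <- nb * dr
  hist_total <- numeric(nb)
  nf <- n_frames(traj)
  same <- pair[1] == pair[2]
  n_a <- n_b <- 0
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    if (use_beads) {
      pts <- fr$coords; sp <- fr$species
    } else {
      cen <- molecule_centers(fr)
      pts <- cen$centers; sp <- cen$species
    }
    ia <- which(sp == pair[1]) - 1L
    ib <- which(sp == pair[2]) - 1L
    n_a <- length(ia); n_b <- length(ib)
    if (n_a == 0 || n_b == 0) stop("no particles of species ",
                                   pair[if (n_a == 0) 1 else 2])
    hist_total <- hist_total + pair_dist_hist_cpp(pts, ia, ib, same,
                                                  traj$box$L, r_max, dr)
  }
  vol <- prod(traj$box$L)
  r_lo <- (seq_len(nb) - 1) * dr
  r_hi <- seq_len(nb) * dr
  shell <- 4 / 3 * pi * (r_hi^3 - r_lo^3)
  n_pairs <- if (same) n_a * (n_a - 1) / 2 else n_a * n_b
  ideal <- nf * n_pairs * shell / vol
  out <- data.frame(r = (r_lo + r_hi) / 2, g = hist_total / ideal)
  attr(out, "counts") <- hist_total
  attr(out, "pair") <- pair
  attr(out, "n_frames") <- nf
  class(out) <- c("rdf_series", class(out))
  out
}

#' Phase region from a density profile
#'
#' Defines a phase region as the bins where a species' density exceeds a
#' fraction (default half) of its plateau (peak) value — the default
#' operational boundary for "the IMID-water phase" in partition analyses.
#'
#' @param profile A `density_profile`.
#' @param species Species defining the region.
#' @param frac Fraction of the peak density (default 0.5).
#' @return Logical vector over bins (TRUE = inside the region), with the
#'   bin edges as attributes.
#' @export
phase_region_from_profile <- function(profile, species, frac = 0.5) {
  dens <- profile[[species]]
  if (is.null(dens)) stop("no profile column for species ", species)
  pk <- max(dens)
  if (pk <= 0) stop("no density contrast: phase region undefined")
  inside <- dens >= frac * pk
  if (all(inside) || !any(inside)) {
    stop("no density contrast: phase region undefined for species ", species)
  }
  attr(inside, "centers") <- profile$center
  attr(inside, "bin_width") <- attr(profile, "bin_width")
  inside
}

#' Pollutant fraction: molecules outside their majority phase
#'
#' Quantifies phase-partition purity: the percentage of a species' molecules
#' found outside its own phase, time-averaged with a standard error across
#' frames. The phase can be supplied as (a) an axis interval region
#' (`region`, e.g. from [phase_region_from_profile()] or explicit bounds),
#' or (b) per-molecule labels from [classify_local_phase()] together with
#' the phase that counts as "home" for the species.
#'
#' @param traj A `trajectory` or `frame`.
#' @param species The species whose pollutant fraction is measured.
#' @param region Either a logical bin vector from
#'   [phase_region_from_profile()], or numeric `c(lo, hi)` bounds along
#'   `axis` (nm, lo < hi within the box).
#' @param labels A `phase_assignment` (or function frame -> assignment);
#'   used when `region` is NULL.
#' @param home_phase Name of the species' home phase when using labels;
#'   default: the phase containing most of the species' molecules.
#' @param axis Axis for interval regions (default 3).
#' @return Object of class `phase_partition`: list with `fraction_outside`
#'   (percent), `se`, `per_frame`, `inside`, `outside`, `total` (counts of
#'   the last frame) and the convention used.
#' @export
pollutant_fraction <- function(traj, species, region = NULL, labels = NULL,
                               home_phase = NULL, axis = 3) {
  if (inherits(traj, "frame")) {
    traj <- make_trajectory(array(traj$coords, c(nrow(traj$coords), 3, 1)),
                            0, traj$species, traj$box, mol_id = traj$mol_id)
  }
  nf <- n_frames(traj)
  per_frame <- numeric(nf)
  inside_n <- outside_n <- total_n <- NA_integer_
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    cen <- molecule_centers(fr)
    sel <- cen$species == species
    if (!any(sel)) stop("no molecules of species ", species)
    if (!is.null(region)) {
      x <- cen$centers[sel, axis]
      if (is.logical(region)) {
        centers <- attr(region, "centers")
        w <- attr(region, "bin_width")
        bin <- pmin(length(region), floor(x / w) + 1L)
        inside <- region[bin]
      } else {
        inside <- x >= region[1] & x < region[2]
      }
    } else {
      lab <- if (is.function(labels)) labels(fr) else labels
      if (is.null(lab)) stop("either region or labels must be supplied")
      ml <- lab$label[match(cen$mol_id[sel], lab$mol_id)]
      hp <- home_phase %||% names(sort(table(ml), decreasing = TRUE))[1]
      inside <- ml == hp
    }
    per_frame[f] <- 100 * sum(!inside) / sum(sel)
    inside_n <- sum(inside); outside_n <- sum(!inside); total_n <- sum(sel)
  }
  structure(list(
    fraction_outside = mean(per_frame),
    se = if (nf > 1) stats::sd(per_frame) / sqrt(nf) else NA_real_,
    per_frame = per_frame,
    inside = inside_n, outside = outside_n, total = total_n,
    species = species,
    definition = if (!is.null(region)) "profile/interval region" else "local-composition labels"
  ), class = "phase_partition")
}

#' @export
print.phase_partition <- function(x, ...) {
  cat(sprintf("<phase_partition> %s: %.1f%% outside its phase (SE %.2g, %d/%d molecules outside, %s)\n",
              x$species, x$fraction_outside, x$se, x$outside, x$total,
              x$definition))
  invisible(x)
}
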