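#' Periodic box geometry
#'
#' @param Lx,Ly,Lz Edge lengths (nm).
#' @param periodic Logical vector of length 3.
#' @return An object of class `box_geometry` with edge lengths `L` and the
#'   z/x elongation ratio recorded.
#' @export
box_geometry <- function(Lx, Ly = Lx, Lz = Lx, periodic = c(TRUE, TRUE, TRUE)) {
  if (any(c(Lx, Ly, Lz) <= 0)) stop("box edges must be positive")
  structure(list(L = c(Lx, Ly, Lz), periodic = periodic,
                 elongation = Lz / Lx),
            class = "box_geometry")
}

#' A single configuration frame
#'
#' @param coords N x 3 matrix of positions (nm), wrapped into the box.
#' @param species Character vector of per-particle species labels.
#' @param box A [box_geometry()].
#' @param mol_id Integer molecule id per particle (defaults to one molecule
#'   per particle).
#' @param velocities Optional N x 3 matrix (nm/ps).
#' @param time Frame time (ps).
#' @return An object of class `frame`.
#' @export
make_frame <- function(coords, species, box, mol_id = seq_len(nrow(coords)),
                       velocities = NULL, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (length(species) != n) stop("species must have one label per particle")
  if (length(mol_id) != n) stop("mol_id must have one id per particle")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(coords))) stop("velocities must match coords")
  }
  coords <- wrap_coords(coords, box)
  structure(list(coords = coords, species = as.character(species),
                 mol_id = as.integer(mol_id), box = box,
                 velocities = velocities, time = time),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> %d particles, %d molecules, %d species, box %.2f x %.2f x %.2f nm, t = %g ps\n",
              nrow(x$coords), length(unique(x$mol_id)),
              length(unique(x$species)), x$box$L[1], x$box$L[2], x$box$L[3],
              x$time))
  invisible(x)
}

#' Wrap coordinates into the primary periodic image
#'
#' @param coords N x 3 matrix.
#' @param box A `box_geometry`.
#' @return Matrix with each periodic coordinate folded into \[0, L).
#' @export
wrap_coords <- function(coords, box) {
  for (k in 1:3) {
    if (box$periodic[k]) {
      coords[, k] <- coords[, k] - box$L[k] * floor(coords[, k] / box$L[k])
    }
  }
  coords
}

#' Minimum-image displacement vectors
#'
#' @param d N x 3 matrix of raw displacements.
#' @param box A `box_geometry`.
#' @return Displacements mapped into (-L/2, L/2\] per periodic axis.
#' @export
minimum_image <- function(d, box) {
  for (k in 1:3) {
    if (box$periodic[k]) d[, k] <- d[, k] - box$L[k] * round(d[, k] / box$L[k])
  }
  d
}

#' Assemble frames into a trajectory
#'
#' A trajectory stores positions as an N x 3 x F array with uniformly spaced,
#' strictly increasing times and constant particle identity across frames.
#' Unwrapped (image-consistent) coordinates, needed for mean-squared
#' displacements, are carried alongside wrapped ones when available.
#'
#' @param coords N x 3 x F array of wrapped positions (nm).
#' @param times Frame times (ps), strictly increasing.
#' @param species Per-particle species labels.
#' @param box A `box_geometry` (or 3 x F matrix of box edges if the box
#'   fluctuates).
#' @param unwrapped Optional N x 3 x F array of unwrapped positions.
#' @param velocities Optional N x 3 x F array (nm/ps).
#' @param mol_id Integer molecule ids.
#' @param metadata Named list (composition, temperature, seed, ...).
#' @return An object of class `trajectory`.
#' @export
make_trajectory <- function(coords, times, species, box, unwrapped = NULL,
                            velocities = NULL, mol_id = seq_len(dim(coords)[1]),
                            metadata = list()) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (length(times) != dim(coords)[3]) stop("one time per frame required")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  structure(list(coords = coords, unwrapped = unwrapped,
                 velocities = velocities, times = times,
                 species = as.character(species), mol_id = as.integer(mol_id),
                 box = box, metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d particles x %d frames, t = %g..%g ps\n",
              dim(x$coords)[1], dim(x$coords)[3], min(x$times), max(x$times)))
  if (length(x$metadata) > 0) {
    cat("  metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#'
#' @param traj A `trajectory`.
#' @param i Frame index.
#' @return A `frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  vel <- if (!is.null(traj$velocities)) {
    matrix(traj$velocities[, , i], ncol = 3)
  } else NULL
  make_frame(matrix(traj$coords[, , i], ncol = 3), traj$species, traj$box,
             traj$mol_id, velocities = vel, time = traj$times[i])
}

#' Reconstruct unwrapped coordinates from wrapped frames
#'
#' Frame-to-frame displacements are mapped through the minimum-image
#' convention and accumulated, which is exact whenever no particle moves more
#' than half a box edge between stored frames. Trajectories written by the
#' built-in simulator already carry exact unwrapped coordinates; this is for
#' externally read (wrapped-only) trajectories.
#'
#' @param traj A `trajectory` without unwrapped coordinates.
#' @return The trajectory with `unwrapped` filled in.
#' @export
unwrap_trajectory <- function(traj) {
  if (!is.null(traj$unwrapped)) return(traj)
  dims <- dim(traj$coords)
  un <- array(0, dims)
  un[, , 1] <- traj$coords[, , 1]
  for (f in 2:dims[3]) {
    d <- minimum_image(traj$coords[, , f] - traj$coords[, , f - 1], traj$box)
    un[, , f] <- un[, , f - 1] + d
  }
  traj$unwrapped <- un
  traj
}

#' Molecule centres of geometry for a frame
#'
#' For multi-bead molecules the centre is computed from beads made whole
#' across periodic boundaries (minimum image relative to the first bead),
#' then wrapped back into the box.
#'
#' @param frame A `frame`.
#' @return List with `centers` (M x 3), `species` (per molecule) and `mol_id`.
#' @export
molecule_centers <- function(frame) {
  ids <- unique(frame$mol_id)
  if (length(ids) == nrow(frame$coords)) {
    ord <- order(frame$mol_id)
    return(list(centers = frame$coords[ord, , drop = FALSE],
                species = frame$species[ord], mol_id = frame$mol_id[ord]))
  }
  centers <- matrix(0, length(ids), 3)
  sp <- character(length(ids))
  for (m in seq_along(ids)) {
    sel <- which(frame$mol_id == ids[m])
    ref <- frame$coords[sel[1], , drop = FALSE]
    d <- minimum_image(frame$coords[sel, , drop = FALSE] -
                         ref[rep(1, length(sel)), , drop = FALSE], frame$box)
    centers[m, ] <- ref + colMeans(d)
    sp[m] <- frame$species[sel[1]]
  }
  list(centers = wrap_coords(centers, frame$box), species = sp, mol_id = ids)
}
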