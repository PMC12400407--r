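# Shared fixtures and independent oracles for the test suite.

# All-pairs molecular contact counting in plain R: the brute-force oracle the
# cell-list implementation is checked against.
oracle_contact_counts <- function(frame, cutoff) {
  cen_sp <- frame$species
  ids <- sort(unique(frame$mol_id))
  sp_levels <- sort(unique(frame$species))
  counts <- matrix(0L, length(sp_levels), length(sp_levels),
                   dimnames = list(sp_levels, sp_levels))
  n <- length(ids)
  for (a in seq_len(n - 1)) {
    beads_a <- frame$coords[frame$mol_id == ids[a], , drop = FALSE]
    for (b in (a + 1):n) {
      beads_b <- frame$coords[frame$mol_id == ids[b], , drop = FALSE]
      hit <- FALSE
      for (i in seq_len(nrow(beads_a))) {
        d <- minimum_image(sweep(beads_b, 2, beads_a[i, ]), frame$box)
        if (any(rowSums(d^2) < cutoff^2)) { hit <- TRUE; break }
      }
      if (hit) {
        sa <- frame$species[match(ids[a], frame$mol_id)]
        sb <- frame$species[match(ids[b], frame$mol_id)]
        counts[sa, sb] <- counts[sa, sb] + 1L
        if (sa != sb) counts[sb, sa] <- counts[sb, sa] + 1L
      }
    }
  }
  counts
}

# Brute-force neighbourhood census oracle for the local-phase classifier.
oracle_neighbor_counts <- function(centers, species, box, radius) {
  n <- nrow(centers)
  sp_levels <- sort(unique(species))
  counts <- matrix(0L, n, length(sp_levels), dimnames = list(NULL, sp_levels))
  for (i in seq_len(n)) {
    d <- minimum_image(sweep(centers, 2, centers[i, ]), box)
    near <- which(rowSums(d^2) < radius^2)
    near <- setdiff(near, i)
    for (j in near) counts[i, species[j]] <- counts[i, species[j]] + 1L
  }
  counts
}

# Replicate a frame periodically (nx x ny x nz copies) for scale-consistency
# checks.
replicate_frame <- function(frame, reps = c(2, 2, 2)) {
  shifts <- expand.grid(x = seq_len(reps[1]) - 1, y = seq_len(reps[2]) - 1,
                        z = seq_len(reps[3]) - 1)
  n <- nrow(frame$coords)
  coords <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
    sweep(frame$coords, 2, as.numeric(shifts[s, ]) * frame$box$L, `+`)
  }))
  k <- nrow(shifts)
  make_frame(coords,
             rep(frame$species, k),
             box_geometry(frame$box$L[1] * reps[1], frame$box$L[2] * reps[2],
                          frame$box$L[3] * reps[3]),
             mol_id = rep(frame$mol_id, k) + rep((seq_len(k) - 1) * max(frame$mol_id), each = n))
}

toy_binary <- function(kappa, n = 150, seed = 11, n_steps = 2000,
                       temperature = 300) {
  ff <- toy_forcefield(c("HexA", "IMID"), eps = 3, kappa = kappa)
  fr <- build_random_config(c(HexA = 0.5, IMID = 0.5), n, density = 4.5,
                            min_dist = 0.35, seed = seed)
  run_langevin(fr, ff, temperature = temperature, dt = 0.02,
               n_steps = n_steps, sample_every = 100, seed = seed)
}
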