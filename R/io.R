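#' Write a frame as a GRO configuration file
#'
#' Standard fixed-format GRO: residue number = molecule id, residue and atom
#' names = species label, coordinates in nm to three decimals, optional
#' velocities (nm/ps) to four decimals.
#'
#' @param frame A `frame`.
#' @param path Output file path.
#' @param title Header line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = "desmix configuration") {
  stopifnot(inherits(frame, "frame"))
  n <- nrow(frame$coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, sprintf("%5d", n)), con)
  nm <- substr(frame$species, 1, 5)
  has_v <- !is.null(frame$velocities)
  lines <- vapply(seq_len(n), function(i) {
    base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    frame$mol_id[i] %% 100000, nm[i], nm[i], i %% 100000,
                    frame$coords[i, 1], frame$coords[i, 2], frame$coords[i, 3])
    if (has_v) {
      base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                   frame$velocities[i, 1],
                                   frame$velocities[i, 2],
                                   frame$velocities[i, 3]))
    }
    base
  }, character(1))
  writeLines(lines, con)
  writeLines(sprintf("%10.5f%10.5f%10.5f",
                     frame$box$L[1], frame$box$L[2], frame$box$L[3]), con)
  invisible(path)
}

#' Read a GRO configuration file
#'
#' @param path File path.
#' @return A `frame` (velocities included when the file has them; molecule
#'   ids taken from the residue numbers).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom count at line 2")
  if (length(lines) < n + 3) {
    stop("truncated GRO file: expected ", n + 3, " lines, found ", length(lines))
  }
  atoms <- lines[3:(n + 2)]
  parse_field <- function(x, lo, hi) trimws(substr(x, lo, hi))
  mol_id <- as.integer(parse_field(atoms, 1, 5))
  species <- parse_field(atoms, 6, 10)
  coords <- matrix(NA_real_, n, 3)
  vel <- matrix(NA_real_, n, 3)
  for (k in 1:3) {
    coords[, k] <- suppressWarnings(as.numeric(parse_field(atoms, 21 + 8 * (k - 1), 28 + 8 * (k - 1))))
    vel[, k] <- suppressWarnings(as.numeric(parse_field(atoms, 45 + 8 * (k - 1), 52 + 8 * (k - 1))))
  }
  bad <- which(is.na(coords[, 1]) | is.na(coords[, 2]) | is.na(coords[, 3]))
  if (length(bad) > 0) stop("malformed GRO atom line ", bad[1] + 2)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3])) stop("malformed GRO box line ", n + 3)
  has_v <- !anyNA(vel)
  make_frame(coords, species, box_geometry(boxv[1], boxv[2], boxv[3]),
             mol_id = mol_id, velocities = if (has_v) vel else NULL)
}

fmt_num <- function(x) formatC(x, format = "f", digits = 6)

#' Write a trajectory in extended-XYZ format
#'
#' One block per frame: atom count, a comment line carrying
#' `Lattice="..."`, a `Properties=` descriptor and `Time=`, then one line
#' per particle with species, position (nm) and, when present, velocity
#' (nm/ps) and molecule id.
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n <- dim(traj$coords)[1]
  has_v <- !is.null(traj$velocities)
  props <- paste0("species:S:1:pos:R:3", if (has_v) ":vel:R:3" else "", ":mol:I:1")
  con <- file(path, "w")
  on.exit(close(con))
  L <- traj$box$L
  lattice <- sprintf("Lattice=\"%s 0 0 0 %s 0 0 0 %s\"",
                     fmt_num(L[1]), fmt_num(L[2]), fmt_num(L[3]))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("%d", n), con)
    writeLines(paste0(lattice, " Properties=", props,
                      sprintf(" Time=%s", fmt_num(traj$times[f]))), con)
    rows <- paste(traj$species,
                  fmt_num(traj$coords[, 1, f]), fmt_num(traj$coords[, 2, f]),
                  fmt_num(traj$coords[, 3, f]))
    if (has_v) {
      rows <- paste(rows,
                    fmt_num(traj$velocities[, 1, f]),
                    fmt_num(traj$velocities[, 2, f]),
                    fmt_num(traj$velocities[, 3, f]))
    }
    rows <- paste(rows, traj$mol_id)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an XYZ / extended-XYZ trajectory
#'
#' Accepts plain XYZ (species + 3 coordinate columns; coordinates assumed
#' nm) and the extended dialect written by [write_xyz()] (box from
#' `Lattice`, time from `Time=`, optional velocity and molecule-id columns).
#'
#' @param path File path.
#' @param box Fallback [box_geometry()] for plain-XYZ input without a
#'   `Lattice` entry.
#' @return A `trajectory` (wrapped coordinates only; use
#'   [unwrap_trajectory()] before MSD analysis).
#' @export
read_xyz <- function(path, box = NULL) {
  lines <- readLines(path)
  frames <- list()
  pos <- 1
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "") { pos <- pos + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("malformed XYZ atom count at line ", pos)
    if (pos + 1 + n > length(lines)) {
      stop("truncated XYZ frame starting at line ", pos, ": expected ", n, " atoms")
    }
    comment <- lines[pos + 1]
    lat <- regmatches(comment, regexec("Lattice=\"([^\"]+)\"", comment))[[1]]
    tim <- regmatches(comment, regexec("Time=([0-9eE+.-]+)", comment))[[1]]
    body <- lines[(pos + 2):(pos + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol_body <- length(toks[[1]])
    if (any(vapply(toks, length, integer(1)) != ncol_body)) {
      stop("inconsistent column count in XYZ frame at line ", pos + 2)
    }
    mat <- matrix(unlist(toks), n, ncol_body, byrow = TRUE)
    coords <- matrix(suppressWarnings(as.numeric(mat[, 2:4])), n, 3)
    if (anyNA(coords)) {
      stop("malformed XYZ atom line ", pos + 1 + which(is.na(coords[, 1]))[1])
    }
    fr <- list(species = mat[, 1], coords = coords, vel = NULL, mol = NULL)
    if (ncol_body >= 7) fr$vel <- matrix(as.numeric(mat[, 5:7]), n, 3)
    if (ncol_body %in% c(5, 8)) fr$mol <- as.integer(mat[, ncol_body])
    fr$lattice <- if (length(lat) == 2) as.numeric(strsplit(lat[2], "\\s+")[[1]]) else NULL
    fr$time <- if (length(tim) == 2) as.numeric(tim[2]) else NA_real_
    frames[[length(frames) + 1]] <- fr
    pos <- pos + 2 + n
  }
  if (length(frames) == 0) stop("no frames found in ", path)
  n <- nrow(frames[[1]]$coords)
  nf <- length(frames)
  if (any(vapply(frames, function(f) nrow(f$coords), integer(1)) != n)) {
    stop("inconsistent atom counts across XYZ frames")
  }
  co <- array(0, c(n, 3, nf))
  vel <- if (!is.null(frames[[1]]$vel)) array(0, c(n, 3, nf)) else NULL
  for (f in seq_len(nf)) {
    co[, , f] <- frames[[f]]$coords
    if (!is.null(vel)) vel[, , f] <- frames[[f]]$vel
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (anyNA(times)) times <- seq(0, by = 1, length.out = nf)
  lat <- frames[[1]]$lattice
  bx <- if (!is.null(lat)) box_geometry(lat[1], lat[5], lat[9]) else box
  if (is.null(bx)) stop("no Lattice entry in file and no fallback box supplied")
  make_trajectory(co, times, frames[[1]]$species, bx, velocities = vel,
                  mol_id = frames[[1]]$mol %||% seq_len(n))
}

#' Read / write a run configuration
#'
#' Run configurations are YAML key-value files holding the species registry,
#' analysis parameters (contact cutoff, local-composition radius, fit
#' windows, bins), grids and seeds. [read_run_config()] validates bounds and
#' fills defaults; a read-write-read round trip is the identity.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A `run_config` (or plain named list).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  validate_run_config(list())
}

validate_run_config <- function(cfg) {
  defaults <- list(
    species = default_species()$name,
    chi_water = 0.1,
    contact_cutoff = 0.6,
    local_radius = 1.2,
    equilibration_discard = 0.2,
    fit_window = c(0.1, 0.5),
    profile_bin = 0.1,
    rdf_bin = 0.02,
    temperatures = seq(270, 330, by = 10),
    seed = 1L
  )
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  num_fields <- c("chi_water", "contact_cutoff", "local_radius",
                  "equilibration_discard", "fit_window", "profile_bin",
                  "rdf_bin", "temperatures")
  for (nm in num_fields) cfg[[nm]] <- as.numeric(unlist(cfg[[nm]]))
  cfg$seed <- as.integer(cfg$seed)
  cfg$species <- as.character(unlist(cfg$species))
  stopifnot(cfg$contact_cutoff > 0, cfg$local_radius > 0,
            cfg$chi_water >= 0, cfg$chi_water <= 1,
            cfg$equilibration_discard >= 0, cfg$equilibration_discard < 1,
            length(cfg$fit_window) == 2, cfg$fit_window[1] < cfg$fit_window[2])
  structure(cfg, class = c("run_config", "list"))
}

#' Run a seeded simulate-and-analyse demonstration pipeline
#'
#' End-to-end smoke pipeline: simulates a binary toy mixture over a sweep of
#' cross-interaction factors kappa, computes the contact-based mixing metric
#' on equilibrated frames of each run and classifies each cell, writing a
#' miscibility CSV plus one JSON-lines result record per stage. Identical
#' config and seed reproduce identical result files (timestamps excluded
#' from the outputs).
#'
#' @param out_dir Output directory (created if needed).
#' @param kappas Cross-interaction sweep (mixing decreases as kappa drops).
#' @param n_particles Particles per run.
#' @param n_steps Langevin steps per run.
#' @param temperature Temperature (K).
#' @param seed Base seed; per-run seeds are derived deterministically.
#' @param config Optional `run_config` overriding analysis defaults.
#' @return Data frame with one row per kappa (`kappa`, `mean_pct`, `sd_pct`,
#'   `class`), invisibly written to `miscibility.csv` and `records.jsonl`
#'   in `out_dir`.
#' @export
run_demo_pipeline <- function(out_dir, kappas = c(1.0, 0.6, 0.2),
                              n_particles = 150, n_steps = 1500,
                              temperature = 300, seed = 1, config = NULL) {
  cfg <- config %||% default_run_config()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ff0 <- toy_forcefield(c("HexA", "IMID"))
  records <- list()
  rows <- lapply(seq_along(kappas), function(i) {
    kap <- kappas[i]
    run_seed <- cell_seed(seed, c(i))
    ff <- toy_forcefield(c("HexA", "IMID"), kappa = kap, eps = ff0$eps[1, 1],
                         sigma = ff0$sigma, cutoff = ff0$cutoff)
    start <- build_random_config(c(HexA = 0.5, IMID = 0.5), n_particles,
                                 seed = run_seed)
    traj <- run_langevin(start, ff, temperature = temperature,
                         n_steps = n_steps, seed = run_seed)
    ser <- contact_series(traj, cutoff = cfg$contact_cutoff,
                          discard = cfg$equilibration_discard)
    records[[length(records) + 1]] <<- list(
      stage = "simulate+contacts", kappa = kap, seed = run_seed,
      n_particles = n_particles, n_steps = n_steps,
      mean_pct = mean(ser$pct, na.rm = TRUE))
    data.frame(kappa = kap, mean_pct = mean(ser$pct, na.rm = TRUE),
               sd_pct = stats::sd(ser$pct, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out$class <- classify_mixing(pmin(100, pmax(0, out$mean_pct)))
  utils::write.csv(out, file.path(out_dir, "miscibility.csv"), row.names = FALSE)
  con <- file(file.path(out_dir, "records.jsonl"), "w")
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  close(con)
  out
}
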