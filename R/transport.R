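#' Mean squared displacement with multiple time origins
#'
#' Computes the species-resolved MSD from image-consistent (unwrapped)
#' coordinates, averaging over walkers and over time origins spaced
#' `origin_stride` frames apart. Per-walker displacement curves are retained
#' so that downstream fits can report an honest standard error (spread of
#' per-walker diffusion estimates) rather than the optimistic error of a
#' single correlated curve.
#'
#' @param traj A `trajectory`. Wrapped-only trajectories are unwrapped via
#'   minimum-image reconstruction first (see [unwrap_trajectory()]).
#' @param species Species to include (default: all).
#' @param origin_stride Frames between successive time origins.
#' @param max_lag_frames Largest lag, in frames (default: half the
#'   trajectory).
#' @return An object of class `msd_series`: data frame fields `lag` (ps),
#'   `msd` (nm^2), `n_pairs` (origin-walker pairs per lag), plus attributes
#'   `per_walker` (walker x lag matrix) and `dt`.
#' @export
compute_msd <- function(traj, species = NULL, origin_stride = 1,
                        max_lag_frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  traj <- unwrap_trajectory(traj)
  sel <- if (is.null(species)) seq_along(traj$species) else which(traj$species %in% species)
  if (length(sel) == 0) stop("no particles of the requested species")
  un <- traj$unwrapped[sel, , , drop = FALSE]
  nf <- dim(un)[3]
  nw <- dim(un)[1]
  max_lag <- max_lag_frames %||% max(1L, nf %/% 2)
  max_lag <- min(max_lag, nf - 1L)
  origins <- seq(1L, nf - 1L, by = origin_stride)
  dtf <- traj$times[2] - traj$times[1]
  msd_w <- matrix(0, nw, max_lag)
  npairs <- integer(max_lag)
  for (lag in seq_len(max_lag)) {
    os <- origins[origins + lag <= nf]
    if (length(os) == 0) break
    acc <- matrix(0, nw, 1)
    for (o in os) {
      d <- un[, , o + lag] - un[, , o]
      dim(d) <- c(nw, 3)
      acc <- acc + rowSums(d^2)
    }
    msd_w[, lag] <- acc / length(os)
    npairs[lag] <- length(os) * nw
  }
  out <- data.frame(lag = c(0, seq_len(max_lag) * dtf),
                    msd = c(0, colMeans(msd_w)),
                    n_pairs = c(nw * length(origins), npairs))
  attr(out, "per_walker") <- msd_w
  attr(out, "dt") <- dtf
  attr(out, "species") <- species %||% "all"
  class(out) <- c("msd_series", class(out))
  out
}

window_frames <- function(msd, window) {
  maxlag <- max(msd$lag)
  lo <- window[1] * maxlag
  hi <- window[2] * maxlag
  which(msd$lag >= lo & msd$lag <= hi & msd$lag > 0)
}

#' Diffusion coefficient from the Einstein relation
#'
#' Fits MSD = c + 6 D t by least squares over a lag window and reports
#' D = slope/6. The default window, 10--50% of the maximum lag, avoids both
#' the short-time ballistic/cage regime and the poorly averaged long-lag
#' tail. When the MSD carries per-walker curves, the standard error is the
#' spread of per-walker slopes (SEM), which remains valid despite the strong
#' correlation between lags of a single averaged curve; otherwise the
#' ordinary fit error is used. The fit R^2 is reported as a linearity
#' diagnostic (ballistic motion shows up as a poor linear fit on a log
#' scale; here R^2 of the linear fit plus the intercept magnitude serve as
#' the flag).
#'
#' @param msd An `msd_series` (or data frame with `lag`, `msd`).
#' @param window Fractions of the maximum lag delimiting the fit window.
#' @return Object of class `diffusion_result`: list with `D` (nm^2/ps),
#'   `D_cm2_s` (1e-5 cm^2/s), `se`, `r_squared`, `window` (ps), `n_lags`.
#' @examples
#' msd <- data.frame(lag = 0:10, msd = 0.3 * (0:10))
#' einstein_diffusion(msd)$D # exactly 0.05
#' @export
einstein_diffusion <- function(msd, window = c(0.1, 0.5)) {
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be two increasing fractions of the maximum lag")
  }
  idx <- window_frames(msd, window)
  if (length(idx) < 2) stop("fit window contains fewer than 2 lags")
  fit <- stats::lm(msd ~ lag, data = msd[idx, , drop = FALSE])
  slope <- stats::coef(fit)[["lag"]]
  se_fit <- suppressWarnings(summary(fit))$coefficients["lag", "Std. Error"]
  pw <- attr(msd, "per_walker")
  if (!is.null(pw) && nrow(pw) > 1) {
    lags <- msd$lag[idx]
    # per-walker slope via closed-form OLS on the same window
    lg <- lags - mean(lags)
    y <- pw[, idx - 1L, drop = FALSE] # per_walker has no lag-0 column
    slopes <- (y %*% lg) / sum(lg^2)
    se <- stats::sd(slopes) / sqrt(nrow(pw)) / 6
  } else {
    se <- se_fit / 6
  }
  structure(list(
    D = slope / 6,
    D_cm2_s = slope / 6 * 1e3, # nm^2/ps = 1e-5 cm^2/s * 1e3
    se = se,
    r_squared = suppressWarnings(summary(fit))$r.squared,
    intercept = stats::coef(fit)[[1]],
    window = range(msd$lag[idx]),
    n_lags = length(idx)
  ), class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> D = %.4g +/- %.2g nm^2/ps (%.4g x 1e-5 cm^2/s), R^2 = %.4f, window %.3g..%.3g ps\n",
              x$D, x$se, x$D_cm2_s, x$r_squared, x$window[1], x$window[2]))
  invisible(x)
}

#' Finite-size extrapolation of diffusion coefficients
#'
#' Periodic boxes suppress diffusion in proportion to the inverse box edge;
#' fitting measured D against N^(-1/3) (N = particle count) and extrapolating
#' to N^(-1/3) = 0 estimates the infinite-system value. The fit is weighted
#' by 1/SE^2 when standard errors are supplied.
#'
#' @param points Data frame with columns `N`, `D` and optionally `se`.
#' @return Object of class `finite_size_fit`: `D_inf` (intercept), `se`
#'   (intercept standard error), `slope`, `points`.
#' @examples
#' pts <- data.frame(N = c(1e4, 16e4, 81e4), D = 5 - 2 * c(1e4, 16e4, 81e4)^(-1/3))
#' finite_size_extrapolate(pts)$D_inf # 5
#' @export
finite_size_extrapolate <- function(points) {
  if (length(unique(points$N)) < 2) {
    stop("finite-size extrapolation needs at least 2 distinct system sizes")
  }
  points$x <- points$N^(-1 / 3)
  w <- if (!is.null(points$se) && all(points$se > 0)) 1 / points$se^2 else NULL
  fit <- stats::lm(D ~ x, data = points, weights = w)
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(
    D_inf = stats::coef(fit)[[1]],
    se = sm["(Intercept)", "Std. Error"],
    slope = stats::coef(fit)[["x"]],
    points = points[, c("N", "x", "D")]
  ), class = "finite_size_fit")
}

#' @export
print.finite_size_fit <- function(x, ...) {
  cat(sprintf("<finite_size_fit> D_inf = %.4g +/- %.2g (slope %.3g vs N^-1/3, %d sizes)\n",
              x$D_inf, x$se, x$slope, nrow(x$points)))
  invisible(x)
}

#' Classify molecules into phases by local composition
#'
#' Labels every molecule by the composition of molecule centres within a
#' spherical neighbourhood: if the fraction of neighbours belonging to one
#' phase group reaches `threshold`, the molecule is assigned to that phase;
#' ties, empty neighbourhoods and sub-threshold majorities are labelled
#' `interfacial`. Water is excluded from the vote by default since the
#' phases of interest are the HexA-rich and IMID-rich ones.
#'
#' @param frame A `frame`.
#' @param radius Neighbourhood radius (nm); default 1.2.
#' @param groups Named list mapping phase label -> character vector of
#'   species. Default: `HexA-rich` = HexA/HexA-, `IMID-rich` = IMID/IMID+.
#' @param threshold Minimum neighbour fraction for a phase call (default
#'   0.5, strict majority required: exactly 0.5 is a tie -> interfacial).
#' @param exclude Species excluded from the vote (default water).
#' @return Object of class `phase_assignment`: data frame with `mol_id`,
#'   `species`, `label`; attributes record radius/threshold conventions.
#' @export
classify_local_phase <- function(frame, radius = 1.2,
                                 groups = list(
                                   "HexA-rich" = c("HexA", "HexA-"),
                                   "IMID-rich" = c("IMID", "IMID+")),
                                 threshold = 0.5,
                                 exclude = c("water", "W")) {
  stopifnot(inherits(frame, "frame"))
  if (radius > min(frame$box$L) / 2) {
    stop("radius exceeds half the shortest box edge")
  }
  cen <- molecule_centers(frame)
  sp_levels <- sort(unique(cen$species))
  counts <- neighbor_species_counts_cpp(cen$centers,
                                        match(cen$species, sp_levels) - 1L,
                                        length(sp_levels), frame$box$L, radius)
  colnames(counts) <- sp_levels
  voting <- setdiff(sp_levels, exclude)
  group_counts <- vapply(groups, function(g) {
    g <- intersect(g, voting)
    if (length(g) == 0) rep(0, nrow(counts)) else
      rowSums(counts[, g, drop = FALSE])
  }, numeric(nrow(counts)))
  total <- rowSums(counts[, voting, drop = FALSE])
  label <- rep("interfacial", nrow(counts))
  ok <- total > 0
  frac <- group_counts / pmax(total, 1)
  best <- max.col(frac, ties.method = "first")
  bestfrac <- frac[cbind(seq_len(nrow(frac)), best)]
  # strict majority above threshold; exact ties between groups stay interfacial
  second <- apply(frac, 1, function(r) sort(r, decreasing = TRUE)[min(2, length(r))])
  assign <- ok & bestfrac > threshold - 1e-12 & bestfrac > second + 1e-12
  label[assign] <- names(groups)[best[assign]]
  out <- data.frame(mol_id = cen$mol_id, species = cen$species, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "radius") <- radius
  attr(out, "threshold") <- threshold
  attr(out, "exclude") <- exclude
  attr(out, "note") <- "majority of non-excluded neighbour centres; ties/empty -> interfacial"
  class(out) <- c("phase_assignment", class(out))
  out
}

#' Survivor-bias-free per-phase diffusion
#'
#' Estimates a diffusion coefficient separately for molecules that started in
#' each phase. To avoid survivor bias, a molecule is grouped by the phase it
#' occupied at each time origin and contributes its *entire* subsequent
#' displacement to that group, whether or not it later changes phase. The
#' survivor-only variant (molecules discarded once they leave their phase,
#' `survivors_only = TRUE`) is provided solely to demonstrate the bias.
#'
#' @param traj A `trajectory`.
#' @param labels Per-molecule phase labels: either a character vector
#'   (static assignment), an N x F matrix (per frame), or a function
#'   `frame -> phase_assignment` applied at each origin. With the
#'   compartment generator, `metadata$compartment` is used automatically
#'   when `labels` is NULL.
#' @param species Species filter (default all).
#' @param origin_stride Frames between time origins.
#' @param max_lag_frames Largest lag in frames.
#' @param window Fit window for [einstein_diffusion()].
#' @param survivors_only If TRUE, restrict each origin's group to molecules
#'   that remain in the phase for the whole lag (biased; for demonstration).
#' @return A list of `diffusion_result` objects, one per phase label, each
#'   with an attached `msd` series; phases with no members yield `NULL` with
#'   a warning.
#' @export
per_phase_diffusion <- function(traj, labels = NULL, species = NULL,
                                origin_stride = 1, max_lag_frames = NULL,
                                window = c(0.1, 0.5), survivors_only = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  traj <- unwrap_trajectory(traj)
  nf <- n_frames(traj)
  n <- dim(traj$coords)[1]
  if (is.null(labels)) labels <- traj$metadata$compartment
  if (is.null(labels)) stop("no phase labels supplied or stored in the trajectory")
  if (is.function(labels)) {
    lab_mat <- vapply(seq_len(nf), function(f) {
      as.character(labels(get_frame(traj, f))$label)
    }, character(n))
  } else if (is.matrix(labels)) {
    lab_mat <- labels
  } else {
    lab_mat <- matrix(as.character(labels), n, nf)
  }
  storage.mode(lab_mat) <- "character"
  sel <- if (is.null(species)) seq_len(n) else which(traj$species %in% species)
  un <- traj$unwrapped
  max_lag <- max_lag_frames %||% max(1L, nf %/% 2)
  max_lag <- min(max_lag, nf - 1L)
  origins <- seq(1L, nf - 1L, by = origin_stride)
  dtf <- traj$times[2] - traj$times[1]
  phases <- sort(unique(as.vector(lab_mat[sel, ])))
  out <- list()
  for (ph in phases) {
    sums <- numeric(max_lag)
    cnts <- numeric(max_lag)
    per_mol_sum <- matrix(0, length(sel), max_lag)
    per_mol_cnt <- matrix(0, length(sel), max_lag)
    for (o in origins) {
      members <- sel[lab_mat[sel, o] == ph]
      if (length(members) == 0) next
      for (lag in seq_len(min(max_lag, nf - o))) {
        mem <- members
        if (survivors_only) {
          stay <- apply(lab_mat[mem, o:(o + lag), drop = FALSE] == ph, 1, all)
          mem <- mem[stay]
          if (length(mem) == 0) next
        }
        d <- un[mem, , o + lag, drop = FALSE] - un[mem, , o, drop = FALSE]
        dim(d) <- c(length(mem), 3)
        sq <- rowSums(d^2)
        sums[lag] <- sums[lag] + sum(sq)
        cnts[lag] <- cnts[lag] + length(mem)
        rows <- match(mem, sel)
        per_mol_sum[rows, lag] <- per_mol_sum[rows, lag] + sq
        per_mol_cnt[rows, lag] <- per_mol_cnt[rows, lag] + 1
      }
    }
    if (all(cnts == 0)) {
      warning("phase '", ph, "' has no members at any origin")
      out[[ph]] <- NULL
      next
    }
    msd <- data.frame(lag = c(0, seq_len(max_lag) * dtf),
                      msd = c(0, ifelse(cnts > 0, sums / cnts, NA)),
                      n_pairs = c(length(origins) * length(sel), cnts))
    pw <- per_mol_sum / pmax(per_mol_cnt, 1)
    pw <- pw[rowSums(per_mol_cnt) > 0, , drop = FALSE]
    attr(msd, "per_walker") <- pw
    attr(msd, "dt") <- dtf
    res <- einstein_diffusion(msd, window = window)
    res$phase <- ph
    res$msd <- msd
    out[[ph]] <- res
  }
  out
}
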