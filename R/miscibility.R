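#' Count inter-molecular contacts by species pair
#'
#' Two molecules are in contact when any bead of one lies within `cutoff` of
#' any bead of the other under the minimum-image convention; each unordered
#' molecule pair is counted at most once (`mode = "molecule"`, the default).
#' `mode = "bead"` instead counts every inter-molecular bead pair within the
#' cutoff. Counts are aggregated by species pair.
#'
#' @param frame A `frame`.
#' @param cutoff Contact distance (nm); default 0.6, the molecular-contact
#'   cutoff used for the mixing metric. Must not exceed half the shortest
#'   box edge.
#' @param mode `"molecule"` or `"bead"`.
#' @param method `"cell"` (linked-cell search) or `"brute"` (all pairs);
#'   both give identical counts, `"brute"` exists as a cross-check.
#' @return An object of class `contact_report`: list with `counts` (symmetric
#'   species x species matrix), `cutoff`, `mode` and `n_molecules`.
#' @export
count_contacts <- function(frame, cutoff = 0.6,
                           mode = c("molecule", "bead"),
                           method = c("cell", "brute")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(frame, "frame"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (cutoff > min(frame$box$L) / 2) {
    stop("cutoff (", cutoff, " nm) exceeds half the shortest box edge; ",
         "minimum-image contacts would be ambiguous")
  }
  sp_levels <- sort(unique(frame$species))
  uid <- sort(unique(frame$mol_id))
  mol_f <- match(frame$mol_id, uid) - 1L
  if (mode == "molecule") {
    sp_mol <- frame$species[match(uid, frame$mol_id)]
    counts <- contact_counts_cpp(frame$coords, mol_f,
                                 match(sp_mol, sp_levels) - 1L,
                                 length(sp_levels), frame$box$L, cutoff,
                                 method == "cell")
    n_mol <- length(sp_mol)
  } else {
    counts <- bead_contact_counts_cpp(frame$coords, mol_f,
                                      match(frame$species, sp_levels) - 1L,
                                      length(sp_levels), frame$box$L, cutoff)
    n_mol <- length(unique(frame$mol_id))
  }
  dimnames(counts) <- list(sp_levels, sp_levels)
  structure(list(counts = counts, cutoff = cutoff, mode = mode,
                 n_molecules = n_mol),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("<contact_report> %s contacts at %.2f nm, %d molecules\n",
              x$mode, x$cutoff, x$n_molecules))
  print(x$counts)
  invisible(x)
}

report_count <- function(report, pair) {
  cn <- rownames(report$counts)
  if (!all(pair %in% cn)) return(0)
  report$counts[pair[1], pair[2]]
}

#' Contact-based mixing percentage
#'
#' The miscibility metric: 100 * N(numerator pair) / sum over denominator
#' pairs of N. The default follows the DES convention — cross contacts
#' between the hydrogen-bond donor and acceptor over all contacts involving
#' the acceptor: 100 * N(HexA-IMID) / (N(HexA-IMID) + N(IMID-IMID)). High
#' values mean a well-mixed system; preferential self-association of the
#' acceptor drives the percentage down.
#'
#' @param report A `contact_report` from [count_contacts()].
#' @param numerator Character vector of length 2: the cross pair.
#' @param denominator List of species pairs summed in the denominator.
#' @return The percentage in \[0, 100\], or `NA` (with a warning) when the
#'   denominator is zero — an undefined metric, deliberately distinct from 0.
#' @export
mixing_metric <- function(report,
                          numerator = c("HexA", "IMID"),
                          denominator = list(c("HexA", "IMID"),
                                             c("IMID", "IMID"))) {
  stopifnot(inherits(report, "contact_report"))
  num <- report_count(report, numerator)
  den <- sum(vapply(denominator, function(p) report_count(report, p), numeric(1)))
  if (den <= 0) {
    warning("mixing metric undefined: denominator contact count is zero")
    return(NA_real_)
  }
  100 * num / den
}

#' Classify a mixing percentage into miscibility bands
#'
#' Bands: above 50% is `mixed`, 30--45% is `partially_mixed`, below 30% is
#' `almost_biphasic`. The band definitions leave (45, 50\] unassigned; such
#' values are labelled `intermediate` explicitly rather than snapped to a
#' neighbouring band.
#'
#' @param percentage Numeric vector of mixing percentages in \[0, 100\].
#' @return Character vector of class labels.
#' @examples
#' classify_mixing(c(55, 40, 20, 47))
#' @export
classify_mixing <- function(percentage) {
  if (any(is.na(percentage)) || any(percentage < 0 | percentage > 100)) {
    stop("mixing percentage must be within [0, 100]")
  }
  out <- character(length(percentage))
  out[percentage > 50] <- "mixed"
  out[percentage > 45 & percentage <= 50] <- "intermediate"
  out[percentage >= 30 & percentage <= 45] <- "partially_mixed"
  out[percentage < 30] <- "almost_biphasic"
  out
}

#' Per-frame mixing-metric time series for one trajectory
#'
#' @param traj A `trajectory`.
#' @param cutoff Contact cutoff (nm).
#' @param discard Fraction of initial frames dropped as equilibration
#'   (default 0.2).
#' @param ... Passed to [mixing_metric()] (numerator/denominator pairs).
#' @return Data frame with `time` and `pct` for the retained frames.
#' @export
contact_series <- function(traj, cutoff = 0.6, discard = 0.2, ...) {
  nf <- n_frames(traj)
  keep <- seq_len(nf) > floor(discard * nf)
  if (!any(keep)) stop("all frames discarded as equilibration")
  idx <- which(keep)
  pct <- vapply(idx, function(f) {
    mixing_metric(count_contacts(get_frame(traj, f), cutoff = cutoff), ...)
  }, numeric(1))
  data.frame(time = traj$times[idx], pct = pct)
}

#' Miscibility table over a composition x temperature grid
#'
#' Aggregates the contact-based mixing metric over a grid of trajectories:
#' per cell, the metric is time-averaged over post-equilibration frames of
#' every replica; the cell mean, the spread across frames/replicas and the
#' class label of the mean are reported.
#'
#' @param cells A list of cells; each cell is a list with elements
#'   `chi_imid`, `temperature` and `trajectories` (a list of `trajectory`
#'   objects). Missing grid labels fall back to trajectory metadata.
#' @param cutoff Contact cutoff (nm).
#' @param discard Equilibration fraction discarded per trajectory.
#' @param ... Passed to [mixing_metric()].
#' @return A data frame of class `miscibility_table` with columns `chi_imid`,
#'   `temperature`, `mean_pct`, `sd_pct`, `n_obs`, `class`.
#' @export
miscibility_scan <- function(cells, cutoff = 0.6, discard = 0.2, ...) {
  rows <- lapply(cells, function(cell) {
    trajs <- cell$trajectories
    if (length(trajs) == 0) stop("every grid cell needs at least one trajectory")
    pct <- unlist(lapply(trajs, function(tr) {
      contact_series(tr, cutoff = cutoff, discard = discard, ...)$pct
    }))
    pct <- pct[!is.na(pct)]
    if (length(pct) == 0) stop("cell has no defined mixing metric")
    data.frame(
      chi_imid = cell$chi_imid %||% trajs[[1]]$metadata$chi_imid %||% NA_real_,
      temperature = cell$temperature %||% trajs[[1]]$metadata$temperature %||% NA_real_,
      mean_pct = mean(pct),
      sd_pct = if (length(pct) > 1) stats::sd(pct) else 0,
      n_obs = length(pct)
    )
  })
  out <- do.call(rbind, rows)
  out$class <- classify_mixing(pmin(100, pmax(0, out$mean_pct)))
  class(out) <- c("miscibility_table", class(out))
  out
}
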