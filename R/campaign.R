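#' Define a simulation campaign grid
#'
#' A campaign plan enumerates every simulation cell of a property scan:
#' composition x temperature x system size x replica, optionally crossed with
#' a list of cosine acceleration rates for viscosity campaigns. The default
#' grids are the property-scan conditions used throughout this package's
#' analyses: 7 compositions (chi_IMID 0.10--0.50), temperatures 270--330 K in
#' 10 K steps, three system sizes (10^4, 20^4, 30^4 beads) and 4 replicas of
#' 300 ns each.
#'
#' @param compositions Numeric vector of chi_IMID values.
#' @param temperatures Strictly increasing temperature grid (K).
#' @param system_sizes Particle counts.
#' @param replicas Number of replicas per cell.
#' @param per_run_length Simulated time per run (ns).
#' @param acceleration_rates Optional vector of cosine acceleration rates
#'   (nm/ps^2) for viscosity campaigns; crossed with the other grids and, by
#'   convention, run at a single system size.
#' @return An object of class `sim_plan`.
#' @examples
#' sim_plan() # the 588-run property campaign
#' @export
sim_plan <- function(compositions = c(0.10, 0.20, 0.25, 0.30, 0.35, 0.40, 0.50),
                     temperatures = seq(270, 330, by = 10),
                     system_sizes = c(10^4, 20^4, 30^4),
                     replicas = 4,
                     per_run_length = 300,
                     acceleration_rates = NULL) {
  if (length(compositions) == 0 || length(temperatures) == 0 ||
      length(system_sizes) == 0 || replicas < 1) {
    stop("every campaign grid dimension must be non-empty")
  }
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("temperatures must be strictly increasing")
  }
  structure(
    list(compositions = compositions, temperatures = temperatures,
         system_sizes = system_sizes, replicas = as.integer(replicas),
         per_run_length = per_run_length,
         acceleration_rates = acceleration_rates),
    class = "sim_plan"
  )
}

#' The viscosity-campaign plan
#'
#' Convenience constructor for the periodic-perturbation viscosity protocol:
#' the property-scan composition and temperature grids crossed with 7 cosine
#' acceleration rates (0.002 to 0.008 nm/ps^2 in 0.001 steps) and 4 replicas,
#' in 1:1:3 elongated boxes, 3 ns per run.
#'
#' @inheritParams sim_plan
#' @return A `sim_plan`.
#' @export
viscosity_plan <- function(compositions = c(0.10, 0.20, 0.25, 0.30, 0.35, 0.40, 0.50),
                           temperatures = seq(270, 330, by = 10),
                           replicas = 4, per_run_length = 3) {
  sim_plan(compositions = compositions, temperatures = temperatures,
           system_sizes = 1, replicas = replicas,
           per_run_length = per_run_length,
           acceleration_rates = seq(0.002, 0.008, by = 0.001))
}

# Deterministic per-cell seed: a small multiplicative hash folded into
# [1, 2^31 - 2]. Stable across platforms (all arithmetic below 2^53).
cell_seed <- function(base_seed, idx) {
  h <- base_seed %% 2147483647
  for (i in idx) {
    h <- (h * 31 + i * 2654435) %% 2147483647
  }
  as.integer(h + 1)
}

#' Enumerate a campaign plan into a run manifest
#'
#' Expands a [sim_plan()] into one record per simulation cell, with a
#' deterministic per-cell seed derived from the base seed and the cell's grid
#' indices, the total run count and the total simulated time.
#'
#' @param plan A `sim_plan`.
#' @param base_seed Base random seed; each cell's seed is a stable hash of
#'   this value and the cell indices.
#' @return A list with `manifest` (data frame: one row per run with columns
#'   `run`, `chi_imid`, `temperature`, `system_size`, `replica`, optionally
#'   `acceleration`, and `seed`), `n_runs` and `total_time_us`.
#' @examples
#' cam <- build_campaign(sim_plan())
#' cam$n_runs        # 588
#' cam$total_time_us # 176.4
#' @export
build_campaign <- function(plan, base_seed = 1L) {
  stopifnot(inherits(plan, "sim_plan"))
  grids <- list(chi_imid = plan$compositions,
                temperature = plan$temperatures,
                system_size = plan$system_sizes,
                replica = seq_len(plan$replicas))
  if (!is.null(plan$acceleration_rates)) {
    grids$acceleration <- plan$acceleration_rates
    if (length(plan$system_sizes) == 1) grids$system_size <- NULL
  }
  manifest <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)
  manifest <- manifest[, rev(names(manifest)), drop = FALSE]
  idx <- lapply(names(grids), function(nm) match(manifest[[nm]], grids[[nm]]))
  manifest$seed <- vapply(seq_len(nrow(manifest)), function(r) {
    cell_seed(base_seed, vapply(idx, `[[`, numeric(1), r))
  }, integer(1))
  manifest <- cbind(run = seq_len(nrow(manifest)), manifest)
  list(
    manifest = manifest,
    n_runs = nrow(manifest),
    total_time_us = nrow(manifest) * plan$per_run_length / 1000
  )
}
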