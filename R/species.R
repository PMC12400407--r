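#' Boltzmann constant in internal units
#'
#' Boltzmann constant in the internal unit system (kJ mol^-1 K^-1). All
#' quantities in this package use the nm / ps / amu / kJ mol^-1 / K
#' convention common in coarse-grained molecular simulation, so that
#' velocities are nm/ps, diffusion coefficients nm^2/ps and energies kJ/mol.
#'
#' @format A length-one numeric.
#' @export
kB <- 0.0083144621

#' Built-in species registry
#'
#' Returns the registry of the species handled by the composition algebra:
#' hexanoic acid (HexA) and its conjugate base hexanoate (HexA-), imidazole
#' (IMID) and imidazolium (IMID+), water, oleic acid (OLEC) and linoleic acid
#' (LINO). Two mass models are provided: `atomistic` molar masses (g/mol) and
#' a `cg-bead` table in which each molecule carries the summed mass of its
#' coarse-grained beads (one water bead stands for four water molecules).
#'
#' @param mass_model Either `"atomistic"` (default) or `"cg-bead"`.
#' @return A data frame with columns `name`, `molar_mass`, `charge_state`
#'   and `role`, one row per species.
#' @examples
#' default_species()
#' @export
default_species <- function(mass_model = c("atomistic", "cg-bead")) {
  mass_model <- match.arg(mass_model)
  atomistic <- c(
    HexA = 116.16, `HexA-` = 115.15, IMID = 68.08, `IMID+` = 69.09,
    water = 18.02, OLEC = 282.46, LINO = 280.45
  )
  cg <- c(
    HexA = 126, `HexA-` = 126, IMID = 108, `IMID+` = 108,
    water = 72, OLEC = 342, LINO = 342
  )
  mm <- if (mass_model == "atomistic") atomistic else cg
  data.frame(
    name = names(mm),
    molar_mass = unname(mm),
    charge_state = c("neutral", "anion", "neutral", "cation",
                     "neutral", "neutral", "neutral"),
    role = c("HBD", "HBD", "HBA", "HBA", "water", "oil", "oil"),
    stringsAsFactors = FALSE
  )
}

#' Look up molar masses for a set of species
#'
#' @param species Character vector of species names.
#' @param mass_model `"atomistic"` or `"cg-bead"`; alternatively a named
#'   numeric vector supplying a custom mass table.
#' @return Named numeric vector of molar masses (g/mol).
#' @export
molar_masses <- function(species, mass_model = "atomistic") {
  if (is.numeric(mass_model)) {
    tab <- mass_model
  } else {
    reg <- default_species(mass_model)
    tab <- stats::setNames(reg$molar_mass, reg$name)
  }
  missing <- setdiff(species, names(tab))
  if (length(missing) > 0) {
    stop("no molar mass for species: ", paste(missing, collapse = ", "))
  }
  tab[species]
}
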