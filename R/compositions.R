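#' Build a solvent composition on the HexA / IMID / water simplex
#'
#' Constructs a mole-fraction composition for the hexanoic acid (HexA) +
#' imidazole (IMID) deep eutectic solvent with a fixed water content. Mole
#' fractions are defined over the solvent species only (HexA, IMID, water and
#' their reacted forms); the balance after IMID and water is assigned to HexA.
#' An optional oil loading (grams of oil per gram of solvent) attaches oil on
#' a mass basis without entering the solvent mole-fraction simplex.
#'
#' @param chi_imid Mole fraction of imidazole.
#' @param chi_water Mole fraction of water (default 0.1, the hydration level
#'   used throughout the composition grids).
#' @param oil_loading Optional mass of oil per mass of solvent (g/g).
#' @param oil_species Oil identity, `"OLEC"` (oleic) or `"LINO"` (linoleic).
#' @param mass_model Mass table used to convert the oil loading to moles;
#'   see [molar_masses()].
#' @return An object of class `composition`: a list with `fractions` (named,
#'   sums to 1), `xi` (extent of reaction, starts at 0), `oil_loading`,
#'   `oil_species` and `oil_moles` (per mole of solvent).
#' @examples
#' make_composition(0.30, 0.10) # HexA:IMID = 2:1
#' @export
make_composition <- function(chi_imid, chi_water = 0.1, oil_loading = NULL,
                             oil_species = "OLEC", mass_model = "atomistic") {
  if (!is.numeric(chi_imid) || length(chi_imid) != 1 || chi_imid < 0 || chi_imid > 1) {
    stop("chi_imid must be a single mole fraction in [0, 1], got ", chi_imid)
  }
  if (!is.numeric(chi_water) || length(chi_water) != 1 || chi_water < 0 || chi_water > 1) {
    stop("chi_water must be a single mole fraction in [0, 1], got ", chi_water)
  }
  chi_hexa <- 1 - chi_imid - chi_water
  if (chi_hexa < -1e-12) {
    stop("infeasible composition: chi_HexA = 1 - chi_imid - chi_water = ",
         signif(chi_hexa, 6), " is negative")
  }
  chi_hexa <- max(chi_hexa, 0)
  fr <- c(HexA = chi_hexa, `HexA-` = 0, IMID = chi_imid, `IMID+` = 0,
          water = chi_water)
  oil_moles <- 0
  if (!is.null(oil_loading)) {
    if (oil_loading < 0) stop("oil_loading must be non-negative")
    mm <- molar_masses(c(names(fr), oil_species), mass_model)
    solvent_mass <- sum(fr * mm[names(fr)]) # g per mole of solvent
    oil_moles <- oil_loading * solvent_mass / mm[[oil_species]]
  }
  structure(
    list(fractions = fr, xi = 0,
         oil_loading = if (is.null(oil_loading)) NA_real_ else oil_loading,
         oil_species = oil_species, oil_moles = oil_moles),
    class = "composition"
  )
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition>\n")
  fr <- x$fractions[x$fractions > 0 | names(x$fractions) %in% c("HexA", "IMID", "water")]
  for (s in names(fr)) cat(sprintf("  chi_%-6s %.4f\n", s, fr[[s]]))
  cat(sprintf("  extent of reaction xi = %.2f\n", x$xi))
  if (!is.na(x$oil_loading)) {
    cat(sprintf("  oil: %s, %.3f g/g solvent (%.4f mol per mol solvent)\n",
                x$oil_species, x$oil_loading, x$oil_moles))
  }
  invisible(x)
}

#' Extract a mole fraction from a composition
#'
#' @param comp A `composition`.
#' @param species Species name.
#' @return The mole fraction (0 if the species is absent).
#' @export
chi <- function(comp, species) {
  stopifnot(inherits(comp, "composition"))
  if (species %in% names(comp$fractions)) comp$fractions[[species]] else 0
}

check_composition <- function(comp) {
  s <- sum(comp$fractions)
  if (any(comp$fractions < -1e-12)) stop("negative mole fraction")
  if (abs(s - 1) > 1e-9) stop("mole fractions sum to ", s, ", not 1")
  invisible(comp)
}

#' Apply an extent of reaction to a DES composition
#'
#' Advances the proton-transfer reaction HexA + IMID -> HexA- + IMID+ to a
#' stated extent. The extent xi is the fraction of the *available* IMID that
#' is converted; conversion is capped by the HexA present, so the number of
#' reacted pairs is min(xi * n_IMID, n_HexA) per mole of mixture. The swap is
#' mole-for-mole (a bead identity change), so total moles and the elemental
#' totals IMID + IMID+ and HexA + HexA- are conserved.
#'
#' @param comp A `composition` containing HexA and IMID entries.
#' @param xi Extent of reaction in \[0, 1\].
#' @return A new `composition` with `xi` recorded.
#' @examples
#' comp <- make_composition(0.50, 0.10)
#' apply_reaction_extent(comp, 1) # 0.10 IMID left unreacted (HexA exhausted)
#' @export
apply_reaction_extent <- function(comp, xi) {
  stopifnot(inherits(comp, "composition"))
  if (!is.numeric(xi) || length(xi) != 1 || is.na(xi) || xi < 0 || xi > 1) {
    stop("extent of reaction xi must be in [0, 1], got ", xi)
  }
  fr <- comp$fractions
  if (!all(c("IMID", "HexA") %in% names(fr))) {
    stop("composition must contain IMID and HexA entries")
  }
  reacted <- min(xi * fr[["IMID"]], fr[["HexA"]])
  fr[["IMID"]] <- fr[["IMID"]] - reacted
  fr[["HexA"]] <- fr[["HexA"]] - reacted
  fr[["IMID+"]] <- fr[["IMID+"]] + reacted
  fr[["HexA-"]] <- fr[["HexA-"]] + reacted
  out <- comp
  out$fractions <- fr
  out$xi <- xi
  check_composition(out)
}

#' Solvent-regeneration mass balance
#'
#' Computes how much hexanoic acid must be added to a phase-separated mixture
#' to dilute the imidazole content back to a target mole fraction, and the
#' resulting growth of the solvent mass. Writing n for the initial total
#' solvent moles and x for the added HexA moles, the target chi satisfies
#' chi_IMID * n / (n + x) = target, so x = n (chi_IMID/target - 1).
#'
#' @param start A `composition` (the phase-separated state).
#' @param target_chi_imid Desired chi_IMID after HexA addition; must be below
#'   the starting value.
#' @param mass_model `"atomistic"` (default) or `"cg-bead"`, or a named mass
#'   table; see [molar_masses()].
#' @param include_oil Whether the oil mass (if any) is counted in the solvent
#'   mass ratio. Default `FALSE`: the factor refers to the solvent only.
#' @return A list with `added_moles_HexA` (per mole of initial solvent),
#'   `mass_factor` (final/initial mass), the post-addition `composition`, and
#'   the conventions used.
#' @examples
#' reg <- regeneration_mass_balance(make_composition(0.60, 0.10), 0.30)
#' reg$mass_factor # about 2.5
#' @export
regeneration_mass_balance <- function(start, target_chi_imid,
                                      mass_model = "atomistic",
                                      include_oil = FALSE) {
  stopifnot(inherits(start, "composition"))
  chi0 <- chi(start, "IMID") + chi(start, "IMID+")
  if (target_chi_imid <= 0) stop("target chi_IMID must be positive")
  if (target_chi_imid >= chi0) {
    stop("target chi_IMID (", target_chi_imid,
         ") must be below the starting value (", chi0, ")")
  }
  # per 1 mole of initial solvent
  added <- chi0 / target_chi_imid - 1
  fr <- start$fractions
  mm <- molar_masses(names(fr), mass_model)
  mass0 <- sum(fr * mm[names(fr)])
  if (include_oil && !is.na(start$oil_loading)) {
    mass0 <- mass0 + start$oil_moles * molar_masses(start$oil_species, mass_model)[[1]]
  }
  mass_add <- added * molar_masses("HexA", mass_model)[[1]]
  new_fr <- fr
  new_fr[["HexA"]] <- new_fr[["HexA"]] + added
  new_fr <- new_fr / (1 + added)
  after <- start
  after$fractions <- new_fr
  check_composition(after)
  list(
    added_moles_HexA = added,
    mass_factor = (mass0 + mass_add) / mass0,
    after = after,
    mass_model = if (is.numeric(mass_model)) "custom" else mass_model,
    oil_included = include_oil
  )
}

#' Unreacted IMID fraction at full reaction extent
#'
#' At full extent every IMID is converted until the HexA supply is exhausted;
#' mixtures with more IMID than HexA keep an unreacted IMID excess. With
#' chi_H2O fixed, the excess is max(0, chi_IMID - (1 - chi_IMID - chi_H2O)),
#' which first becomes positive at chi_IMID = (1 - chi_H2O)/2 (0.45 at the
#' default hydration).
#'
#' @param chi_imid Imidazole mole fraction (vectorised).
#' @param chi_water Water mole fraction.
#' @return Unreacted IMID mole fraction at xi = 1.
#' @export
unreacted_imid_at_full_extent <- function(chi_imid, chi_water = 0.1) {
  vapply(chi_imid, function(ci) {
    chi(apply_reaction_extent(make_composition(ci, chi_water), 1), "IMID")
  }, numeric(1))
}
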