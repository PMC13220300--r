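#' Sugar molar composition
#'
#' @param glucose,xylose,arabinose Molar ratio parts (dimensionless,
#'   `glucose > 0`, others >= 0). Only ratios matter: `c(53, 37, 4)` and
#'   `c(5.3, 3.7, 0.4)` are equivalent.
#' @return An object of class `sugar_composition`.
#' @export
sugar_composition <- function(glucose, xylose = 0, arabinose = 0) {
  if (glucose <= 0) stop_invalid("`glucose` must be > 0")
  if (xylose < 0 || arabinose < 0) stop_invalid("parts must be >= 0")
  structure(list(glucose = glucose, xylose = xylose, arabinose = arabinose),
            class = "sugar_composition")
}

#' Default monomer masses (g/mol)
#'
#' Anhydro-glucose 162, anhydro-xylose and anhydro-arabinose 132, a lignin
#' C9 unit of 211 (an equal syringyl:guaiacyl mixture), water 18.02.
#'
#' @return Named numeric vector.
#' @export
default_monomer_masses <- function() {
  c(glucose = 162, xylose = 132, arabinose = 132, lignin = 211,
    water = 18.02)
}

#' Decimal half-up rounding for presentation values
#'
#' Rounds halves away from zero on the decimal representation (base
#' `round()` is round-half-even), with a small guard against binary
#' representation error so that e.g. 15.85 rounds to 15.9 at one decimal.
#' Intended for non-negative presentation quantities (counts, radii).
#'
#' @param x Non-negative numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9) / s
}

#' Per-microfibril stoichiometry from composition measurements
#'
#' Converts a sugar molar composition, a carbohydrate:lignin mass ratio and
#' a dry-basis moisture content into residue counts per 18 glucose units
#' (one 18-chain microfibril repeat): `xylose = 18 * xyl/glc`,
#' `arabinose = 18 * ara/glc`, lignin monomers from the carbohydrate mass
#' per 18 glucose times the lignin:carbohydrate mass ratio divided by the
#' monomer mass, and water molecules from the moisture content applied to
#' the dry (carbohydrate + lignin) mass. Exact real counts are kept
#' alongside half-up-rounded presentation integers.
#'
#' @param sugars A [sugar_composition] (e.g. 53:37:4).
#' @param carb_to_lignin_mass Length-2 mass ratio carbohydrate:lignin
#'   (default `c(65, 20)`).
#' @param moisture_dry_basis Moisture content on a dry basis (default 0.30).
#' @param monomer_masses Named masses as in [default_monomer_masses()].
#' @return An object of class `microfibril_stoichiometry`: lists `exact` and
#'   `rounded` with entries `xylose`, `arabinose`, `lignin`, `water`, plus
#'   the input record.
#' @export
per_fibril_counts <- function(sugars,
                              carb_to_lignin_mass = c(65, 20),
                              moisture_dry_basis = 0.30,
                              monomer_masses = default_monomer_masses()) {
  stopifnot(inherits(sugars, "sugar_composition"))
  if (any(carb_to_lignin_mass <= 0))
    stop_invalid("`carb_to_lignin_mass` parts must be > 0")
  if (moisture_dry_basis < 0)
    stop_invalid("`moisture_dry_basis` must be >= 0")
  if (any(monomer_masses <= 0)) stop_invalid("monomer masses must be > 0")
  m <- monomer_masses
  n_xyl <- 18 * sugars$xylose / sugars$glucose
  n_ara <- 18 * sugars$arabinose / sugars$glucose
  carb_mass <- 18 * m[["glucose"]] + n_xyl * m[["xylose"]] +
    n_ara * m[["arabinose"]]
  lignin_mass <- carb_mass * carb_to_lignin_mass[2] / carb_to_lignin_mass[1]
  n_lig <- lignin_mass / m[["lignin"]]
  dry_mass <- carb_mass + lignin_mass
  n_wat <- moisture_dry_basis * dry_mass / m[["water"]]
  exact <- c(xylose = n_xyl, arabinose = n_ara, lignin = n_lig,
             water = n_wat)
  structure(list(exact = exact,
                 rounded = round_half_up(exact),
                 inputs = list(sugars = unclass(sugars),
                               carb_to_lignin_mass = carb_to_lignin_mass,
                               moisture_dry_basis = moisture_dry_basis,
                               monomer_masses = m)),
            class = "microfibril_stoichiometry")
}

#' @export
print.microfibril_stoichiometry <- function(x, ...) {
  cat("<microfibril_stoichiometry> per 18 glucose residues:\n")
  for (nm in names(x$exact))
    cat(sprintf("  %-9s %7.2f (about %d)\n", nm, x$exact[[nm]],
                x$rounded[[nm]]))
  invisible(x)
}

#' Equivalent fibril radius from chain count and density
#'
#' The cross-section area of an n-chain fibril is
#' `n * residue_mass / (rise * density * N_A)` (one residue per chain per
#' axial rise); the equivalent radius is `sqrt(area / pi)`. Eighteen chains
#' of anhydroglucose (162 g/mol) at a 5.19 Angstrom rise and crystal density
#' 1.6 g/cm^3 give 13.6 Angstrom.
#'
#' @param n_chains Number of chains (default 18).
#' @param residue_mass Residue mass in g/mol (default 162).
#' @param rise_per_residue Axial rise per residue in Angstrom (default 5.19,
#'   half the cellulose I-beta c-axis repeat).
#' @param density Crystal density in g/cm^3 (default 1.6).
#' @return Equivalent radius in Angstrom.
#' @export
fibril_radius_from_chains <- function(n_chains = 18, residue_mass = 162,
                                      rise_per_residue = 5.19,
                                      density = 1.6) {
  if (any(c(n_chains, residue_mass, rise_per_residue, density) <= 0))
    stop_invalid("all arguments must be > 0")
  avogadro <- 6.02214076e23
  ## g/cm^3 -> g/A^3: 1 cm^3 = 1e24 A^3
  vol_per_rise <- n_chains * residue_mass / (avogadro * density * 1e-24)
  area <- vol_per_rise / rise_per_residue
  sqrt(area / pi)
}

#' Molecular volume from molar mass and density
#'
#' `mass / (density * N_A)` converted to cubic Angstrom; water (18.02 g/mol,
#' 0.997 g/cm^3) occupies 30 Angstrom^3.
#'
#' @param mass Molar mass in g/mol.
#' @param density Density in g/cm^3.
#' @return Volume per molecule in Angstrom^3.
#' @export
molecular_volume <- function(mass, density) {
  if (any(c(mass, density) <= 0)) stop_invalid("arguments must be > 0")
  avogadro <- 6.02214076e23
  mass / (density * avogadro) * 1e24
}

#' Default component densities (g/cm^3)
#'
#' Package defaults, configurable: cellulose 1.6, hemicellulose 1.5, lignin
#' 1.35, water 1.0.
#'
#' @return Named numeric vector.
#' @export
default_densities <- function() {
  c(cellulose = 1.6, hemicellulose = 1.5, lignin = 1.35, water = 1.0)
}

#' Component volume fractions from masses and densities
#'
#' Divides each dry-component mass by its density, adds water from the
#' dry-basis moisture content, and normalises the volumes to fractions
#' summing to one.
#'
#' @param mass_comp Named numeric vector of dry-component masses (any common
#'   unit).
#' @param densities Named densities covering every component in `mass_comp`
#'   (default [default_densities()]).
#' @param moisture_dry_basis Water mass as a fraction of the total dry mass
#'   (default 0.30); the water density must be present in `densities` when
#'   positive.
#' @return Named volume fractions summing to 1 (including `water` when
#'   moisture > 0).
#' @export
volume_fractions <- function(mass_comp, densities = default_densities(),
                             moisture_dry_basis = 0.30) {
  if (is.null(names(mass_comp)) || any(!nzchar(names(mass_comp))))
    stop_invalid("`mass_comp` must be fully named")
  if (any(mass_comp < 0)) stop_invalid("masses must be >= 0")
  miss <- setdiff(names(mass_comp), names(densities))
  if (length(miss) > 0)
    stop_invalid("missing density for component(s): ",
                 paste(miss, collapse = ", "))
  vols <- mass_comp / densities[names(mass_comp)]
  if (moisture_dry_basis > 0) {
    if (!"water" %in% names(densities))
      stop_invalid("missing density for component(s): water")
    vols <- c(vols, water = unname(moisture_dry_basis * sum(mass_comp) /
                                     densities[["water"]]))
  }
  vols / sum(vols)
}

#' Split rounded residues between two- and three-fold conformers
#'
#' `n_2fold = round_half_up(count * share)`; the three-fold count is the
#' rounded total minus that, so the pair always sums to the rounded residue
#' count (12 xylose at a 58.3% two-fold share gives 7 + 5).
#'
#' @param xylose_count Residue count (>= 0, may be fractional).
#' @param twofold_share Two-fold share in `[0, 1]`.
#' @return Named integer-valued vector `c(n_2fold = , n_3fold = )`.
#' @export
conformer_allocation <- function(xylose_count, twofold_share) {
  if (xylose_count < 0) stop_invalid("`xylose_count` must be >= 0")
  if (twofold_share < 0 || twofold_share > 1)
    stop_invalid("`twofold_share` must be in [0, 1]")
  n2 <- round_half_up(xylose_count * twofold_share)
  c(n_2fold = n2, n_3fold = round_half_up(xylose_count) - n2)
}

#' Default bead radii for schematic layouts (Angstrom)
#'
#' Xylose (two- and three-fold) drawn at 3 Angstrom (volume roughly that of
#' a glucose), lignin monomers at 3, water at its effective 1.9 Angstrom
#' radius.
#'
#' @return Named numeric vector.
#' @export
default_bead_radii <- function() {
  c(xylose_2f = 3.0, xylose_3f = 3.0, arabinose = 3.0, lignin = 3.0,
    water = 1.9)
}

#' Schematic bead layout in the matrix space of a disk configuration
#'
#' Places matrix beads (xylose conformers, arabinose, lignin, water)
#' uniformly in the space outside the physical disks by rejection sampling
#' against bead-disk overlap. Counts are per fibril times the number of
#' disks; the water count defaults to the projection-adjusted 60 per fibril
#' (the larger stoichiometric count stays available in the stoichiometry
#' record) because water's linear density along the fibril axis is lower
#' than the polymer's.
#'
#' @param config A [disk_configuration].
#' @param stoich A stoichiometry record from [per_fibril_counts()].
#' @param twofold_share Xylan two-fold share for the conformer split
#'   (default 0.583).
#' @param water_per_fibril Projected water beads per fibril (default 60).
#' @param bead_radii Named radii as in [default_bead_radii()].
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per bead batch (default 2000).
#' @return An object of class `schematic_layout`: data frame `beads` with
#'   columns `species`, `x`, `y`, `radius`, plus metadata.
#' @export
schematic_layout <- function(config, stoich, twofold_share = 0.583,
                             water_per_fibril = 60,
                             bead_radii = default_bead_radii(),
                             seed = 1, max_tries = 2000) {
  stopifnot(inherits(config, "disk_configuration"),
            inherits(stoich, "microfibril_stoichiometry"))
  n_fib <- nrow(config$centers)
  conf <- conformer_allocation(stoich$exact[["xylose"]], twofold_share)
  per_fibril <- c(xylose_2f = unname(conf["n_2fold"]),
                  xylose_3f = unname(conf["n_3fold"]),
                  arabinose = unname(stoich$rounded[["arabinose"]]),
                  lignin = unname(stoich$rounded[["lignin"]]),
                  water = water_per_fibril)
  counts <- per_fibril * n_fib
  counts <- counts[counts > 0]
  L <- config$box_side
  R <- config$radius_phys
  matrix_area <- L^2 * (1 - packing_fraction(config, "phys"))
  bead_area <- sum(pi * bead_radii[names(counts)]^2 * counts)
  if (bead_area > matrix_area)
    stop_invalid("infeasible density: requested bead area ",
                 signif(bead_area, 4), " A^2 exceeds matrix area ",
                 signif(matrix_area, 4), " A^2")
  set.seed(seed)
  place <- function(n, r) {
    out <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(out) < n) {
      tries <- tries + 1
      if (tries > max_tries)
        stop_invalid("rejection sampling stalled placing beads of radius ", r)
      need <- n - nrow(out)
      pts <- cbind(runif(2 * need + 16, 0, L), runif(2 * need + 16, 0, L))
      d <- cpp_nearest_center_dist(config$centers, L, pts)
      ok <- d > R + r
      out <- rbind(out, pts[ok, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
  beads <- do.call(rbind, lapply(names(counts), function(sp) {
    xy <- place(counts[[sp]], bead_radii[[sp]])
    data.frame(species = sp, x = xy[, 1], y = xy[, 2],
               radius = bead_radii[[sp]])
  }))
  structure(list(beads = beads, per_fibril = per_fibril, seed = seed,
                 box_side = L, radius_phys = R,
                 water_stoichiometric = stoich$exact[["water"]]),
            class = "schematic_layout")
}

#' Write a schematic layout as CSV plus JSON metadata
#'
#' @param layout A [schematic_layout].
#' @param path CSV path for `(species, x, y, radius)`; metadata goes to
#'   `<path>.json`.
#' @export
write_layout <- function(layout, path) {
  write.table(layout$beads, path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(layout[c("per_fibril", "seed", "box_side",
                                "radius_phys", "water_stoichiometric")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
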