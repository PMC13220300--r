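#' Cylinder scattering model parameters
#'
#' Parameter container for the composite small-angle model
#' `I(q) = A * S(q; phi, q*R_e) * P(q; R) + B (+ c * q^-3)`, where `P` is the
#' form factor of an infinitely long cylinder of radius `R` and `S` the
#' structure factor of a two-dimensional hard-disk fluid at effective area
#' fraction `phi` with non-penetration radius `R_e`. The optional `q^-3`
#' surface term models interface scattering dominating at very low q and is
#' off (`surface_coeff = 0`) by default.
#'
#' @param radius_phys Physical cylinder radius R in Angstrom (> 0).
#' @param radius_eff Effective (non-penetration) radius R_e in Angstrom,
#'   `radius_eff >= radius_phys`.
#' @param phi_eff Effective area fraction in (0, 0.9069), the 2D
#'   close-packing bound.
#' @param scale Overall scale factor A (>= 0), intensity units.
#' @param background Flat background B, intensity units.
#' @param surface_coeff Coefficient c of the `q^-3` surface term (>= 0),
#'   intensity * Angstrom^-3.
#' @return An object of class `cylinder_model`.
#' @export
cylinder_model <- function(radius_phys, radius_eff = radius_phys,
                           phi_eff, scale = 1, background = 0,
                           surface_coeff = 0) {
  if (!is.numeric(radius_phys) || radius_phys <= 0)
    stop_invalid("`radius_phys` must be > 0")
  if (radius_eff < radius_phys)
    stop_invalid("`radius_eff` must be >= `radius_phys`")
  if (phi_eff <= 0 || phi_eff >= PHI_CLOSE_PACK)
    stop_invalid("`phi_eff` must lie in (0, ", round(PHI_CLOSE_PACK, 4),
                 "), the 2D close-packing bound")
  if (scale < 0) stop_invalid("`scale` must be >= 0")
  if (surface_coeff < 0) stop_invalid("`surface_coeff` must be >= 0")
  structure(list(radius_phys = radius_phys, radius_eff = radius_eff,
                 phi_eff = phi_eff, scale = scale, background = background,
                 surface_coeff = surface_coeff),
            class = "cylinder_model")
}

#' Form factor of an infinitely long cylinder
#'
#' `P(q; R) = (J1(qR) / (qR))^2`, with `J1` the first-order Bessel function
#' of the first kind. The removable singularity at q = 0 is handled by the
#' series `J1(x)/x = 1/2 - x^2/16 + x^4/384 - ...` for `qR < 1e-3` (relative
#' error < 1e-6), so the analytic limit `P(0) = 0.25` is returned without
#' any branching burden on callers.
#'
#' @param q Scattering vector magnitudes (Angstrom^-1), `q >= 0`.
#' @param R Cylinder radius (Angstrom), `R > 0`.
#' @return Dimensionless form factor values in `[0, 0.25]`.
#' @examples
#' cylinder_form_factor(0, 13.5)        # 0.25 (analytic limit)
#' cylinder_form_factor(0.2, 13.5)      # qR = 2.7
#' @export
cylinder_form_factor <- function(q, R) {
  if (!is.numeric(R) || length(R) != 1 || R <= 0)
    stop_invalid("`R` must be a single positive number")
  if (any(q < 0)) stop_invalid("`q` must be >= 0")
  x <- q * R
  amp <- numeric(length(x))
  small <- x < 1e-3
  amp[small] <- 0.5 - x[small]^2 / 16 + x[small]^4 / 384
  xb <- x[!small]
  amp[!small] <- besselJ(xb, 1) / xb
  amp^2
}

#' Low-q surface scattering term
#'
#' Power-law `c * q^-3` describing interface (surface) scattering, e.g. at
#' the lumen / cell-wall boundary, which dominates the smallest angles.
#'
#' @param q Scattering vector magnitudes (Angstrom^-1), strictly positive.
#' @param c Coefficient (>= 0), intensity * Angstrom^-3.
#' @return Intensities `c * q^-3`.
#' @export
surface_term <- function(q, c) {
  if (any(q <= 0)) stop_invalid("`q` must be strictly positive")
  if (!is.numeric(c) || c < 0) stop_invalid("`c` must be >= 0")
  c * q^-3
}

#' Evaluate the composite cylinder + hard-disk model
#'
#' Computes `A * S(q; phi, q*R_e) * P(q; R) + B`, adding the `c * q^-3`
#' surface term when `surface_coeff > 0`. The structure factor is supplied by
#' `sf`: a structure-factor table (see [build_structure_factor_table()]), a function `f(phi, x)` of the area
#' fraction and the dimensionless `x = q * R_e`, or `NULL` for `S == 1`
#' (dilute limit).
#'
#' @param q Scattering vector grid (Angstrom^-1).
#' @param model A [cylinder_model].
#' @param sf Structure-factor provider (table, function, or `NULL`).
#' @return Intensity vector of the same length as `q`.
#' @export
model_intensity <- function(q, model, sf = NULL) {
  stopifnot(inherits(model, "cylinder_model"))
  P <- cylinder_form_factor(q, model$radius_phys)
  S <- eval_structure_factor(sf, model$phi_eff, q * model$radius_eff)
  out <- model$scale * S * P + model$background
  if (model$surface_coeff > 0) out <- out + surface_term(q, model$surface_coeff)
  out
}

## dispatch helper: table / function / NULL
eval_structure_factor <- function(sf, phi, x) {
  if (is.null(sf)) return(rep(1, length(x)))
  if (inherits(sf, "structure_factor_table")) return(sf_evaluate(sf, phi, x))
  if (is.function(sf)) return(sf(phi, x))
  stop_invalid("`sf` must be a structure_factor_table, a function(phi, x), or NULL")
}

#' Lorentz correction for fiber geometry
#'
#' Multiplies the intensity (and sigma, if present) by q, compensating the
#' fiber-symmetric geometry before profiles are compared on a double-log
#' plot. Dividing the corrected intensity by q restores the input exactly.
#'
#' @param profile A [scattering_profile].
#' @return A [scattering_profile] with `intensity` replaced by
#'   `q * intensity` (and `sigma` scaled identically).
#' @export
lorentz_correct <- function(profile) {
  stopifnot(inherits(profile, "scattering_profile"))
  scattering_profile(profile$q, profile$q * profile$intensity,
                     sigma = if ("sigma" %in% names(profile))
                       profile$q * profile$sigma else NULL)
}
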