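#' Effective (non-penetration) radius from a sheath layer
#'
#' Microfibrils carry a soft sheath that keeps their surfaces at least
#' `min_surface_sep` apart; the equivalent hard-disk radius is
#' `R + min_surface_sep / 2`, e.g. 13.5 + 4.7/2 = 15.85 Angstrom (15.9 at one
#' decimal).
#'
#' @param R Physical radius in Angstrom (> 0).
#' @param min_surface_sep Minimum surface-to-surface separation in Angstrom
#'   (>= 0).
#' @return Effective radius in Angstrom.
#' @export
effective_radius <- function(R, min_surface_sep) {
  if (any(R <= 0)) stop_invalid("`R` must be > 0")
  if (any(min_surface_sep < 0)) stop_invalid("`min_surface_sep` must be >= 0")
  R + min_surface_sep / 2
}

#' Effective area fraction implied by a sheath
#'
#' Scales a physical area fraction to the effective one at the
#' non-penetration radius: `phi_phys * (R_e / R)^2`. A physical fraction of
#' 29% at R = 13.5 and R_e = 15.85 Angstrom gives an effective fraction of
#' 40%.
#'
#' @param phi_phys Physical area fraction in (0, 1).
#' @param R Physical radius in Angstrom.
#' @param R_e Effective radius in Angstrom, `R_e >= R`.
#' @return Effective area fraction; errors if it reaches the 2D close-packing
#'   bound 0.9069.
#' @export
effective_area_fraction <- function(phi_phys, R, R_e) {
  if (phi_phys <= 0 || phi_phys >= 1) stop_invalid("`phi_phys` must be in (0,1)")
  if (R <= 0 || R_e < R) stop_invalid("need `R_e` >= `R` > 0")
  phi <- phi_phys * (R_e / R)^2
  if (phi >= PHI_CLOSE_PACK)
    stop_invalid("infeasible packing: effective area fraction ", round(phi, 4),
                 " >= close-packing bound ", round(PHI_CLOSE_PACK, 4))
  phi
}

#' Disk configuration container
#'
#' A periodic square box of non-overlapping disk centers. `radius_eff` is the
#' non-penetration radius (every periodic-image pair distance is at least
#' `2 * radius_eff`); `radius_phys` is the physical (scattering / proximity)
#' radius, `radius_phys <= radius_eff`.
#'
#' @param centers Two-column matrix of (x, y) positions in `[0, box_side)`.
#' @param box_side Box side length in Angstrom.
#' @param radius_eff Non-penetration radius in Angstrom.
#' @param radius_phys Physical radius in Angstrom (default `radius_eff`).
#' @param metadata Optional list (seed, sweeps, ...), kept with the object.
#' @param check If `TRUE` (default) run the brute-force O(n^2) overlap check.
#' @return An object of class `disk_configuration`.
#' @export
disk_configuration <- function(centers, box_side, radius_eff,
                               radius_phys = radius_eff, metadata = list(),
                               check = TRUE) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2 || nrow(centers) < 1)
    stop_invalid("`centers` must be an n x 2 matrix with n >= 1")
  if (radius_phys > radius_eff)
    stop_invalid("`radius_phys` must be <= `radius_eff`")
  centers <- centers %% box_side
  obj <- structure(list(centers = centers, box_side = box_side,
                        radius_eff = radius_eff, radius_phys = radius_phys,
                        periodic = TRUE, metadata = metadata),
                   class = "disk_configuration")
  if (check && nrow(centers) > 1) {
    dmin <- cpp_min_pair_dist(centers, box_side)
    if (dmin < 2 * radius_eff - 1e-9)
      stop_invalid("overlapping configuration: min pair distance ", dmin,
                   " < ", 2 * radius_eff)
  }
  obj
}

#' @export
print.disk_configuration <- function(x, ...) {
  cat(sprintf(
    "<disk_configuration> %d disks, box %.4g A, R_e %.4g A, R %.4g A, phi_eff %.4f\n",
    nrow(x$centers), x$box_side, x$radius_eff, x$radius_phys,
    packing_fraction(x)))
  invisible(x)
}

#' Effective packing fraction of a configuration
#' @param config A [disk_configuration].
#' @param radius Which radius to use: `"eff"` (default) or `"phys"`.
#' @return Area fraction `n * pi * r^2 / box_side^2`.
#' @export
packing_fraction <- function(config, radius = c("eff", "phys")) {
  radius <- match.arg(radius)
  r <- if (radius == "eff") config$radius_eff else config$radius_phys
  nrow(config$centers) * pi * r^2 / config$box_side^2
}

#' Generate an equilibrated hard-disk configuration
#'
#' Builds a periodic square box with side `R_e * sqrt(n_disks * pi /
#' phi_eff)`, fills it by random sequential addition (RSA), and equilibrates
#' with Metropolis sweeps: each move picks a disk uniformly, proposes a
#' uniform displacement in `[-delta, delta]^2` and rejects on any overlap.
#' `delta` is auto-tuned to a 30-50% acceptance during equilibration. At
#' effective fractions beyond the RSA saturation regime (about 0.52) the
#' initial placement falls back to a dilute insertion plus compression
#' schedule (noted in the metadata).
#'
#' @param n_disks Number of disks (>= 1).
#' @param phi_eff Effective area fraction, `0 < phi_eff < 0.9069`.
#' @param R_e Non-penetration radius in Angstrom.
#' @param R Physical radius in Angstrom (default `R_e`).
#' @param seed Integer seed; if `NULL`, one is drawn and recorded in the
#'   metadata.
#' @param equil_sweeps Number of equilibration sweeps (default 2000).
#' @param delta Initial maximum displacement (default `0.3 * R_e`).
#' @return A [disk_configuration] with metadata recording the seed, sweeps,
#'   final step size and acceptance.
#' @export
generate_configuration <- function(n_disks, phi_eff, R_e, R = R_e,
                                   seed = NULL, equil_sweeps = 2000,
                                   delta = 0.3 * R_e) {
  if (n_disks < 1) stop_invalid("`n_disks` must be >= 1")
  if (phi_eff <= 0 || phi_eff >= PHI_CLOSE_PACK)
    stop_invalid("infeasible packing: `phi_eff` must be in (0, ",
                 round(PHI_CLOSE_PACK, 4), ")")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("generate_configuration: no seed given, drew seed ", seed)
  }
  set.seed(seed)
  L <- R_e * sqrt(n_disks * pi / phi_eff)
  init_method <- "rsa"
  centers <- cpp_rsa_pack(n_disks, L, R_e, 1e6)
  if (nrow(centers) < n_disks) {
    message("generate_configuration: RSA stalled at ", nrow(centers), "/",
            n_disks, " disks (phi_eff = ", round(phi_eff, 3),
            "); using dilute insertion + compression")
    init_method <- "rsa+compression"
    centers <- compress_pack(n_disks, L, R_e)
  }
  if (n_disks > 1 && equil_sweeps > 0) {
    res <- cpp_mc_sweeps(centers, L, R_e, equil_sweeps, delta, TRUE)
    centers <- res$centers
    delta <- res$delta
    acc <- res$acceptance
  } else acc <- NA_real_
  disk_configuration(
    centers, L, R_e, R,
    metadata = list(seed = seed, equil_sweeps = equil_sweeps,
                    init = init_method, delta = delta, acceptance = acc,
                    phi_eff_requested = phi_eff),
    check = FALSE)
}

## dilute insertion + compression fallback: RSA at a feasible fraction in a
## larger box, then alternate MC sweeps with box rescales that never create
## an overlap (a rescale by s shrinks every pair distance by s, so it is
## admissible whenever min_dist * s >= 2 R_e).
compress_pack <- function(n, L_target, R_e, phi_start = 0.45,
                          max_iter = 4000) {
  L <- R_e * sqrt(n * pi / phi_start)
  if (L < L_target) L <- L_target
  centers <- cpp_rsa_pack(n, L, R_e, 1e7)
  if (nrow(centers) < n)
    stop_invalid("dilute insertion failed even at area fraction ", phi_start)
  delta <- 0.3 * R_e
  for (it in seq_len(max_iter)) {
    if (L <= L_target * (1 + 1e-12)) break
    res <- cpp_mc_sweeps(centers, L, R_e, 5, delta, TRUE)
    centers <- res$centers
    delta <- res$delta
    dmin <- cpp_min_pair_dist(centers, L)
    s_floor <- 2 * R_e / dmin * (1 + 1e-12)
    s <- max(L_target / L, 0.995, s_floor)
    if (s < 1) {
      centers <- centers * s
      L <- L * s
    }
  }
  if (L > L_target * (1 + 1e-9))
    stop_invalid("compression schedule did not reach the target box; ",
                 "requested fraction may be infeasible")
  centers
}

#' Continue Monte Carlo sweeps on a configuration
#'
#' @param config A [disk_configuration].
#' @param n_sweeps Number of Metropolis sweeps.
#' @param seed Optional seed (set before the sweeps when given).
#' @param delta Maximum displacement; defaults to the stored value.
#' @param tune Auto-tune `delta` (default `FALSE` for production sampling).
#' @return The updated [disk_configuration].
#' @export
mc_sweeps <- function(config, n_sweeps, seed = NULL, delta = NULL,
                      tune = FALSE) {
  stopifnot(inherits(config, "disk_configuration"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(delta)) delta <- config$metadata$delta %||% (0.3 * config$radius_eff)
  res <- cpp_mc_sweeps(config$centers, config$box_side, config$radius_eff,
                       n_sweeps, delta, tune)
  config$centers <- res$centers
  config$metadata$delta <- res$delta
  config$metadata$acceptance <- res$acceptance
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## snapshot sampler shared by the RDF and direct-summation routes:
## n_samples configurations separated by sweeps_between sweeps each.
sample_snapshots <- function(config, n_samples, sweeps_between = 10,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  delta <- config$metadata$delta %||% (0.3 * config$radius_eff)
  snaps <- vector("list", n_samples)
  centers <- config$centers
  for (k in seq_len(n_samples)) {
    res <- cpp_mc_sweeps(centers, config$box_side, config$radius_eff,
                         sweeps_between, delta, FALSE)
    centers <- res$centers
    snaps[[k]] <- centers
  }
  snaps
}

#' Radial distribution function of a hard-disk fluid
#'
#' Estimates g(r) from `n_samples` decorrelated Monte Carlo snapshots (every
#' `sweeps_between` >= 10 sweeps) of the given configuration. Pair distances
#' use the minimum-image convention; the histogram is normalised by the
#' finite-N ideal-gas expectation `N(N-1)/2 * annulus_area / box^2`, so an
#' uncorrelated (Poisson) control gives g = 1 in every bin.
#'
#' @param config A [disk_configuration].
#' @param bin_width Histogram bin width in Angstrom.
#' @param r_max Maximum distance, at most `box_side / 2` (minimum image).
#' @param n_samples Number of snapshots (default 100).
#' @param sweeps_between Sweeps between snapshots (default 10).
#' @param seed Optional seed for the sampling chain.
#' @return An object of class `radial_distribution`: list with `r_centers`,
#'   `g`, `g_se` (standard error over snapshots), `density` (disks per
#'   Angstrom^2), and the sampling metadata.
#' @export
radial_distribution <- function(config, bin_width, r_max,
                                n_samples = 100, sweeps_between = 10,
                                seed = NULL) {
  stopifnot(inherits(config, "disk_configuration"))
  L <- config$box_side
  if (r_max > L / 2 + 1e-12)
    stop_invalid("`r_max` must be <= box_side/2 (minimum-image validity); got ",
                 r_max, " > ", L / 2)
  if (sweeps_between < 10)
    stop_invalid("snapshots must be separated by at least 10 sweeps")
  n <- nrow(config$centers)
  nbins <- ceiling(r_max / bin_width)
  r_max <- nbins * bin_width
  snaps <- sample_snapshots(config, n_samples, sweeps_between, seed)
  edges <- seq(0, r_max, by = bin_width)
  area <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  ideal <- n * (n - 1) / 2 * area / L^2
  gmat <- vapply(snaps, function(cen)
    cpp_pair_histogram(cen, L, r_max, nbins) / ideal, numeric(nbins))
  g <- rowMeans(gmat)
  g_se <- apply(gmat, 1, sd) / sqrt(n_samples)
  structure(list(r_centers = edges[-1] - bin_width / 2, g = g, g_se = g_se,
                 density = n / L^2, bin_width = bin_width,
                 radius_eff = config$radius_eff, box_side = L,
                 n_samples = n_samples, sweeps_between = sweeps_between),
            class = "radial_distribution")
}

#' Structure factor from a radial distribution function
#'
#' Two-dimensional liquid-state transform
#' `S(q) = 1 + 2 pi rho * integral_0^rmax (g(r) - 1) J0(q r) r dr`,
#' with a cosine taper over the last 20% of r to suppress truncation
#' ringing. Values at q below `2 pi / box_side` are unreliable (the box does
#' not support such wavelengths) and are flagged via the `reliable`
#' attribute.
#'
#' @param rdf A [radial_distribution].
#' @param q_grid Scattering vector magnitudes (Angstrom^-1).
#' @return Numeric vector S(q) with attributes `reliable` (logical) and
#'   `se` (propagated standard error).
#' @export
structure_factor_from_rdf <- function(rdf, q_grid) {
  stopifnot(inherits(rdf, "radial_distribution"))
  r <- rdf$r_centers
  dr <- rdf$bin_width
  rmax <- max(r) + dr / 2
  w <- ifelse(r < 0.8 * rmax, 1,
              0.5 * (1 + cos(pi * (r - 0.8 * rmax) / (0.2 * rmax))))
  h <- (rdf$g - 1) * w * r * dr
  he <- rdf$g_se * w * r * dr
  rho <- rdf$density
  S <- vapply(q_grid, function(q) 1 + 2 * pi * rho * sum(h * besselJ(q * r, 0)),
              numeric(1))
  se <- vapply(q_grid, function(q)
    2 * pi * rho * sqrt(sum((he * besselJ(q * r, 0))^2)), numeric(1))
  attr(S, "se") <- se
  attr(S, "reliable") <- q_grid >= 2 * pi / rdf$box_side
  S
}

#' Structure factor by direct summation (independent route)
#'
#' Computes `S(q) = <|sum_j exp(i q . r_j)|^2> / N` over the
#' lattice-compatible wave vectors `q = (2 pi / box)(nx, ny)` with
#' `0 < nx^2 + ny^2 <= m_max`, shell-averaged over equal `|q|`. This is a
#' second, transform-free estimator used to cross-check
#' [structure_factor_from_rdf()].
#'
#' @param config A [disk_configuration].
#' @param m_max Maximum squared integer wave index.
#' @param n_samples,sweeps_between,seed Snapshot sampling as in
#'   [radial_distribution()].
#' @return Data frame with columns `q`, `S`, `se` (standard error over
#'   snapshots after shell averaging).
#' @export
direct_structure_factor <- function(config, m_max = 200, n_samples = 100,
                                    sweeps_between = 10, seed = NULL) {
  stopifnot(inherits(config, "disk_configuration"))
  L <- config$box_side
  mm <- floor(sqrt(m_max))
  grid <- expand.grid(nx = 0:mm, ny = -mm:mm)
  grid <- grid[grid$nx^2 + grid$ny^2 > 0 &
               grid$nx^2 + grid$ny^2 <= m_max &
               !(grid$nx == 0 & grid$ny < 0), ]   # one of each +/- pair
  nvec <- as.matrix(grid)
  storage.mode(nvec) <- "integer"
  m2 <- grid$nx^2 + grid$ny^2
  snaps <- sample_snapshots(config, n_samples, sweeps_between, seed)
  smat <- vapply(snaps, function(cen) {
    sv <- cpp_direct_sf(cen, L, nvec)
    tapply(sv, m2, mean)                          # shell average per snapshot
  }, numeric(length(unique(m2))))
  q <- 2 * pi / L * sqrt(sort(unique(m2)))
  data.frame(q = q,
             S = rowMeans(smat),
             se = apply(smat, 1, sd) / sqrt(n_samples))
}

#' Tabulated structure factor on a (phi, qR_e) grid
#'
#' Runs one Monte Carlo simulation per area fraction and stores
#' `S[phi, x]` on the dimensionless grid `x = q * R_e` (simulated at unit
#' effective radius, so the table applies to any R_e). Queries are
#' interpolated with separable cubic splines (C1-smooth); grid nodes
#' reproduce the stored values exactly and queries outside the grid raise an
#' out-of-range error rather than extrapolating. The row at phi = 0 is
#' identically 1.
#'
#' @param phi_grid Area fractions in `[0, 0.55]`, increasing.
#' @param x_grid Dimensionless `q * R_e` values in `[0.2, 20]`, increasing.
#' @param n_disks Disks per simulation (default 2000).
#' @param equil_sweeps Equilibration sweeps (default 2000).
#' @param n_samples,sweeps_between Snapshot sampling for g(r).
#' @param bin_width RDF bin width in units of R_e (default 0.02).
#' @param seed Integer seed; per-phi simulations use `seed + i`.
#' @return An object of class `structure_factor_table`.
#' @export
build_structure_factor_table <- function(phi_grid, x_grid,
                                         n_disks = 2000, equil_sweeps = 2000,
                                         n_samples = 100, sweeps_between = 10,
                                         bin_width = 0.02, seed = 1) {
  if (any(phi_grid < 0) || any(phi_grid > 0.55))
    stop_invalid("`phi_grid` must lie within [0, 0.55]")
  if (any(x_grid < 0.2) || any(x_grid > 20))
    stop_invalid("`x_grid` must lie within [0.2, 20]")
  if (is.unsorted(phi_grid, strictly = TRUE) ||
      is.unsorted(x_grid, strictly = TRUE))
    stop_invalid("grids must be strictly increasing")
  S <- matrix(NA_real_, length(phi_grid), length(x_grid))
  for (i in seq_along(phi_grid)) {
    phi <- phi_grid[i]
    if (phi == 0) { S[i, ] <- 1; next }
    cfg <- generate_configuration(n_disks, phi, R_e = 1, seed = seed + i,
                                  equil_sweeps = equil_sweeps)
    q_lo <- 2 * pi / cfg$box_side
    if (min(x_grid) < q_lo)
      stop_invalid("x = ", min(x_grid), " below reliable bound 2*pi/box = ",
                   signif(q_lo, 3), " at phi = ", phi,
                   "; increase n_disks")
    rdf <- radial_distribution(cfg, bin_width, cfg$box_side / 2,
                               n_samples, sweeps_between, seed = seed + 1000 + i)
    S[i, ] <- as.numeric(structure_factor_from_rdf(rdf, x_grid))
  }
  structure(list(phi_grid = phi_grid, x_grid = x_grid, S_values = S,
                 metadata = list(n_disks = n_disks,
                                 equil_sweeps = equil_sweeps,
                                 n_samples = n_samples,
                                 sweeps_between = sweeps_between,
                                 bin_width = bin_width, seed = seed)),
            class = "structure_factor_table")
}

#' Evaluate a tabulated structure factor
#'
#' @param table A structure-factor table (see [build_structure_factor_table()]) (from
#'   [build_structure_factor_table()] or [read_sf_table()]).
#' @param phi Area fraction (scalar).
#' @param x Dimensionless `q * R_e` values.
#' @return S values at `(phi, x)`.
#' @export
sf_evaluate <- function(table, phi, x) {
  stopifnot(inherits(table, "structure_factor_table"))
  pg <- table$phi_grid; xg <- table$x_grid
  if (phi < min(pg) - 1e-12 || phi > max(pg) + 1e-12)
    stop_invalid("phi = ", phi, " outside table range [", min(pg), ", ",
                 max(pg), "]")
  if (any(x < min(xg) - 1e-12) || any(x > max(xg) + 1e-12))
    stop_invalid("q*R_e outside table range [", min(xg), ", ", max(xg),
                 "]: got [", signif(min(x), 4), ", ", signif(max(x), 4), "]")
  ## separable cubic splines: along x within each phi row, then across phi
  at_phi <- vapply(seq_along(pg), function(i)
    splinefun(xg, table$S_values[i, ], method = "fmm")(x),
    numeric(length(x)))
  if (length(pg) == 1) return(as.numeric(at_phi))
  at_phi <- matrix(at_phi, nrow = length(x))
  vapply(seq_along(x), function(j)
    splinefun(pg, at_phi[j, ], method = "fmm")(phi), numeric(1))
}

#' Matrix-proximity shell fractions
#'
#' Lays a square lattice of spacing `grid_spacing` over the periodic box; a
#' lattice point is "matrix" when its distance to the nearest disk center
#' exceeds the physical radius `R`. For each threshold `d` the function
#' returns the fraction of matrix points whose distance to the nearest disk
#' surface is at most `d`.
#'
#' @param config A [disk_configuration].
#' @param R Physical disk radius in Angstrom (default the configuration's).
#' @param distances Positive shell distances in Angstrom.
#' @param grid_spacing Lattice spacing in Angstrom, at most 1 (default 1).
#' @return An object of class `proximity_result`: list with
#'   `shell_distances`, `matrix_fraction_within`, `grid_spacing`,
#'   `phi_phys`, and point counts.
#' @export
proximity_fractions <- function(config, R = config$radius_phys, distances,
                                grid_spacing = 1) {
  stopifnot(inherits(config, "disk_configuration"))
  if (grid_spacing > 1) stop_invalid("`grid_spacing` must be <= 1 Angstrom")
  if (any(distances <= 0)) stop_invalid("`distances` must be positive")
  res <- cpp_proximity_counts(config$centers, config$box_side, R,
                              grid_spacing, as.numeric(distances))
  if (res$n_matrix == 0)
    stop_invalid("degenerate input: no matrix lattice points (phi_phys -> 1)")
  structure(list(shell_distances = as.numeric(distances),
                 matrix_fraction_within = as.numeric(res$within) / res$n_matrix,
                 grid_spacing = res$spacing_used,
                 phi_phys = 1 - res$n_matrix / res$n_total,
                 n_matrix_points = res$n_matrix,
                 n_total_points = res$n_total),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat("<proximity_result> phi_phys =", round(x$phi_phys, 4), "\n")
  for (i in seq_along(x$shell_distances))
    cat(sprintf("  within %5.2f A of surface: %5.1f%%\n",
                x$shell_distances[i], 100 * x$matrix_fraction_within[i]))
  invisible(x)
}

#' Write / read a disk configuration as CSV + JSON sidecar
#'
#' @param config A [disk_configuration].
#' @param path CSV path for (x, y); metadata goes to `<path>.json`.
#' @export
write_configuration <- function(config, path) {
  write.table(data.frame(x = config$centers[, 1], y = config$centers[, 2]),
              path, sep = ",", row.names = FALSE, quote = FALSE)
  meta <- c(list(box_side = config$box_side, radius_eff = config$radius_eff,
                 radius_phys = config$radius_phys,
                 phi_eff = packing_fraction(config)),
            config$metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_configuration
#' @export
read_configuration <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  disk_configuration(as.matrix(df), meta$box_side, meta$radius_eff,
                     meta$radius_phys, metadata = meta, check = FALSE)
}

#' Write / read a structure-factor table as a JSON bundle
#'
#' @param table A structure-factor table (see [build_structure_factor_table()]).
#' @param path Output JSON path.
#' @export
write_sf_table <- function(table, path) {
  jsonlite::write_json(list(phi_grid = table$phi_grid, x_grid = table$x_grid,
                            S_values = table$S_values,
                            metadata = table$metadata),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sf_table
#' @export
read_sf_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- obj$S_values
  if (!is.matrix(S))
    S <- matrix(unlist(S), nrow = length(obj$phi_grid), byrow = TRUE)
  structure(list(phi_grid = obj$phi_grid, x_grid = obj$x_grid,
                 S_values = S, metadata = obj$metadata),
            class = "structure_factor_table")
}
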