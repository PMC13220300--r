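test_that("effective radius and area fraction follow the sheath geometry", {
  expect_equal(effective_radius(13.5, 4.7), 15.85)
  expect_equal(round_half_up(effective_radius(13.5, 4.7), 1), 15.9)
  expect_equal(effective_radius(10, 0), 10)
  expect_equal(effective_radius(10, 4), 12)
  expect_error(effective_radius(13.5, -1))

  expect_equal(effective_area_fraction(0.29, 13.5, 15.85), 0.3997505,
               tolerance = 1e-6)
  expect_equal(effective_area_fraction(0.3, 10, 10), 0.3)
  expect_equal(effective_area_fraction(0.1, 10, 20), 4 * 0.1)
  expect_error(effective_area_fraction(0.5, 10, 20), "infeasible")
})

test_that("generated configurations never contain overlaps", {
  # single disk
  c1 <- generate_configuration(1, 0.3, R_e = 10, seed = 1)
  expect_equal(nrow(c1$centers), 1)
  # dilute and dense cases, brute-force O(n^2) oracle in plain R
  for (phi in c(0.05, 0.40)) {
    cfg <- generate_configuration(300, phi, R_e = 15.85, R = 13.5,
                                  seed = 5, equil_sweeps = 300)
    expect_gte(r_min_pair_dist(cfg$centers, cfg$box_side),
               2 * 15.85 - 1e-9)
    # effective packing fraction matches the request to within one disk
    expect_equal(packing_fraction(cfg), phi,
                 tolerance = pi * 15.85^2 / cfg$box_side^2 + 1e-9)
  }
})

test_that("configurations are deterministic for a fixed seed", {
  a <- generate_configuration(200, 0.40, R_e = 1, seed = 123,
                              equil_sweeps = 200)
  b <- generate_configuration(200, 0.40, R_e = 1, seed = 123,
                              equil_sweeps = 200)
  expect_identical(a$centers, b$centers)
  d <- generate_configuration(200, 0.40, R_e = 1, seed = 124,
                              equil_sweeps = 200)
  expect_false(identical(a$centers, d$centers))
})

test_that("sweeps conserve disk count and non-penetration", {
  cfg <- generate_configuration(250, 0.45, R_e = 2, seed = 7,
                                equil_sweeps = 100)
  n0 <- nrow(cfg$centers)
  for (k in 1:3) {
    cfg <- mc_sweeps(cfg, 50, seed = 100 + k)
    expect_equal(nrow(cfg$centers), n0)
    expect_gte(r_min_pair_dist(cfg$centers, cfg$box_side), 2 * 2 - 1e-9)
  }
})

test_that("compression fallback reaches fractions beyond RSA saturation", {
  cfg <- generate_configuration(120, 0.56, R_e = 1, seed = 11,
                                equil_sweeps = 150)
  expect_equal(packing_fraction(cfg), 0.56,
               tolerance = pi / cfg$box_side^2 + 1e-9)
  expect_gte(r_min_pair_dist(cfg$centers, cfg$box_side), 2 - 1e-9)
  expect_match(cfg$metadata$init, "compression")
})

test_that("g(r) is zero inside contact and near one for an ideal gas", {
  # near-ideal control: tiny non-penetration radius
  set.seed(42)
  L <- 100
  ideal <- disk_configuration(cbind(runif(600, 0, L), runif(600, 0, L)),
                              L, radius_eff = 1e-6,
                              metadata = list(delta = 10), check = FALSE)
  rdf0 <- radial_distribution(ideal, bin_width = 2, r_max = 50,
                              n_samples = 40, seed = 3)
  z <- abs(rdf0$g - 1) / pmax(rdf0$g_se, 1e-12)
  expect_true(all(z[rdf0$r_centers > 5] < 5))

  cfg <- generate_configuration(300, 0.40, R_e = 1, seed = 9,
                                equil_sweeps = 300)
  rdf <- radial_distribution(cfg, 0.05, cfg$box_side / 2, n_samples = 40,
                             seed = 4)
  expect_true(all(rdf$g[rdf$r_centers < 2] == 0))
  # contact peak above 1 with decaying oscillations toward 1
  expect_gt(max(rdf$g[rdf$r_centers > 2 & rdf$r_centers < 2.2]), 1)
  outer <- rdf$r_centers > 0.9 * max(rdf$r_centers)
  expect_lt(max(abs(rdf$g[outer] - 1)), 0.1)
  expect_error(radial_distribution(cfg, 0.05, cfg$box_side, n_samples = 5),
               "box_side/2")
})

test_that("structure factor transform has the right limits", {
  # g == 1 gives S == 1 exactly
  flat <- structure(list(r_centers = seq(0.025, 25, by = 0.05),
                         g = rep(1, 500), g_se = rep(0, 500),
                         density = 0.1, bin_width = 0.05, radius_eff = 1,
                         box_side = 60, n_samples = 1, sweeps_between = 10),
                    class = "radial_distribution")
  S <- structure_factor_from_rdf(flat, c(0.3, 1, 5))
  expect_equal(as.numeric(S), c(1, 1, 1))

  # dilute limit: |S - 1| bounded by the excluded-area virial term
  cfg <- generate_configuration(400, 0.01, R_e = 1, seed = 21,
                                equil_sweeps = 200)
  rdf <- radial_distribution(cfg, 0.1, cfg$box_side / 2, n_samples = 30,
                             seed = 22)
  q <- seq(0.3, 8, length.out = 40)
  Sd <- as.numeric(structure_factor_from_rdf(rdf, q))
  expect_lt(max(abs(Sd - 1)), 8 * 0.01 + 0.05)
})

test_that("rdf-route and direct-summation structure factors agree", {
  cfg <- generate_configuration(300, 0.35, R_e = 1, seed = 31,
                                equil_sweeps = 300)
  rdf <- radial_distribution(cfg, 0.02, cfg$box_side / 2, n_samples = 40,
                             seed = 33)
  ds <- direct_structure_factor(cfg, m_max = 120, n_samples = 40, seed = 33)
  Sr <- structure_factor_from_rdf(rdf, ds$q)
  keep <- ds$q > 2 * pi / cfg$box_side * 2
  z <- abs(as.numeric(Sr) - ds$S) / sqrt(attr(Sr, "se")^2 + ds$se^2)
  expect_true(all(z[keep] < 4))
})

test_that("structure-factor tables interpolate and guard their domain", {
  tab <- build_structure_factor_table(
    c(0, 0.2, 0.4), seq(0.6, 10, length.out = 24),
    n_disks = 300, equil_sweeps = 200, n_samples = 30, seed = 17)
  # phi = 0 row identically one
  expect_equal(unname(tab$S_values[1, ]), rep(1, 24))
  expect_true(all(tab$S_values > 0))
  # S -> 1 at large x for every tabulated phi (loose bound at this reduced
  # disk count; the full-size 2% contract is exercised in the acceptance
  # suite)
  expect_true(all(abs(tab$S_values[, 24] - 1) < 0.05))
  # node round-trip is exact
  for (i in 1:3) {
    expect_equal(sf_evaluate(tab, tab$phi_grid[i], tab$x_grid),
                 unname(tab$S_values[i, ]), tolerance = 1e-12)
  }
  # mid-cell query against a fresh simulation at that phi
  phi_mid <- 0.3
  cfg <- generate_configuration(300, phi_mid, R_e = 1, seed = 61,
                                equil_sweeps = 300)
  rdf <- radial_distribution(cfg, 0.02, cfg$box_side / 2, n_samples = 40,
                             seed = 62)
  xq <- c(1.5, 3, 6)
  fresh <- structure_factor_from_rdf(rdf, xq)
  interp <- sf_evaluate(tab, phi_mid, xq)
  expect_true(all(abs(interp - as.numeric(fresh)) <
                    pmax(3 * attr(fresh, "se"), 0.08)))
  # out-of-range queries name the bound
  expect_error(sf_evaluate(tab, 0.5, 5), "phi")
  expect_error(sf_evaluate(tab, 0.3, 15), "range")
  expect_error(build_structure_factor_table(c(0, 0.6), c(1, 2)), "0.55")
  # JSON round trip
  f <- tempfile(fileext = ".json")
  write_sf_table(tab, f)
  tab2 <- read_sf_table(f)
  expect_equal(tab2$S_values, tab$S_values, tolerance = 1e-12)
  expect_equal(sf_evaluate(tab2, 0.3, xq), interp, tolerance = 1e-12)
  unlink(f)
})

test_that("proximity fractions behave like shell statistics", {
  cfg <- small_paper_config(n = 400, seed = 99)
  pr <- proximity_fractions(cfg, distances = c(2, 4, 6, 8, 10, 14),
                            grid_spacing = 1)
  # monotone non-decreasing in distance; consistent with phi_phys
  expect_true(all(diff(pr$matrix_fraction_within) >= 0))
  expect_equal(pr$phi_phys, 0.29, tolerance = 0.01)
  # approaches 1 at large distance
  pr_far <- proximity_fractions(cfg, distances = cfg$box_side / 5,
                                grid_spacing = 1)
  expect_gt(pr_far$matrix_fraction_within, 0.999)
  # invariant (within MC noise) under doubling the disk count
  cfg2 <- small_paper_config(n = 800, seed = 101)
  pr2 <- proximity_fractions(cfg2, distances = c(6, 10), grid_spacing = 1)
  expect_equal(pr2$matrix_fraction_within,
               pr$matrix_fraction_within[c(3, 5)], tolerance = 0.03)
  # grid-spacing convergence: 0.5 A agrees with 1 A
  pr_h <- proximity_fractions(cfg, distances = c(6, 10), grid_spacing = 0.5)
  expect_equal(pr_h$matrix_fraction_within,
               pr$matrix_fraction_within[c(3, 5)], tolerance = 0.01)
  expect_error(proximity_fractions(cfg, distances = c(6), grid_spacing = 2),
               "spacing")
  expect_error(proximity_fractions(cfg, distances = -1), "positive")
})

test_that("dilute proximity matches the independent-shell formula", {
  cfg <- generate_configuration(60, 0.02, R_e = 13.5, R = 13.5, seed = 71,
                                equil_sweeps = 200)
  rho <- nrow(cfg$centers) / cfg$box_side^2
  phi_p <- packing_fraction(cfg, "phys")
  for (d in c(5, 10)) {
    expected <- rho * pi * ((13.5 + d)^2 - 13.5^2) / (1 - phi_p)
    pr <- proximity_fractions(cfg, distances = d, grid_spacing = 1)
    expect_equal(pr$matrix_fraction_within, expected, tolerance = 0.05)
  }
})

test_that("configuration CSV round trip preserves geometry", {
  cfg <- small_paper_config(n = 50, seed = 13)
  f <- tempfile(fileext = ".csv")
  write_configuration(cfg, f)
  cfg2 <- read_configuration(f)
  expect_equal(cfg2$centers, cfg$centers, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(cfg2$box_side, cfg$box_side)
  expect_equal(cfg2$radius_eff, cfg$radius_eff)
  unlink(c(f, paste0(f, ".json")))
})
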