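#' Truth record for a synthetic dataset
#'
#' Every generator returns its full parameterisation alongside the data, so
#' that regeneration from the record is bit-identical and downstream
#' round-trip tests know the ground truth.
#'
#' @param generator Generator name.
#' @param params Named list of ground-truth parameters.
#' @param seed Integer seed used.
#' @param noise Named list describing the noise model and level.
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(generator, params, seed, noise) {
  structure(list(generator = generator, params = params, seed = seed,
                 noise = noise),
            class = "truth_record")
}

#' Synthetic SAXS profile from the cylinder + hard-disk model
#'
#' Evaluates [model_intensity()] on the grid (including the surface term
#' when the model carries one) and applies multiplicative lognormal noise
#' (`exp(rnorm(0, noise_frac))`), matching the roughly constant relative
#' error of counting data viewed on a double-log plot.
#'
#' @param model A [cylinder_model] (ground truth).
#' @param sf_table Structure-factor provider for [model_intensity()].
#' @param q_grid Scattering-vector grid (Angstrom^-1).
#' @param noise_frac Lognormal sigma (0 = noise free).
#' @param seed Integer seed.
#' @return List with elements `profile` ([scattering_profile]) and `truth`
#'   ([truth_record]).
#' @export
gen_saxs_profile <- function(model, sf_table, q_grid, noise_frac = 0,
                             seed = 1) {
  set.seed(seed)
  itrue <- model_intensity(q_grid, model, sf_table)
  fac <- if (noise_frac > 0) exp(rnorm(length(q_grid), 0, noise_frac)) else 1
  list(profile = scattering_profile(q_grid, itrue * fac),
       truth = truth_record("gen_saxs_profile",
                            params = unclass(model), seed = seed,
                            noise = list(model = "lognormal",
                                         sigma = noise_frac)))
}

#' Default wide-angle preset: cellulose equatorial doublet
#'
#' The 110/1-10 composite near 1.10 Angstrom^-1 and the 200 reflection at
#' `2 pi / 4.05` Angstrom^-1 with a width giving a Scherrer size of 31.6
#' Angstrom at K = 0.90.
#'
#' @return List of two [diffraction_peak]s.
#' @export
waxs_preset_peaks <- function() {
  list(diffraction_peak(center = 1.10, fwhm = 0.25, eta = 0.5,
                        amplitude = 0.6),
       diffraction_peak(center = 2 * pi / 4.05,
                        fwhm = 2 * pi * 0.90 / 31.6, eta = 0.5,
                        amplitude = 1.0))
}

#' Synthetic WAXS equatorial profile
#'
#' Sum of pseudo-Voigt peaks on a linear background plus additive Gaussian
#' noise.
#'
#' @param peaks List of [diffraction_peak]s (default [waxs_preset_peaks()]).
#' @param background `c(intercept, slope)` (default `c(0.05, 0)`).
#' @param noise_sd Additive Gaussian sigma (0 = noise free).
#' @param seed Integer seed.
#' @param q_grid Grid (default `seq(0.8, 2.0, by = 0.002)` Angstrom^-1).
#' @return List with `profile` and `truth`.
#' @export
gen_waxs_profile <- function(peaks = waxs_preset_peaks(),
                             background = c(0.05, 0), noise_sd = 0,
                             seed = 1, q_grid = seq(0.8, 2.0, by = 0.002)) {
  set.seed(seed)
  y <- background[1] + background[2] * q_grid
  for (pk in peaks) y <- y + pseudo_voigt(q_grid, pk)
  if (noise_sd > 0) y <- y + rnorm(length(q_grid), 0, noise_sd)
  list(profile = scattering_profile(q_grid, pmax(y, 0)),
       truth = truth_record("gen_waxs_profile",
                            params = list(peaks = lapply(peaks, unclass),
                                          background = background),
                            seed = seed,
                            noise = list(model = "gaussian", sd = noise_sd)))
}

## wheat-like line list: Gaussian lines (area, center, sd in ppm), each
## center at least 4 sd from every region boundary it must respect, so
## region integrals equal the nominal areas to well under 0.5% absolute.
wheat_like_lines <- function() {
  data.frame(
    area   = c(2.0,
               3.0, 3.0, 2.5, 2.0, 1.5,
               7.0, 5.0,
               3.8, 6.2,
               16, 14, 13, 11,
               4.0,
               2.0, 2.0,
               2.0) / 100,
    center = c(172.5,
               115.5, 122, 130, 148, 153.5,
               102.5, 105.5,
               88.3, 83.3,
               62.5, 65.5, 72, 75.5,
               54.3,
               30, 33,
               21),
    sd     = c(0.9,
               1.2, 1.2, 1.2, 1.2, 0.8,
               0.6, 0.7,
               0.55, 0.55,
               0.6, 0.7, 0.9, 0.9,
               0.6,
               0.9, 0.9,
               0.8))
}

#' Synthetic quantitative 1D carbon spectrum
#'
#' The `wheat_like` preset is a mixture of Gaussian lines (widths 1-3 ppm
#' FWHM) whose region integrals reproduce, before noise, the fractions of a
#' quantitative lignocellulose spectrum: aromatic 12%, sugar 76%, methoxy
#' 4%, acetyl carbonyl 2% and methyl 2%, anomeric C1 12%, two-fold C4 band
#' 10% with an interior/surface split of 38/62. Lines sit at least four
#' standard deviations inside their region boundaries, so cross-boundary
#' spill is below 0.01%.
#'
#' @param preset `"wheat_like"` or `"custom"` (then supply `lines`).
#' @param lines Data frame with columns `area`, `center`, `sd` (custom
#'   preset).
#' @param noise_sd Additive Gaussian sigma on the intensity (0 = noise
#'   free).
#' @param seed Integer seed.
#' @param ppm_grid Axis (default `seq(0, 200, by = 0.05)`).
#' @return List with `spectrum` ([spectrum1d]) and `truth`; the truth
#'   parameters include the nominal region fractions for the wheat preset.
#' @export
gen_spectrum1d <- function(preset = c("wheat_like", "custom"), lines = NULL,
                           noise_sd = 0, seed = 1,
                           ppm_grid = seq(0, 200, by = 0.05)) {
  preset <- match.arg(preset)
  if (preset == "wheat_like") lines <- wheat_like_lines()
  if (is.null(lines)) stop_invalid("custom preset requires `lines`")
  if (sum(lines$area) > 1 + 1e-9)
    stop_invalid("preset line areas must sum to at most 1")
  set.seed(seed)
  y <- numeric(length(ppm_grid))
  for (k in seq_len(nrow(lines)))
    y <- y + lines$area[k] * dnorm(ppm_grid, lines$center[k], lines$sd[k])
  if (noise_sd > 0) y <- y + rnorm(length(ppm_grid), 0, noise_sd)
  fractions <- if (preset == "wheat_like")
    c(aromatic = 0.12, sugar = 0.76, methoxy = 0.04, acetyl_co = 0.02,
      acetyl_ch3 = 0.02, c1 = 0.12, c4_twofold = 0.10,
      c4_interior = 0.038, c4_surface = 0.062) else NULL
  list(spectrum = spectrum1d(ppm_grid, y),
       truth = truth_record("gen_spectrum1d",
                            params = list(preset = preset, lines = lines,
                                          fractions = fractions),
                            seed = seed,
                            noise = list(model = "gaussian", sd = noise_sd)))
}

## default site chemical shifts for cross-peak table synthesis (ppm)
default_site_shifts <- function() {
  c(i4 = 88.8, s4 = 84.3, i6 = 65.2, s6 = 62.4, i1 = 105.3, s1 = 105.3,
    i3 = 74.8, s3 = 74.8,
    `2fXn4` = 82.3, `3fXn4` = 77.4, Xn1 = 102.2, Xn5 = 63.5,
    S3 = 152.6, S1 = 134.5, G3 = 148.0, G4 = 145.5, H4 = 157.8,
    FA2 = 111.0, OMe = 55.8, AcMe = 20.9, AcCO = 172.9)
}

#' Synthetic cross-peak table with known intensity classes
#'
#' Samples one relative intensity per requested cross-peak uniformly inside
#' its class band — strong (4.05, 8)%, medium (2.05, 3.95)%, weak
#' (0.2, 1.95)% — keeping a 0.05 margin off the 2% / 4% class boundaries so
#' [classify_cross_peaks()] recovers the truth unambiguously.
#'
#' @param truth Data frame with columns `source`, `sink`, `class`
#'   (`strong`/`medium`/`weak`).
#' @param seed Integer seed.
#' @return List with `table` (data frame: `source`, `sink`, `f1_ppm`,
#'   `f2_ppm`, `rel_intensity_pct`) and `truth` ([truth_record]).
#' @export
gen_crosspeak_table <- function(truth, seed = 1) {
  if (nrow(truth) == 0) {
    tab <- data.frame(source = character(), sink = character(),
                      f1_ppm = numeric(), f2_ppm = numeric(),
                      rel_intensity_pct = numeric())
    return(list(table = tab,
                truth = truth_record("gen_crosspeak_table",
                                     params = list(classes = truth),
                                     seed = seed, noise = list())))
  }
  cls <- as.character(truth$class)
  if (!all(cls %in% c("strong", "medium", "weak")))
    stop_invalid("`class` must be strong/medium/weak")
  set.seed(seed)
  lo <- c(strong = 4.05, medium = 2.05, weak = 0.20)[cls]
  hi <- c(strong = 8.00, medium = 3.95, weak = 1.95)[cls]
  shifts <- default_site_shifts()
  ppm_of <- function(lab) ifelse(lab %in% names(shifts),
                                 shifts[lab], 100)
  tab <- data.frame(source = truth$source, sink = truth$sink,
                    f1_ppm = unname(ppm_of(as.character(truth$source))),
                    f2_ppm = unname(ppm_of(as.character(truth$sink))),
                    rel_intensity_pct = runif(nrow(truth), lo, hi))
  list(table = tab,
       truth = truth_record("gen_crosspeak_table",
                            params = list(classes = truth), seed = seed,
                            noise = list(model = "uniform-in-band",
                                         margin = 0.05)))
}
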