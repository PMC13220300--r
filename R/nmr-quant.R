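#' One-dimensional NMR spectrum container
#'
#' @param ppm Chemical-shift axis, strictly monotonic (either direction).
#' @param intensity Intensities, same length as `ppm`.
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop_invalid("`ppm` and `intensity` must have the same length")
  d <- diff(ppm)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop_invalid("`ppm` must be strictly monotonic")
  structure(list(ppm = ppm, intensity = intensity), class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %d points, %.4g to %.4g ppm\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Named integration regions for spectral quantitation
#'
#' @param regions Named list of `c(lo, hi)` ppm pairs (lo < hi).
#' @param reference `c(lo, hi)` normalisation region; must cover every named
#'   region (default `c(0, 200)`, the full quantitative carbon range).
#' @return An object of class `region_set`.
#' @export
region_set <- function(regions, reference = c(0, 200)) {
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop_invalid("`regions` must be a fully named list")
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (length(r) != 2 || r[1] >= r[2])
      stop_invalid("region '", nm, "' must be c(lo, hi) with lo < hi")
    if (r[1] < reference[1] - 1e-9 || r[2] > reference[2] + 1e-9)
      stop_invalid("region '", nm, "' lies outside the reference region")
  }
  structure(list(regions = regions, reference = reference),
            class = "region_set")
}

#' Default quantitation regions for a lignocellulosic carbon spectrum
#'
#' Aromatic 110-170 ppm, sugar 60-110, methoxy 50-58, acetyl carbonyl
#' 168-178 and methyl 15-25, anomeric C1 100-110, two-fold C4 80-90, and the
#' interior (86-90) / surface (80-86) C4 sub-regions split at 86 ppm.
#'
#' @return A [region_set] normalised to 0-200 ppm.
#' @export
wheat_regions <- function() {
  region_set(list(
    aromatic     = c(110, 170),
    sugar        = c(60, 110),
    methoxy      = c(50, 58),
    acetyl_co    = c(168, 178),
    acetyl_ch3   = c(15, 25),
    c1           = c(100, 110),
    c4_twofold   = c(80, 90),
    c4_interior  = c(86, 90),
    c4_surface   = c(80, 86)
  ))
}

## trapezoidal integral of a spectrum between lo and hi ppm (sub-grid ends
## are clipped to the available axis)
integrate_window <- function(spec, lo, hi) {
  ppm <- spec$ppm; y <- spec$intensity
  if (ppm[1] > ppm[length(ppm)]) { ppm <- rev(ppm); y <- rev(y) }
  sel <- ppm >= lo & ppm <= hi
  if (sum(sel) < 2) return(0)
  pracma::trapz(ppm[sel], y[sel])
}

#' Integrate named regions of a spectrum
#'
#' Trapezoidal integrals on the native ppm grid, each divided by the
#' integral of the reference region (no baseline correction).
#'
#' @param spec A [spectrum1d].
#' @param regions A [region_set].
#' @return Named numeric vector of fractions.
#' @export
integrate_regions <- function(spec, regions) {
  stopifnot(inherits(spec, "spectrum1d"), inherits(regions, "region_set"))
  rng <- range(spec$ppm)
  for (nm in names(regions$regions)) {
    r <- regions$regions[[nm]]
    if (r[1] < rng[1] - 1e-9 || r[2] > rng[2] + 1e-9)
      stop_invalid("region '", nm, "' outside the spectrum axis [",
                   rng[1], ", ", rng[2], "] ppm")
  }
  ref <- integrate_window(spec, regions$reference[1], regions$reference[2])
  if (ref <= 0) stop_invalid("reference region integral is not positive")
  vapply(regions$regions, function(r)
    integrate_window(spec, r[1], r[2]) / ref, numeric(1))
}

#' Overall two-fold conformer fraction from C1 and C4 integrals
#'
#' The anomeric C1 fraction counts every glycan residue once; the 80-90 ppm
#' C4 band counts only residues in (near) two-fold conformation. Their ratio
#' bounds the two-fold share of all polysaccharides from below: 10% / 12%
#' gives at least 83%.
#'
#' @param c1_frac C1 region fraction (0 < c1 <= 1).
#' @param c4_2f_frac Two-fold C4 region fraction (clipped to `c1_frac` with a
#'   warning if larger).
#' @return Two-fold fraction `c4_2f_frac / c1_frac`.
#' @export
twofold_fraction <- function(c1_frac, c4_2f_frac) {
  if (c1_frac <= 0 || c1_frac > 1) stop_invalid("`c1_frac` must be in (0, 1]")
  if (c4_2f_frac < 0) stop_invalid("`c4_2f_frac` must be >= 0")
  if (c4_2f_frac > c1_frac) {
    warning("c4_2f_frac > c1_frac; clipping to c1_frac")
    c4_2f_frac <- c1_frac
  }
  c4_2f_frac / c1_frac
}

#' Two-fold share among xylan assuming all cellulose is two-fold
#'
#' With a cellulose share `cellulose_share` of all glycans (e.g. 0.6 from a
#' 6:4 glucose:xylose ratio) and all cellulose in two-fold conformation, the
#' two-fold share of the xylan pool is
#' `(overall_2f - cellulose_share) / (1 - cellulose_share)`.
#'
#' @param overall_2f Overall two-fold fraction (from [twofold_fraction()]).
#' @param cellulose_share Cellulose share of glycan residues, `< 1`.
#' @return Xylan two-fold share in `[0, 1]`.
#' @export
xylan_twofold_share <- function(overall_2f, cellulose_share) {
  if (cellulose_share >= 1) stop_invalid("`cellulose_share` must be < 1")
  if (overall_2f < cellulose_share)
    stop_invalid("assumption violated: overall two-fold fraction ",
                 overall_2f, " < cellulose share ", cellulose_share,
                 " (cellulose cannot all be two-fold)")
  (overall_2f - cellulose_share) / (1 - cellulose_share)
}

#' Interior / surface split of the two-fold C4 band
#'
#' Normalises the downfield (> 86 ppm, "interior") and upfield (< 86 ppm,
#' "surface") C4 integrals to a pair summing to one.
#'
#' @param downfield Integral of the > 86 ppm component (>= 0).
#' @param upfield Integral of the < 86 ppm component (>= 0).
#' @return Named numeric `c(interior = , surface = )`.
#' @export
interior_surface_split <- function(downfield, upfield) {
  if (downfield < 0 || upfield < 0) stop_invalid("integrals must be >= 0")
  tot <- downfield + upfield
  if (tot == 0) stop_invalid("degenerate input: both integrals are zero")
  c(interior = downfield / tot, surface = upfield / tot)
}

#' Average residues per acetyl group
#'
#' Ratio of the residue-pool carbon fraction to the acetyl carbon fraction;
#' e.g. a xylan anomeric-equivalent fraction of 5.4% against 2% acetyl
#' carbon means one acetyl per 2.7 residues.
#'
#' @param residue_frac Carbon fraction of the residue pool (> 0).
#' @param acetyl_frac Acetyl carbon fraction (>= 0).
#' @return Residues per acetyl; `Inf` when `acetyl_frac` is zero (explicit
#'   "no acetylation" sentinel, not an error).
#' @export
acetylation_degree <- function(residue_frac, acetyl_frac) {
  if (residue_frac <= 0) stop_invalid("`residue_frac` must be > 0")
  if (acetyl_frac < 0) stop_invalid("`acetyl_frac` must be >= 0")
  if (acetyl_frac == 0) return(Inf)
  residue_frac / acetyl_frac
}

#' Classify cross-peaks by relative intensity
#'
#' Intensities are percentages of the one-dimensional slice integral over
#' 10-180 ppm. Peaks above 4% are `strong`, peaks from 2% to 4% inclusive
#' are `medium`, and peaks below 2% are `weak` (both boundary values map to
#' `medium`).
#'
#' @param rel_intensity_pct Numeric vector of non-negative relative
#'   intensities in percent.
#' @return Factor with levels `strong`, `medium`, `weak`.
#' @export
classify_cross_peaks <- function(rel_intensity_pct) {
  if (any(rel_intensity_pct < 0))
    stop_invalid("relative intensities must be >= 0")
  cls <- ifelse(rel_intensity_pct > 4, "strong",
         ifelse(rel_intensity_pct >= 2, "medium", "weak"))
  factor(cls, levels = c("strong", "medium", "weak"))
}

#' Default site-label to component map
#'
#' Seeds the mapping used by [chord_weights()]: interior/surface cellulose
#' carbons (`i*`, `s*`) to `cellulose`, two-/three-fold xylan (`2fXn*`,
#' `3fXn*`, `Xn*`) to `xylan`, syringyl/guaiacyl/p-hydroxyphenyl/ferulate
#' carbons to `lignin`, acetyl methyl/carbonyl to `acetyl`, and `OMe` to
#' `methoxy`. Editable: pass your own named vector to [chord_weights()].
#'
#' @return Named character vector, site-label prefix -> component.
#' @export
default_component_map <- function() {
  c(i = "cellulose", s = "cellulose",
    `2fXn` = "xylan", `3fXn` = "xylan", Xn = "xylan",
    S = "lignin", G = "lignin", H = "lignin", FA = "lignin",
    AcMe = "acetyl", AcCO = "acetyl",
    OMe = "methoxy")
}

## map a site label like "i4" or "2fXn5" to its component via prefix match
map_component <- function(labels, component_map) {
  prefixes <- names(component_map)[order(nchar(names(component_map)),
                                         decreasing = TRUE)]
  out <- rep(NA_character_, length(labels))
  for (p in prefixes) {
    hit <- is.na(out) & startsWith(labels, p)
    out[hit] <- component_map[[p]]
  }
  if (any(is.na(out)))
    stop_invalid("unmapped site labels: ",
                 paste(unique(labels[is.na(out)]), collapse = ", "))
  out
}

#' Chord-diagram interaction weights from classified cross-peaks
#'
#' Strong, medium and weak cross-peaks contribute 3, 2 and 1 respectively;
#' weights are summed per (source component, sink component) pair using a
#' site-label to component map.
#'
#' @param peaks Data frame with columns `source`, `sink` (site labels) and
#'   `class` (`strong`/`medium`/`weak`, e.g. from [classify_cross_peaks()]).
#' @param component_map Named vector mapping label prefixes to components
#'   (default [default_component_map()]).
#' @param symmetric If `TRUE`, fold (a, b) and (b, a) together into an upper
#'   triangle (flagged in the attributes). Default `FALSE`.
#' @return Integer matrix of summed weights, components x components, with
#'   attribute `symmetric`.
#' @export
chord_weights <- function(peaks, component_map = default_component_map(),
                          symmetric = FALSE) {
  if (nrow(peaks) == 0) {
    comps <- sort(unique(unname(component_map)))
    m <- matrix(0L, length(comps), length(comps),
                dimnames = list(comps, comps))
    attr(m, "symmetric") <- symmetric
    return(m)
  }
  cls <- as.character(peaks$class)
  if (!all(cls %in% c("strong", "medium", "weak")))
    stop_invalid("`class` must be strong/medium/weak")
  w <- c(strong = 3L, medium = 2L, weak = 1L)[cls]
  src <- map_component(as.character(peaks$source), component_map)
  snk <- map_component(as.character(peaks$sink), component_map)
  comps <- sort(unique(unname(component_map)))
  m <- matrix(0L, length(comps), length(comps),
              dimnames = list(source = comps, sink = comps))
  for (k in seq_along(w)) {
    a <- src[k]; b <- snk[k]
    if (symmetric && match(a, comps) > match(b, comps)) { tmp <- a; a <- b; b <- tmp }
    m[a, b] <- m[a, b] + w[k]
  }
  attr(m, "symmetric") <- symmetric
  m
}

#' Water-edited intensity ratios
#'
#' Element-wise S/S0 between a water-edited spectrum and its control. Sites
#' with non-positive control intensity are excluded (NA) with a warning;
#' ratios above 1.2 are flagged (attribute `flagged`), not rejected.
#'
#' @param S Named or plain numeric vector, water-edited intensities.
#' @param S0 Control intensities, same length.
#' @return Numeric vector of ratios with attribute `flagged`.
#' @export
water_edited_ratio <- function(S, S0) {
  if (length(S) != length(S0))
    stop_invalid("`S` and `S0` must have the same length")
  out <- rep(NA_real_, length(S))
  ok <- S0 > 0
  if (any(!ok))
    warning(sum(!ok), " site(s) with non-positive S0 excluded")
  out[ok] <- S[ok] / S0[ok]
  attr(out, "flagged") <- !is.na(out) & out > 1.2
  out
}

#' Single-exponential relaxation fit
#'
#' Least-squares fit of `I0 * exp(-t / T)` (decay) or the inversion-recovery
#' form `I0 * (1 - 2 * exp(-t / T))` (recovery). Starting values come from a
#' log-linear fit (decay) or the signal range (recovery); the final fit is
#' Levenberg-Marquardt.
#'
#' @param times Non-negative, increasing times in seconds (>= 4 points).
#' @param intensities Signal intensities.
#' @param mode `"decay"` or `"recovery"`.
#' @return List of class `exp_fit`: `T` (time constant, s), `I0`, `fitted`,
#'   `residual_ss`, `mode`.
#' @export
fit_exponential <- function(times, intensities,
                            mode = c("decay", "recovery")) {
  mode <- match.arg(mode)
  if (length(times) < 4) stop_invalid("need at least 4 points")
  if (any(times < 0) || any(diff(times) <= 0))
    stop_invalid("`times` must be non-negative and increasing")
  if (length(intensities) != length(times))
    stop_invalid("length mismatch")
  t <- times; y <- intensities
  if (mode == "decay") {
    pos <- y > 0
    if (sum(pos) >= 2) {
      lf <- lm.fit(cbind(1, t[pos]), log(y[pos]))
      T0 <- -1 / min(lf$coefficients[2], -1e-8)
      I0 <- exp(lf$coefficients[1])
    } else { T0 <- diff(range(t)) / 2; I0 <- max(abs(y)) }
    fn <- function(p) y - p[1] * exp(-t / p[2])
  } else {
    I0 <- max(abs(y))
    ## zero crossing of 1 - 2 exp(-t/T) is at t = T log 2
    cross <- t[which.min(abs(y))]
    T0 <- max(cross / log(2), diff(range(t)) / 10)
    fn <- function(p) y - p[1] * (1 - 2 * exp(-t / p[2]))
  }
  fit <- minpack.lm::nls.lm(par = unname(c(I0, T0)), fn = fn,
                            lower = c(0, 1e-10), upper = c(Inf, Inf),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (fit$info %in% c(0, 9))
    stop_invalid("relaxation fit did not converge: ", fit$message)
  structure(list(T = fit$par[2], I0 = fit$par[1],
                 fitted = y - fit$fvec, residual_ss = sum(fit$fvec^2),
                 mode = mode),
            class = "exp_fit")
}

#' Lignin S:G:H proportions from HSQC integrals
#'
#' The S(2,6) and H(2,6) cross-peaks each carry two equivalent carbons, so
#' their integrals are divided by two before normalisation against G(2).
#'
#' @param s26 Integral of the syringyl 2,6 signal (>= 0).
#' @param g2 Integral of the guaiacyl 2 signal (>= 0).
#' @param h26 Integral of the p-hydroxyphenyl 2,6 signal (>= 0).
#' @return Named proportions `c(S = , G = , H = )` summing to 1.
#' @export
hsqc_lignin_ratios <- function(s26, g2, h26) {
  if (any(c(s26, g2, h26) < 0)) stop_invalid("integrals must be >= 0")
  v <- c(S = s26 / 2, G = g2, H = h26 / 2)
  if (sum(v) == 0) stop_invalid("degenerate input: all integrals are zero")
  v / sum(v)
}

#' Read a cross-peak table from CSV
#'
#' Expected columns: `source`, `sink`, `f1_ppm`, `f2_ppm`,
#' `rel_intensity_pct`.
#'
#' @param path CSV path.
#' @return Data frame with an added `class` column from
#'   [classify_cross_peaks()].
#' @export
read_crosspeaks <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("source", "sink", "f1_ppm", "f2_ppm", "rel_intensity_pct")
  if (!all(need %in% names(df)))
    stop_invalid("cross-peak CSV must have columns: ",
                 paste(need, collapse = ", "))
  df$class <- classify_cross_peaks(df$rel_intensity_pct)
  df
}
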