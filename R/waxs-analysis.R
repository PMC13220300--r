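#' Diffraction peak (pseudo-Voigt) parameters
#'
#' @param center Peak position in Angstrom^-1.
#' @param fwhm Full width at half maximum in Angstrom^-1 (> 0).
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @param amplitude Peak height (>= 0), intensity units.
#' @return An object of class `diffraction_peak`.
#' @export
diffraction_peak <- function(center, fwhm, eta = 0.5, amplitude = 1) {
  if (fwhm <= 0) stop_invalid("`fwhm` must be > 0")
  if (eta < 0 || eta > 1) stop_invalid("`eta` must be in [0, 1]")
  if (amplitude < 0) stop_invalid("`amplitude` must be >= 0")
  structure(list(center = center, fwhm = fwhm, eta = eta,
                 amplitude = amplitude),
            class = "diffraction_peak")
}

#' Pseudo-Voigt lineshape
#'
#' `amplitude * (eta * L(x) + (1 - eta) * G(x))` with unit-height Lorentzian
#' `L` and Gaussian `G` sharing the same full width at half maximum, so the
#' value at `center +/- fwhm/2` is `amplitude / 2` for any `eta`.
#'
#' @param x Positions (Angstrom^-1).
#' @param peak A [diffraction_peak].
#' @return Intensities at `x`.
#' @export
pseudo_voigt <- function(x, peak) {
  stopifnot(inherits(peak, "diffraction_peak"))
  u <- (x - peak$center) / peak$fwhm
  L <- 1 / (1 + 4 * u^2)
  G <- exp(-4 * log(2) * u^2)
  peak$amplitude * (peak$eta * L + (1 - peak$eta) * G)
}

#' Closed-form area of a pseudo-Voigt peak
#'
#' Component areas: Lorentzian `amp * fwhm * pi / 2`, Gaussian
#' `amp * fwhm * sqrt(pi / (4 log 2))`; the pseudo-Voigt area is their
#' eta-weighted combination.
#'
#' @param peak A [diffraction_peak].
#' @return Integrated area (intensity * Angstrom^-1).
#' @export
pseudo_voigt_area <- function(peak) {
  stopifnot(inherits(peak, "diffraction_peak"))
  aL <- peak$amplitude * peak$fwhm * pi / 2
  aG <- peak$amplitude * peak$fwhm * sqrt(pi / (4 * log(2)))
  peak$eta * aL + (1 - peak$eta) * aG
}

#' Fit pseudo-Voigt peaks to an equatorial diffraction profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) of `n_peaks` pseudo-Voigt
#' functions plus a linear background over a fit window. Intended for the
#' cellulose equatorial profile: the 110/1-10 composite and the 200
#' reflection (2 peaks), optionally 3.
#'
#' @param profile A [scattering_profile] (q in Angstrom^-1).
#' @param n_peaks 2 or 3.
#' @param init List of [diffraction_peak] initial guesses (length `n_peaks`)
#'   supplying center, width and lineshape-mix starts; amplitude starts are
#'   read off the data at the guessed centers, which keeps the fit exactly
#'   equivariant under intensity rescaling.
#' @param q_window Fit window (default `c(0.8, 2.0)` Angstrom^-1).
#' @return List of class `waxs_fit`: `peaks` (sorted by center),
#'   `background` (intercept, slope), `residual_ss`, and `fitted` profile.
#' @export
fit_equatorial_peaks <- function(profile, n_peaks = 2, init,
                                 q_window = c(0.8, 2.0)) {
  stopifnot(inherits(profile, "scattering_profile"))
  if (!n_peaks %in% c(2L, 3L)) stop_invalid("`n_peaks` must be 2 or 3")
  if (length(init) != n_peaks)
    stop_invalid("`init` must supply one guess per peak")
  sel <- profile$q >= q_window[1] & profile$q <= q_window[2]
  q <- profile$q[sel]
  y <- profile$intensity[sel]
  if (sd(y) < 1e-14 * max(abs(y), 1))
    stop_invalid("degenerate input: profile is flat over the fit window")
  for (pk in init)
    if (pk$center < min(q) || pk$center > max(q))
      stop_invalid("initial center ", pk$center, " outside the fit window")

  ## normalise intensities so the optimisation (and hence the fit) is
  ## exactly equivariant under rescaling of the data; initial amplitudes are
  ## read off the (smoothed) data at the guessed centers for the same reason
  s_norm <- max(abs(y))
  y <- y / s_norm
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  base <- min(y)

  par0 <- unlist(lapply(init, function(p) {
    amp0 <- max(as.numeric(ys[which.min(abs(q - p$center))]) - base, 1e-8)
    c(p$center, p$fwhm, p$eta, amp0)
  }))
  par0 <- c(par0, base, 0)  # background intercept, slope
  lower <- c(rep(c(min(q), 1e-4, 0, 0), n_peaks), -Inf, -Inf)
  upper <- c(rep(c(max(q), diff(range(q)), 1, Inf), n_peaks), Inf, Inf)

  model_fn <- function(par) {
    out <- par[4 * n_peaks + 1] + par[4 * n_peaks + 2] * q
    for (k in seq_len(n_peaks)) {
      p <- par[(4 * (k - 1) + 1):(4 * k)]
      out <- out + pseudo_voigt(q, diffraction_peak(p[1], p[2], p[3], p[4]))
    }
    out
  }
  ## deterministic multi-start: overlapping peaks on a truncated window make
  ## the LM landscape multi-modal, so vary the lineshape mix and widths and
  ## keep the best converged solution
  idx_eta <- 4 * (seq_len(n_peaks) - 1) + 3
  idx_fwhm <- 4 * (seq_len(n_peaks) - 1) + 2
  idx_ctr <- 4 * (seq_len(n_peaks) - 1) + 1
  idx_amp <- 4 * (seq_len(n_peaks) - 1) + 4
  starts <- list(par0)
  for (e in c(0.25, 0.75)) { p <- par0; p[idx_eta] <- e; starts <- c(starts, list(p)) }
  for (f in c(0.7, 1.4)) { p <- par0; p[idx_fwhm] <- par0[idx_fwhm] * f; starts <- c(starts, list(p)) }
  ## extra starts with centers snapped to the tallest local maxima of the
  ## smoothed profile (classical peak-picking initialisation)
  is_max <- which(diff(sign(diff(ys))) == -2) + 1
  if (length(is_max) >= n_peaks) {
    pk_idx <- is_max[order(ys[is_max], decreasing = TRUE)[seq_len(n_peaks)]]
    pk_idx <- pk_idx[order(q[pk_idx])]
    est_fwhm <- vapply(pk_idx, function(i) {
      half <- base + (as.numeric(ys[i]) - base) / 2
      l <- i; while (l > 1 && ys[l] > half) l <- l - 1
      r <- i; while (r < length(q) && ys[r] > half) r <- r + 1
      max(q[r] - q[l], 2 * (q[2] - q[1]))
    }, numeric(1))
    for (f in c(1, 0.7, 1.4)) {
      p <- par0
      p[idx_ctr] <- q[pk_idx]
      p[idx_fwhm] <- est_fwhm * f
      p[idx_amp] <- pmax(as.numeric(ys[pk_idx]) - base, 1e-8)
      starts <- c(starts, list(p))
    }
  }
  fit <- NULL
  for (p0 in starts) {
    ft <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                             fn = function(par) y - model_fn(par),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500, ftol = 1e-12, ptol = 1e-12))
    if (ft$info %in% c(0, 9)) next
    if (is.null(fit) || sum(ft$fvec^2) < sum(fit$fvec^2)) fit <- ft
  }
  if (is.null(fit))
    stop_invalid("peak fit did not converge from any start")
  par <- fit$par
  peaks <- lapply(seq_len(n_peaks), function(k) {
    p <- par[(4 * (k - 1) + 1):(4 * k)]
    diffraction_peak(p[1], p[2], min(max(p[3], 0), 1),
                     max(p[4], 0) * s_norm)
  })
  ord <- order(vapply(peaks, `[[`, numeric(1), "center"))
  structure(list(peaks = peaks[ord],
                 background = c(intercept = par[4 * n_peaks + 1] * s_norm,
                                slope = par[4 * n_peaks + 2] * s_norm),
                 residual_ss = sum(fit$fvec^2) * s_norm^2,
                 fitted = scattering_profile(q,
                                             pmax(model_fn(par), 0) * s_norm),
                 q_window = q_window),
            class = "waxs_fit")
}

#' Scherrer crystallite size from peak width
#'
#' `L = 2 pi K / B` with `B` the full width at half maximum of the
#' diffraction peak expressed in Q-space (Angstrom^-1) and `K` the shape
#' factor (default 0.90). With the peak width in Q-space the wavelength
#' cancels out of the classical Scherrer relation; the conventional
#' wavelength 1.542 Angstrom is recorded in the result's attributes for
#' provenance only.
#'
#' @param fwhm_q Peak FWHM in Angstrom^-1 (> 0).
#' @param K Shape factor (> 0, default 0.90).
#' @return Crystallite size in Angstrom.
#' @export
scherrer_size <- function(fwhm_q, K = 0.90) {
  if (any(fwhm_q <= 0)) stop_invalid("`fwhm_q` must be > 0")
  if (K <= 0) stop_invalid("`K` must be > 0")
  out <- 2 * pi * K / fwhm_q
  attr(out, "lambda_A") <- 1.542
  out
}

#' Bragg d-spacing from a peak position
#'
#' `d = 2 pi / q`; the function is an involution
#' (`d_spacing(d_spacing(x)) == x`).
#'
#' @param q_center Peak position in Angstrom^-1 (> 0).
#' @return d-spacing in Angstrom.
#' @export
d_spacing <- function(q_center) {
  if (any(q_center <= 0)) stop_invalid("`q_center` must be > 0")
  2 * pi / q_center
}

#' Relative lattice expansion in percent
#'
#' `100 * (d_obs - d_ref) / d_ref`; e.g. an observed 200 d-spacing of 4.05
#' Angstrom against the 3.86 Angstrom crystalline reference is an a-axis
#' swelling of about 5%.
#'
#' @param d_obs Observed spacing (Angstrom, > 0).
#' @param d_ref Reference spacing (Angstrom, > 0).
#' @return Expansion in percent.
#' @export
relative_expansion <- function(d_obs, d_ref) {
  if (any(d_ref <= 0) || any(d_obs <= 0))
    stop_invalid("spacings must be > 0")
  100 * (d_obs - d_ref) / d_ref
}
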