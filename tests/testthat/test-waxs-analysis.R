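test_that("pseudo-Voigt hits its closed-form landmarks", {
  pk <- diffraction_peak(1.5, 0.2, eta = 0, amplitude = 3)
  expect_equal(pseudo_voigt(1.5, pk), 3)
  pkL <- diffraction_peak(1.5, 0.2, eta = 1, amplitude = 3)
  expect_equal(pseudo_voigt(1.5 + 0.1, pkL), 1.5)   # half max at half width
  pkM <- diffraction_peak(1.5, 0.2, eta = 0.5, amplitude = 3)
  expect_equal(pseudo_voigt(1.5 - 0.1, pkM), 1.5)   # both components at half
  expect_error(diffraction_peak(1.5, -0.1), "fwhm")
  expect_error(diffraction_peak(1.5, 0.2, eta = 1.2), "eta")
})

test_that("pseudo-Voigt area matches numeric integration", {
  for (eta in c(0, 0.3, 0.5, 1)) {
    pk <- diffraction_peak(0, 0.37, eta = eta, amplitude = 2.2)
    x <- seq(-120, 120, by = 0.002)   # wide window for the Lorentzian tails
    num <- pracma::trapz(x, pseudo_voigt(x, pk))
    expect_equal(num, pseudo_voigt_area(pk),
                 tolerance = if (eta > 0) 5e-3 else 1e-6)
  }
})

test_that("peak fitting round-trips the generator exactly without noise", {
  g <- gen_waxs_profile(noise_sd = 0)
  fit <- fit_equatorial_peaks(g$profile, 2,
                              init = list(diffraction_peak(1.05, 0.3, 0.5, 0.5),
                                          diffraction_peak(1.62, 0.25, 0.5, 0.7)))
  truth <- waxs_preset_peaks()
  for (k in 1:2) {
    expect_equal(fit$peaks[[k]]$center, truth[[k]]$center, tolerance = 1e-6)
    expect_equal(fit$peaks[[k]]$fwhm, truth[[k]]$fwhm, tolerance = 1e-6)
    expect_equal(fit$peaks[[k]]$eta, truth[[k]]$eta, tolerance = 1e-4)
    expect_equal(fit$peaks[[k]]$amplitude, truth[[k]]$amplitude,
                 tolerance = 1e-6)
  }
  expect_lt(fit$residual_ss, 1e-10)
})

test_that("fitted centers stay within 0.5% under 2% noise", {
  truth <- waxs_preset_peaks()
  errs <- vapply(1:12, function(s) {
    g <- gen_waxs_profile(noise_sd = 0.02, seed = s)
    fit <- fit_equatorial_peaks(g$profile, 2,
                                init = list(diffraction_peak(1.05, 0.3, 0.5, 0.5),
                                            diffraction_peak(1.6, 0.25, 0.5, 0.7)))
    max(abs(fit$peaks[[1]]$center / truth[[1]]$center - 1),
        abs(fit$peaks[[2]]$center / truth[[2]]$center - 1))
  }, numeric(1))
  expect_true(all(errs < 0.005))
})

test_that("fit is equivariant under intensity rescaling", {
  g <- gen_waxs_profile(noise_sd = 0.01, seed = 4)
  ini <- list(diffraction_peak(1.05, 0.3, 0.5, 0.5),
              diffraction_peak(1.6, 0.25, 0.5, 0.7))
  f1 <- fit_equatorial_peaks(g$profile, 2, init = ini)
  k <- 12.5
  f2 <- fit_equatorial_peaks(
    scattering_profile(g$profile$q, k * g$profile$intensity), 2, init = ini)
  for (j in 1:2) {
    expect_equal(f2$peaks[[j]]$center, f1$peaks[[j]]$center,
                 tolerance = 1e-6)
    expect_equal(f2$peaks[[j]]$fwhm, f1$peaks[[j]]$fwhm, tolerance = 1e-5)
    expect_equal(f2$peaks[[j]]$eta, f1$peaks[[j]]$eta, tolerance = 1e-3)
    expect_equal(f2$peaks[[j]]$amplitude, k * f1$peaks[[j]]$amplitude,
                 tolerance = 1e-5)
  }
  expect_error(fit_equatorial_peaks(
    scattering_profile(g$profile$q, rep(1, length(g$profile$q))), 2,
    init = ini), "flat")
})

test_that("two-peak fit on a single-peak profile zeroes one amplitude", {
  lone <- gen_waxs_profile(peaks = list(waxs_preset_peaks()[[2]]),
                           noise_sd = 0)
  fit <- fit_equatorial_peaks(lone$profile, 2,
                              init = list(diffraction_peak(1.1, 0.2, 0.5, 0.3),
                                          diffraction_peak(1.55, 0.2, 0.5, 0.9)))
  amps <- sort(vapply(fit$peaks, `[[`, numeric(1), "amplitude"))
  expect_lt(amps[1], 1e-4)
  expect_equal(amps[2], 1, tolerance = 1e-4)
})

test_that("Scherrer size and d-spacing follow their reciprocal laws", {
  expect_equal(scherrer_size(2 * pi * 0.90 / 31.6, K = 0.90), 31.6,
               ignore_attr = TRUE)
  expect_equal(scherrer_size(2 * pi, K = 1), 1, ignore_attr = TRUE)
  b <- 0.2
  expect_equal(as.numeric(scherrer_size(b / 2)),
               2 * as.numeric(scherrer_size(b)))
  # inverse identity: fwhm -> size -> fwhm
  expect_equal(2 * pi * 0.9 / as.numeric(scherrer_size(b)), b)
  expect_error(scherrer_size(0), "fwhm")

  expect_equal(d_spacing(2 * pi), 1)
  expect_equal(d_spacing(1.5514), 4.05, tolerance = 1e-4)
  x <- c(0.7, 1.55, 3.2)
  expect_equal(d_spacing(d_spacing(x)), x)
  expect_error(d_spacing(0))

  expect_equal(relative_expansion(4.05, 3.86), 4.92, tolerance = 1e-2)
  expect_equal(round(relative_expansion(4.05, 3.86)), 5)
  expect_equal(relative_expansion(2, 2), 0)
  expect_equal(relative_expansion(2, 1), 100)
  expect_error(relative_expansion(1, 0))
})
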