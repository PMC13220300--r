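test_that("region integration normalises and partitions correctly", {
  # rectangular test spectrum: region == reference gives 1
  sp <- spectrum1d(seq(0, 200, by = 0.1), rep(2, 2001))
  rs <- region_set(list(all = c(0, 200)))
  expect_equal(unname(integrate_regions(sp, rs)[1]), 1)
  # two disjoint regions covering the axis sum to 1
  rs2 <- region_set(list(lo = c(0, 80), hi = c(80, 200)))
  fr <- integrate_regions(sp, rs2)
  expect_equal(unname(sum(fr)), 1, tolerance = 1e-9)
  # fractions over any partition sum to 1
  cuts <- c(0, 33, 71, 120, 162, 200)
  parts <- lapply(seq_len(5), function(i) c(cuts[i], cuts[i + 1]))
  names(parts) <- paste0("p", 1:5)
  g <- gen_spectrum1d("wheat_like", seed = 3)
  frp <- integrate_regions(g$spectrum, region_set(parts))
  expect_equal(unname(sum(frp)), 1, tolerance = 1e-6)
  expect_error(integrate_regions(sp, region_set(list(bad = c(150, 250)),
                                                reference = c(0, 250))),
               "outside")
})

test_that("wheat-like generator fractions are recovered by integration", {
  g <- gen_spectrum1d("wheat_like", noise_sd = 0, seed = 1)
  fr <- integrate_regions(g$spectrum, wheat_regions())
  truth <- g$truth$params$fractions
  for (nm in names(truth))
    expect_equal(unname(fr[nm]), unname(truth[nm]), tolerance = 0.005)
  # interior/surface split at 86 ppm recovers the generated 38/62
  split <- interior_surface_split(fr[["c4_interior"]], fr[["c4_surface"]])
  expect_equal(unname(split["interior"]), 0.38, tolerance = 0.01)
})

test_that("conformer arithmetic reproduces the rule-based quantities", {
  expect_equal(twofold_fraction(0.12, 0.10), 0.8333, tolerance = 1e-4)
  expect_equal(twofold_fraction(0.4, 0.4), 1)
  expect_equal(twofold_fraction(0.4, 0), 0)
  expect_warning(out <- twofold_fraction(0.1, 0.2), "clip")
  expect_equal(out, 1)
  expect_error(twofold_fraction(0, 0.1))

  expect_equal(xylan_twofold_share(0.8333, 0.6), 0.583, tolerance = 1e-3)
  expect_equal(xylan_twofold_share(0.6, 0.6), 0)
  expect_equal(xylan_twofold_share(1, 0.6), 1)
  expect_error(xylan_twofold_share(0.5, 0.6), "violated")

  expect_equal(interior_surface_split(0.38, 0.62),
               c(interior = 0.38, surface = 0.62))
  expect_equal(interior_surface_split(3, 0), c(interior = 1, surface = 0))
  expect_error(interior_surface_split(0, 0), "degenerate")

  expect_equal(acetylation_degree(0.054, 0.02), 2.7)
  expect_equal(acetylation_degree(0.02, 0.02), 1)
  expect_equal(acetylation_degree(0.04, 0.02), 2)
  expect_identical(acetylation_degree(0.05, 0), Inf)
})

test_that("fraction operations are scale invariant", {
  g <- gen_spectrum1d("wheat_like", seed = 6)
  sp <- g$spectrum
  spk <- spectrum1d(sp$ppm, 17.3 * sp$intensity)
  fr1 <- integrate_regions(sp, wheat_regions())
  fr2 <- integrate_regions(spk, wheat_regions())
  expect_equal(fr1, fr2, tolerance = 1e-12)
  expect_equal(twofold_fraction(fr1[["c1"]], fr1[["c4_twofold"]]),
               twofold_fraction(fr2[["c1"]], fr2[["c4_twofold"]]))
  expect_equal(interior_surface_split(2 * 0.38, 2 * 0.62),
               interior_surface_split(0.38, 0.62))
})

test_that("cross-peak classification applies the 2% / 4% thresholds", {
  got <- classify_cross_peaks(c(5.0, 3.0, 1.0, 4.0, 2.0, 0, 100))
  expect_equal(as.character(got),
               c("strong", "medium", "weak", "medium", "medium", "weak",
                 "strong"))
  expect_error(classify_cross_peaks(c(1, -2)), ">= 0")
  # class counts invariant under a common rescale of peak and slice total:
  # percentages are unchanged by construction, classes identical
  pct <- c(0.5, 2.5, 4.5, 7.9)
  expect_identical(classify_cross_peaks(pct), classify_cross_peaks(pct))
})

test_that("chord weights sum 3/2/1 per component pair", {
  pk <- data.frame(source = c("i4", "2fXn4", "2fXn5", "S3"),
                   sink = c("s6", "i6", "i6", "2fXn4"),
                   class = c("strong", "medium", "weak", "medium"))
  m <- chord_weights(pk)
  expect_equal(m["cellulose", "cellulose"], 3L)
  expect_equal(m["xylan", "cellulose"], 2L + 1L)
  expect_equal(m["lignin", "xylan"], 2L)
  expect_equal(sum(m), 3L + 3L + 2L)
  # one strong peak alone weighs 3
  m1 <- chord_weights(data.frame(source = "i4", sink = "s4",
                                 class = "strong"))
  expect_equal(sum(m1), 3L)
  # empty table gives an all-zero matrix
  m0 <- chord_weights(data.frame(source = character(), sink = character(),
                                 class = character()))
  expect_true(all(m0 == 0L))
  expect_error(chord_weights(data.frame(source = "mystery9", sink = "i4",
                                        class = "weak")), "mystery9")
})

test_that("water-edited ratios pass through, clip-flag, and exclude", {
  S0 <- c(a = 2, b = 4, c = 1)
  expect_equal(unname(water_edited_ratio(S0, S0)), c(1, 1, 1),
               ignore_attr = TRUE)
  expect_equal(unname(water_edited_ratio(c(0, 0, 0), S0)), c(0, 0, 0),
               ignore_attr = TRUE)
  r <- water_edited_ratio(c(1, 6, 0.5), S0)
  expect_equal(attr(r, "flagged"), c(FALSE, TRUE, FALSE))
  expect_warning(r2 <- water_edited_ratio(c(1, 1), c(2, 0)), "excluded")
  expect_true(is.na(r2[2]))
  # synthetic 31-site table round trip
  set.seed(10)
  truth_ratio <- runif(31, 0.2, 1.1)
  s0 <- runif(31, 1, 5)
  expect_equal(as.numeric(water_edited_ratio(truth_ratio * s0, s0)),
               truth_ratio, tolerance = 1e-12)
})

test_that("exponential fits recover time constants", {
  t <- seq(0, 20, length.out = 12)
  for (Tc in c(0.1, 0.5, 2, 10, 50)) {
    f <- fit_exponential(t, 3 * exp(-t / Tc), mode = "decay")
    expect_equal(f$T, Tc, tolerance = 1e-6)
    expect_equal(f$I0, 3, tolerance = 1e-6)
  }
  # recovery convention
  fr <- fit_exponential(t, 2 * (1 - 2 * exp(-t / 4)), mode = "recovery")
  expect_equal(fr$T, 4, tolerance = 1e-6)
  # two-point closed form T = dt / log(I1/I2), checked on a 4-point decay
  tt <- c(0, 1, 2, 3)
  y <- 5 * exp(-tt / 1.7)
  expect_equal(fit_exponential(tt, y)$T, 1 / log(y[1] / y[2]),
               tolerance = 1e-8)
  # 5% noise, repeated seeds: median error within 5%
  errs <- vapply(1:40, function(s) {
    set.seed(s)
    yy <- 3 * exp(-seq(0, 15, length.out = 10) / 5) *
      (1 + rnorm(10, 0, 0.05))
    fit_exponential(seq(0, 15, length.out = 10), yy)$T / 5 - 1
  }, numeric(1))
  expect_lt(abs(median(errs)), 0.05)
  expect_error(fit_exponential(c(0, 1, 2), c(1, 0.5, 0.25)), "4 points")
})

test_that("HSQC lignin proportions halve the doubled carbons", {
  expect_equal(hsqc_lignin_ratios(2, 1, 0), c(S = 0.5, G = 0.5, H = 0))
  expect_equal(hsqc_lignin_ratios(0, 1, 0), c(S = 0, G = 1, H = 0))
  expect_equal(hsqc_lignin_ratios(2, 1, 2), c(S = 1, G = 1, H = 1) / 3)
  expect_error(hsqc_lignin_ratios(0, 0, 0), "degenerate")
})

test_that("cross-peak CSV reader attaches classes", {
  truth <- data.frame(source = c("i4", "s6", "2fXn4"),
                      sink = c("s6", "2fXn4", "S3"),
                      class = c("strong", "weak", "medium"))
  g <- gen_crosspeak_table(truth, seed = 5)
  f <- tempfile(fileext = ".csv")
  write.table(g$table, f, sep = ",", row.names = FALSE, quote = FALSE)
  df <- read_crosspeaks(f)
  expect_equal(as.character(df$class), as.character(truth$class))
  unlink(f)
})
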