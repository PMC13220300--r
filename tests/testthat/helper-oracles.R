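# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# First-order Bessel function by its power series:
# J1(x) = sum_k (-1)^k / (k! (k+1)!) (x/2)^(2k+1); adequate for |x| <= 15.
j1_series <- function(x, nterms = 60) {
  vapply(x, function(xx) {
    term <- xx / 2        # k = 0 term
    total <- term
    for (k in seq_len(nterms - 1)) {
      term <- term * (-(xx / 2)^2) / (k * (k + 1))
      total <- total + term
    }
    total
  }, numeric(1))
}

# Zeroth-order Bessel series for the 2D transform cross-checks.
j0_series <- function(x, nterms = 60) {
  vapply(x, function(xx) {
    term <- 1
    total <- 1
    for (k in seq_len(nterms - 1)) {
      term <- term * (-(xx / 2)^2) / (k * k)
      total <- total + term
    }
    total
  }, numeric(1))
}

# Brute-force periodic minimum pair distance in plain R (overlap oracle,
# independent of the C++ implementation).
r_min_pair_dist <- function(centers, L) {
  n <- nrow(centers)
  best <- Inf
  for (i in seq_len(n - 1)) {
    dx <- centers[(i + 1):n, 1] - centers[i, 1]
    dy <- centers[(i + 1):n, 2] - centers[i, 2]
    dx <- dx - L * round(dx / L)
    dy <- dy - L * round(dy / L)
    best <- min(best, sqrt(min(dx^2 + dy^2)))
  }
  best
}

# A tiny wheat-like geometry shared by several tests (kept small so the
# default test run stays fast; the acceptance suite uses the full size).
small_paper_config <- function(n = 400, seed = 99) {
  phi <- effective_area_fraction(0.29, 13.5, 15.85)
  generate_configuration(n, phi, R_e = 15.85, R = 13.5, seed = seed,
                         equil_sweeps = 400)
}
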