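test_that("tissue windows are the three fixed disjoint HU ranges covering [-200, 200]", {
  w <- tissue_windows()
  expect_equal(w$tissue, c("fat", "con", "mus"))
  expect_equal(w$lo, c(-200L, -9L, 41L))
  expect_equal(w$hi, c(-10L, 40L, 200L))
  covered <- unlist(purrr::map2(w$lo, w$hi, seq))
  expect_equal(sort(covered), hu_grid())           # union covers, no overlap
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("mode density matches the closed form and an independent erfc evaluation", {
  # at the location with no skew: N / (sigma * sqrt(2*pi))
  expect_equal(dntra_mode(0, N = 3, mu = 0, sigma = 2), 3 / (2 * sqrt(2 * pi)))
  # zero amplitude is identically zero
  expect_equal(dntra_mode(seq(-200, 200, 25), N = 0, mu = 10, sigma = 5,
                          alpha = 1), rep(0, 17))
  # frozen high-precision values (arbitrary-precision erfc + exp)
  expect_equal(dntra_mode(1, N = 1, mu = 0, sigma = 1, alpha = 2),
               0.011009731820814066, tolerance = 1e-14)
  expect_equal(dntra_mode(-40, N = 135, mu = -65, sigma = 30, alpha = 0.5),
               0.8587458805925615, tolerance = 1e-14)
  # agreement with pracma's erfc across a grid and skewness values
  x <- seq(-200, 200, length.out = 101)
  for (a in c(-5, -1.3, 0, 0.7, 5))
    expect_equal(dntra_mode(x, 1000, -30, 25, a),
                 oracle_mode_density(x, 1000, -30, 25, a), tolerance = 1e-12)
})

test_that("alpha = 0 reduces the mode to an N-scaled Gaussian pointwise", {
  x <- seq(-200, 200, 0.5)
  expect_equal(dntra_mode(x, N = 42, mu = 17, sigma = 9, alpha = 0),
               42 * dnorm(x, 17, 9), tolerance = 1e-12)
})

test_that("invalid mode parameters are rejected", {
  expect_error(dntra_mode(0, N = 1, mu = 0, sigma = 0), "sigma")
  expect_error(dntra_mode(0, N = 1, mu = 0, sigma = -3), "sigma")
  expect_error(dntra_mode(0, N = -1, mu = 0, sigma = 1), "N")
  expect_error(ntra_params(1, -300, 10, 0, 1, 0, 10, 1, 50, 10, 0), "mu_fat")
  expect_error(ntra_params(1, -50, 10, 0, 1, 50, 10, 1, 50, 10, 0), "mu_con")
})

test_that("trimodal curve is the sum of its three modes and vanishes at zero amplitude", {
  p <- fixture_truth()
  x <- as.numeric(hu_grid())
  by_hand <-
    dntra_mode(x, p["N_fat"], p["mu_fat"], p["sigma_fat"], p["alpha_fat"]) +
    dntra_mode(x, p["N_con"], p["mu_con"], p["sigma_con"], 0) +
    dntra_mode(x, p["N_mus"], p["mu_mus"], p["sigma_mus"], p["alpha_mus"])
  expect_equal(dntra(x, p), by_hand)
  p0 <- p
  p0[c("N_fat", "N_con", "N_mus")] <- 0
  expect_equal(dntra(x, p0), rep(0, length(x)))
  expect_true(all(dntra(x, p) >= 0))
})

test_that("each mode integrates to its amplitude for any skewness (quadrature oracle)", {
  set.seed(401)
  for (i in 1:25) {
    N <- runif(1, 0.5, 5e4)
    mu <- runif(1, -150, 150)
    sigma <- runif(1, 2, 60)
    alpha <- runif(1, -5, 5)
    expect_equal(oracle_mode_quadrature(N, mu, sigma, alpha), N,
                 tolerance = 1e-6)
    expect_equal(ntra_mode_mass(N, mu, sigma, alpha), N)
  }
  expect_equal(ntra_mode_mass(N = 0, mu = 0, sigma = 1, alpha = 2), 0)
  expect_equal(ntra_mode_mass(N = 3, mu = 10, sigma = 4, alpha = 0), 3)
  # whole curve integrates to the summed amplitudes
  p <- fixture_truth()
  total <- stats::integrate(function(x) dntra(x, p), -Inf, 0,
                            rel.tol = 1e-9)$value +
    stats::integrate(function(x) dntra(x, p), 0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, sum(p[c("N_fat", "N_con", "N_mus")]),
               tolerance = 1e-6)
})

test_that("parameter vectors flatten to the 11 canonical scalars in order", {
  expect_length(ntra_parameter_names(), 11L)
  p <- ntra_params(1, -50, 10, 0.1, 2, 0, 10, 3, 50, 10, -0.1)
  expect_named(p, ntra_parameter_names())
  df <- tibble::as_tibble(as.list(p))
  expect_equal(validate_ntra_params(df), p, ignore_attr = FALSE)
})

test_that("HU values bin to unit-width integer-centered bins with out-of-range discard", {
  h <- bin_hu(c(0.2, -0.3, 0.4))
  expect_equal(h$count[h$bin_center == 0], 3)
  expect_equal(sum(h$count), 3)
  expect_equal(attr(h, "discarded"), 0L)
  # bin k covers [k - 0.5, k + 0.5)
  h2 <- bin_hu(c(10.5, 10.49999, -199.5, 200.49))
  expect_equal(h2$count[h2$bin_center == 11], 1)
  expect_equal(h2$count[h2$bin_center == 10], 1)
  expect_equal(h2$count[h2$bin_center == -199], 1)
  expect_equal(h2$count[h2$bin_center == 200], 1)
  h3 <- bin_hu(c(0, -300, 250, 201))
  expect_equal(attr(h3, "discarded"), 3L)
  expect_error(bin_hu(c(-300, 250)), "outside")
  expect_error(bin_hu(numeric(0)), "no HU values")
})

test_that("binned draws from a known trimodal density match expected counts", {
  set.seed(402)
  truth <- fixture_truth(mass = 1e5)
  # sample by inverse transform on the binned density itself
  expected <- oracle_expected_counts(as.list(truth))
  n <- 1e5
  draws <- sample(hu_grid(), n, replace = TRUE, prob = expected) +
    runif(n, -0.5, 0.499)
  h <- bin_hu(draws)
  exp_counts <- n * expected / sum(expected)
  # multinomial sampling error: compare within 6 sd per bin
  sds <- sqrt(pmax(exp_counts, 1e-12))
  big <- exp_counts > 20
  expect_true(all(abs(h$count[big] - exp_counts[big]) < 6 * sds[big]))
  expect_equal(sum(h$count), n)
})
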