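# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: direct formulas, normal-equation solves and
# quadrature, so each check is a genuine dual route.

# skewed-mode density via pracma's erfc (independent of the pnorm identity
# used inside the package)
oracle_mode_density <- function(x, N, mu, sigma, alpha) {
  z <- (x - mu) / sigma
  N / (sigma * sqrt(2 * pi)) * exp(-z^2 / 2) * pracma::erfc(alpha * z / sqrt(2))
}

# numeric quadrature of one mode over the real line, split at the location
oracle_mode_quadrature <- function(N, mu, sigma, alpha) {
  f <- function(x) oracle_mode_density(x, N, mu, sigma, alpha)
  stats::integrate(f, -Inf, mu, rel.tol = 1e-10, abs.tol = 0)$value +
    stats::integrate(f, mu, Inf, rel.tol = 1e-10, abs.tol = 0)$value
}

# min-max normalization straight from the formula
oracle_minmax <- function(v) (v - min(v)) / (max(v) - min(v))

# cubic least squares via a direct QR solve of the design matrix
oracle_cubic <- function(age, value) {
  X <- cbind(1, age, age^2, age^3)
  beta <- qr.solve(X, value)
  fitted <- X %*% beta
  sse <- sum((value - fitted)^2)
  sst <- sum((value - mean(value))^2)
  list(coef = as.numeric(beta), r_squared = 1 - sse / sst)
}

# paired t statistic from the textbook formula
oracle_paired_t <- function(left, right) {
  d <- left - right
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1))
}

# expected counts of one leg's histogram: per-bin Simpson integral of the
# truncated trimodal density times the expected pixel count
oracle_expected_counts <- function(params) {
  grid <- -200:200
  simpson <- function(f) (f(grid - 0.5) + 4 * f(grid) + f(grid + 0.5)) / 6
  modes <- list(c("N_fat", "mu_fat", "sigma_fat", "alpha_fat"),
                c("N_con", "mu_con", "sigma_con", NA),
                c("N_mus", "mu_mus", "sigma_mus", "alpha_mus"))
  out <- numeric(length(grid))
  for (m in modes) {
    a <- if (is.na(m[4])) 0 else params[[m[4]]]
    dens <- function(x) oracle_mode_density(x, 1, params[[m[2]]],
                                            params[[m[3]]], a)
    p_bin <- simpson(dens)
    z <- oracle_mode_quadrature(1, params[[m[2]]], params[[m[3]]], a)
    # truncated sampling keeps the mode's pixel count fixed, so bin
    # probabilities are renormalized to the in-range mass
    p_in <- sum(p_bin)  # close to the [-200.5, 200.5) mass on this grid
    out <- out + params[[m[1]]] * p_bin / p_in
  }
  out
}

# a well-separated truth used by several fitting tests (amplitudes in pixels)
fixture_truth <- function(mass = 1e5) {
  p <- ntra_params(33000, -65, 30, 0.5, 22000, 20, 15, 45000, 55, 12, 3.1)
  f <- mass / sum(p[c("N_fat", "N_con", "N_mus")])
  p[c("N_fat", "N_con", "N_mus")] <- p[c("N_fat", "N_con", "N_mus")] * f
  p
}

# exact model curve of a truth, as a histogram table
fixture_curve <- function(truth) {
  tibble::tibble(bin_center = hu_grid(), count = dntra(hu_grid(), truth))
}

# random valid truths: generator-style jitter around the fixture base
random_truth <- function(base = fixture_truth()) {
  jit <- c(N_fat = 8000, mu_fat = 7, sigma_fat = 4, alpha_fat = 0.15,
           N_con = 5500, mu_con = 6, sigma_con = 3,
           N_mus = 10000, mu_mus = 4, sigma_mus = 2, alpha_mus = 0.5)
  repeat {
    tr <- base + rnorm(11, 0, jit[names(base)])
    ok <- tryCatch({ validate_ntra_params(tr); TRUE },
                   error = function(e) FALSE)
    if (ok) return(tr)
  }
}

# small per-leg parameter table for pipeline tests
fixture_fits <- function(n = 8, seed = 5) {
  coh <- generate_cohort(cohort_config(n_subjects = n, sampling_mass = 0,
                                       seed = seed))
  coh$truth
}
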