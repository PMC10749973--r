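make_fits <- function(left, right) {
  dplyr::bind_rows(
    tibble::tibble(subject_id = "s1", side = "L",
                   !!!as.list(setNames(left, ntra_parameter_names()))),
    tibble::tibble(subject_id = "s1", side = "R",
                   !!!as.list(setNames(right, ntra_parameter_names()))))
}

test_that("asymmetry indicators are absolute differences, symmetric in leg order", {
  left <- ntra_params(135.16, -65, 30, 0.5, 90.05, 20, 15, 184.84, 55, 12, 3.09)
  right <- ntra_params(137.48, -64, 31, 0.45, 91.10, 21, 14, 186.41, 54, 13, 3.15)
  a <- compute_asymmetry(make_fits(left, right))
  # worked arithmetic on published-scale amplitudes: |135.16 - 137.48|
  expect_equal(a$N_fat, 2.32)
  expect_equal(a$N_mus, abs(184.84 - 186.41))
  expect_true(all(as.matrix(a[ntra_parameter_names()]) >= 0))
  swapped <- compute_asymmetry(make_fits(right, left))
  expect_equal(a, swapped)
  zero <- compute_asymmetry(make_fits(left, left))
  expect_equal(unlist(zero[ntra_parameter_names()]),
               setNames(rep(0, 11), ntra_parameter_names()))
})

test_that("subjects without both legs are dropped with a message", {
  fits <- fixture_fits(n = 4)
  fits <- fits[-2, ]   # remove one leg
  expect_message(a <- compute_asymmetry(fits), "dropping 1")
  expect_equal(nrow(a), 3L)
})

test_that("min-max normalization maps to [0, 1], attains both ends, matches the formula", {
  expect_equal(as.numeric(minmax_scale(c(2, 4, 6))), c(0, 0.5, 1))
  expect_warning(z <- minmax_scale(c(5, 5, 5)), "degenerate")
  expect_equal(as.numeric(z), c(0, 0, 0))
  expect_error(minmax_scale(3), "at least 2")
  set.seed(404)
  for (i in 1:100) {
    v <- rnorm(sample(3:40, 1), sd = runif(1, 0.1, 50))
    got <- minmax_scale(v)
    expect_equal(as.numeric(got), oracle_minmax(v), tolerance = 1e-8)
    expect_true(all(got >= 0 & got <= 1))
    expect_equal(min(got), 0)
    expect_equal(max(got), 1)
    # invariance under positive affine maps
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 20)
    expect_equal(as.numeric(minmax_scale(a * v + b)), as.numeric(got),
                 tolerance = 1e-8)
  }
})

test_that("indicator-table normalization records the scale used", {
  fits <- fixture_fits(n = 10)
  a <- compute_asymmetry(fits)
  nrm <- normalize_indicators(a)
  sc <- attr(nrm, "scale")
  expect_equal(sc$parameter, ntra_parameter_names())
  for (p in ntra_parameter_names()) {
    expect_equal(nrm[[p]],
                 (a[[p]] - min(a[[p]])) / (max(a[[p]]) - min(a[[p]])),
                 tolerance = 1e-12)
  }
})

test_that("age averaging is the per-age arithmetic mean with subject counts", {
  tab <- tibble::tibble(subject_id = c("a", "b", "c"), N_fat = c(0.2, 0.4, 0.9))
  coh <- tibble::tibble(subject_id = c("a", "b", "c"), age = c(80L, 80L, 81L))
  s <- age_average(tab, coh)
  expect_equal(s$value[s$age == 80], 0.3)
  expect_equal(s$n[s$age == 80], 2L)
  expect_equal(s$value[s$age == 81], 0.9)
  # one subject per age: series equals the subject values
  coh2 <- tibble::tibble(subject_id = c("a", "b", "c"), age = 71:73)
  expect_equal(age_average(tab, coh2)$value, tab$N_fat)
  # absent ages are absent, not zero-filled
  expect_equal(sort(unique(s$age)), c(80L, 81L))
  expect_error(age_average(tab, dplyr::mutate(coh, age = age + 0.5)),
               "integer")
})

test_that("age averages recombine to the overall mean (mass balance, 100 cases)", {
  set.seed(405)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    tab <- tibble::tibble(subject_id = as.character(1:n), N_fat = runif(n))
    coh <- tibble::tibble(subject_id = as.character(1:n),
                          age = sample(71:98, n, replace = TRUE))
    s <- age_average(tab, coh)
    expect_equal(sum(s$value * s$n) / sum(s$n), mean(tab$N_fat),
                 tolerance = 1e-8)
  }
})

test_that("cubic trend fit matches a normal-equations oracle and handles degenerate series", {
  # exact cubic reproduced with R^2 = 1
  s <- tibble::tibble(age = 71:98,
                      value = 1 + 0.001 * (71:98)^3 - 0.2 * (71:98)^2)
  tr <- fit_cubic_trend(s)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)
  expect_equal(c(tr$b0, tr$b1, tr$b2, tr$b3), c(1, 0, -0.2, 0.001),
               tolerance = 1e-6)
  # constant series: R^2 defined as 0 with a warning
  expect_warning(tr0 <- fit_cubic_trend(tibble::tibble(age = 71:80,
                                                       value = rep(2, 10))),
                 "constant")
  expect_equal(tr0$r_squared, 0)
  expect_error(fit_cubic_trend(tibble::tibble(age = c(71, 72, 73),
                                              value = 1:3)), "4 distinct")
  set.seed(406)
  for (i in 1:100) {
    ages <- sample(65:100, 10)
    vals <- rnorm(10)
    got <- fit_cubic_trend(tibble::tibble(age = ages, value = vals))
    want <- oracle_cubic(ages, vals)
    expect_equal(c(got$b0, got$b1, got$b2, got$b3), want$coef,
                 tolerance = 1e-8)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-8)
  }
})

test_that("indicator selection picks the per-tissue R^2 maximum with canonical tie-breaks", {
  # R^2 table shaped like the published per-tissue table:
  # fat 0.50/0.23/0.21/0.18, muscle 0.31/0.34/0.76/0.16, connective 0.36/0.21/0.75
  r2 <- c(N_fat = 0.50, mu_fat = 0.23, sigma_fat = 0.21, alpha_fat = 0.18,
          N_con = 0.36, mu_con = 0.21, sigma_con = 0.75,
          N_mus = 0.31, mu_mus = 0.34, sigma_mus = 0.76, alpha_mus = 0.16)
  trends <- tibble::tibble(parameter = names(r2), b0 = 0, b1 = 0, b2 = 0,
                           b3 = 0, r_squared = unname(r2), n_points = 28L)
  sel <- select_top_indicators(trends)
  expect_equal(sel$parameter[sel$tissue == "fat"], "N_fat")
  expect_equal(sel$parameter[sel$tissue == "mus"], "sigma_mus")
  expect_equal(sel$parameter[sel$tissue == "con"], "sigma_con")
  expect_false(any(sel$tie))
  # all equal: first in canonical order per tissue, tie flagged
  sel2 <- select_top_indicators(dplyr::mutate(trends, r_squared = 0.5))
  expect_equal(sel2$parameter, c("N_fat", "N_con", "N_mus"))
  expect_true(all(sel2$tie))
  # an all-zero tissue still returns its first indicator
  r3 <- dplyr::mutate(trends,
                      r_squared = ifelse(grepl("con$", parameter), 0,
                                         r_squared))
  sel3 <- select_top_indicators(r3)
  expect_equal(sel3$parameter[sel3$tissue == "con"], "N_con")
  expect_true(sel3$tie[sel3$tissue == "con"])
})

test_that("stratified trends reduce to the pooled analysis for trivial groupings", {
  coh <- generate_cohort(cohort_config(n_subjects = 60, sampling_mass = 0,
                                       seed = 21))
  a <- compute_asymmetry(coh$truth)
  nrm <- normalize_indicators(a)
  cohort <- dplyr::mutate(coh$cohort, one = "all",
                          copy_a = "g", copy_b = "g")
  # single group: equals the ungrouped pipeline
  g1 <- grouped_trends(cohort, nrm, "one", parameters = "sigma_mus")
  pooled_series <- age_average(nrm[, c("subject_id", "sigma_mus")], cohort)
  expect_equal(dplyr::select(g1$series, -"group"), pooled_series)
  pooled_trend <- fit_cubic_trend(pooled_series)
  expect_equal(g1$trends$r_squared, pooled_trend$r_squared)
  # identical member groups give identical curves
  cohort2 <- dplyr::mutate(cohort,
                           two = rep(c("x", "y"), length.out = nrow(cohort)))
  both <- dplyr::bind_rows(dplyr::mutate(cohort, two = "x"),
                           dplyr::mutate(cohort, two = "y"))
  nrm2 <- dplyr::bind_rows(nrm, nrm)
  g2 <- grouped_trends(both, dplyr::distinct(nrm2), "two",
                       parameters = "sigma_mus")
  tx <- dplyr::filter(g2$trends, group == "x")
  ty <- dplyr::filter(g2$trends, group == "y")
  expect_equal(dplyr::select(tx, -"group"), dplyr::select(ty, -"group"))
})

test_that("strata with too few ages are marked unfittable and missing labels excluded", {
  coh <- generate_cohort(cohort_config(n_subjects = 40, sampling_mass = 0,
                                       seed = 22))
  a <- compute_asymmetry(coh$truth)
  nrm <- normalize_indicators(a)
  cohort <- coh$cohort
  cohort$lab <- c("tiny", rep("big", nrow(cohort) - 1))
  cohort$lab[2] <- NA
  expect_message(
    g <- grouped_trends(cohort, nrm, "lab", parameters = "sigma_mus"),
    "excluded")
  expect_false(g$trends$fittable[g$trends$group == "tiny"])
  expect_true(g$trends$fittable[g$trends$group == "big"])
})

test_that("a configured uniform shift separates group curves at every age", {
  set.seed(407)
  ages <- rep(71:90, each = 6)
  n <- length(ages)
  base_val <- 0.2 + 0.02 * (ages - 71) + rnorm(n, 0, 0.01)
  tab <- tibble::tibble(subject_id = as.character(1:(2 * n)),
                        sigma_mus = c(base_val, base_val + 0.2))
  cohort <- tibble::tibble(subject_id = as.character(1:(2 * n)),
                           age = rep(ages, 2),
                           grp = rep(c("A", "B"), each = n))
  g <- grouped_trends(cohort, tab, "grp", parameters = "sigma_mus")
  eval_ages <- 71:90
  cv <- function(lab) {
    tr <- dplyr::filter(g$trends, group == lab)
    tr$b0 + tr$b1 * eval_ages + tr$b2 * eval_ages^2 + tr$b3 * eval_ages^3
  }
  expect_true(all(cv("B") > cv("A")))
})
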