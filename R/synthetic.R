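#' Configuration of the synthetic aging-cohort generator
#'
#' Bundles every knob of [generate_cohort()].  The defaults emulate the
#' structure of a large community-dwelling elderly cohort: 3157 subjects
#' aged 71-98, trimodal mid-thigh HU distributions with amplitudes in the
#' proportion fat : connective : muscle of about 0.33 : 0.22 : 0.45 and
#' roughly 1e5 soft-tissue pixels per leg, small left-right parameter
#' differences whose expected magnitude rises with age as a cubic for the
#' fat amplitude and the muscle and connective widths (flat for the
#' remaining indicators), BMI spanning the four clinical classes, gait
#' speeds spanning the 1.0 / 1.3 m/s thresholds, TUG times spanning the
#' 10 / 13 / 29 s thresholds, a negative muscle-width-asymmetry effect on
#' fast gait speed only, and a few percent missingness in the mobility
#' tests.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Integer `c(lo, hi)` years; ages drawn uniformly.
#' @param base_params Cohort-mean model parameters (amplitudes in pixels).
#' @param jitter_sd Named vector: between-subject SD of each parameter.
#' @param asymmetry_trend Named list mapping each of the 11 parameters to
#'   cubic coefficients `c(b0, b1, b2, b3)` giving the expected absolute
#'   left-right difference as a function of scaled age
#'   `t = (age - lo) / (hi - lo)` in `[0, 1]`.
#' @param sampling_mass Expected soft-tissue pixels per leg at the default
#'   amplitude scale; set 0 to skip histogram sampling (parameter-level
#'   cohort only).  Amplitudes, their jitter and their asymmetry trends are
#'   rescaled by `sampling_mass / sum of base amplitudes`.
#' @param outcome_model Named list of lists (`v_norm`, `v_fast`, `tug`, `bmi`)
#'   with fields `intercept`, `age_coef` (per year above `age_range[1]`),
#'   `asym_coef` (per HU of true muscle-width asymmetry; 0 = no link) and
#'   `sd`; `tug` acts on the log scale, `bmi` ignores age and asymmetry.
#' @param missingness Named rates in `[0, 1]` for `v_norm`, `v_fast`, `tug`.
#' @param seed Integer seed; mandatory, every draw is governed by it.
#' @return A list of class `ntra_cohort_config`.
#' @export
cohort_config <- function(
    n_subjects = 3157,
    age_range = c(71L, 98L),
    base_params = ntra_params(33000, -70, 25, 0.5,
                              22000, 10, 12,
                              45000, 58, 10, 1.5),
    jitter_sd = c(N_fat = 8000, mu_fat = 7, sigma_fat = 4, alpha_fat = 0.15,
                  N_con = 5500, mu_con = 5, sigma_con = 2,
                  N_mus = 10000, mu_mus = 4, sigma_mus = 2,
                  alpha_mus = 0.3),
    asymmetry_trend = list(
      N_fat = c(250, 0, 0, 1750),
      mu_fat = c(0.3, 0, 0, 0),
      sigma_fat = c(0.5, 0, 0, 0),
      alpha_fat = c(0.02, 0, 0, 0),
      N_con = c(250, 0, 0, 0),
      mu_con = c(0.3, 0, 0, 0),
      sigma_con = c(0.4, 0, 0, 2.6),
      N_mus = c(375, 0, 0, 0),
      mu_mus = c(0.3, 0, 0, 0),
      sigma_mus = c(0.8, 0, 0, 5.2),
      alpha_mus = c(0.2, 0, 0, 0)),
    sampling_mass = 1e5,
    outcome_model = list(
      v_norm = list(intercept = 1.15, age_coef = -0.004, asym_coef = 0,
                    sd = 0.20),
      v_fast = list(intercept = 1.48, age_coef = -0.005, asym_coef = -0.1,
                    sd = 0.15),
      tug = list(intercept = log(10.8), age_coef = 0.008, asym_coef = 0,
                 sd = 0.22),
      bmi = list(intercept = 26.5, sd = 4.2)),
    missingness = c(v_norm = 0.033, v_fast = 0.033, tug = 0.033),
    seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility",
                          call. = FALSE)
  stopifnot(n_subjects >= 1, length(age_range) == 2,
            age_range[1] <= age_range[2], sampling_mass >= 0)
  base_params <- validate_ntra_params(base_params)
  pn <- ntra_parameter_names()
  stopifnot(all(pn %in% names(jitter_sd)), all(pn %in% names(asymmetry_trend)))
  structure(
    list(n_subjects = as.integer(n_subjects),
         age_range = as.integer(age_range),
         base_params = base_params,
         jitter_sd = jitter_sd[pn],
         asymmetry_trend = asymmetry_trend[pn],
         sampling_mass = sampling_mass,
         outcome_model = outcome_model,
         missingness = missingness,
         seed = as.integer(seed)),
    class = "ntra_cohort_config")
}

# internal: expected |left - right| of one parameter at given ages
trend_value <- function(coefs, ages, age_range) {
  t <- (ages - age_range[1]) / max(age_range[2] - age_range[1], 1)
  pmax(coefs[1] + coefs[2] * t + coefs[3] * t^2 + coefs[4] * t^3, 0)
}

# internal: per-parameter validity for jitter rejection
param_ok <- function(p, name) {
  tis <- sub("^.*_", "", name)
  kind <- sub("_.*$", "", name)
  switch(kind,
         N = p >= 0,
         mu = {
           w <- window_bounds(tis)
           p >= w["lo"] & p <= w["hi"]
         },
         sigma = p >= 0.7 & p <= 110,
         alpha = abs(p) <= 9)
}

# internal: draw n values of one parameter around centers, rejecting invalid
draw_valid <- function(center, sd, name, max_attempts = 1000) {
  x <- rnorm(length(center), center, sd)
  bad <- !param_ok(x, name)
  attempts <- 0
  while (any(bad)) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("could not draw valid '", name, "' after ", max_attempts,
           " attempts; widen the window or shrink jitter/trend SDs",
           call. = FALSE)
    x[bad] <- rnorm(sum(bad), center[bad], sd[if (length(sd) > 1) bad else 1])
    bad <- !param_ok(x, name)
  }
  x
}

# internal: n draws from one skewed mode, truncated to [-200, 200]
rmode_truncated <- function(n, mu, sigma, alpha, max_attempts = 1000) {
  if (n == 0) return(list(x = numeric(0), truncated = 0L))
  lambda <- -alpha
  delta <- lambda / sqrt(1 + lambda^2)
  draw <- function(m) {
    z0 <- abs(rnorm(m)); z1 <- rnorm(m)
    mu + sigma * (delta * z0 + sqrt(1 - delta^2) * z1)
  }
  x <- draw(n)
  truncated <- 0L
  bad <- x < -200.5 | x >= 200.5
  attempts <- 0
  while (any(bad)) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("mode mass lies almost entirely outside [-200, 200] HU",
           call. = FALSE)
    truncated <- truncated + sum(bad)
    x[bad] <- draw(sum(bad))
    bad <- x < -200.5 | x >= 200.5
  }
  list(x = x, truncated = truncated)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws, per subject: a uniform integer age; left-leg model parameters as
#' the configured base plus Gaussian between-subject jitter (rejection keeps
#' locations inside their tissue windows); right-leg parameters as left plus
#' a zero-mean Gaussian whose scale is set so that the *expected absolute*
#' difference follows the configured age trend (for `X ~ N(0, s)`,
#' `E|X| = s * sqrt(2/pi)`); per-leg HU histograms by drawing Poisson
#' pixel counts per mode and skew-normal HU values truncated to
#' `[-200, 200]`; and BMI / gait / TUG outcomes from linear (log-linear for
#' TUG) models in age and true muscle-width asymmetry, with configured
#' missingness.  Everything is deterministic under the configured seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `ntra_cohort`: list with
#'   \describe{
#'     \item{cohort}{tibble `subject_id`, `age`, `sex`, `bmi`, `v_norm`,
#'       `v_fast`, `tug` plus the four class-label columns.}
#'     \item{truth}{tibble `subject_id`, `side`, the 11 true parameters per
#'       leg (the recovery oracle).}
#'     \item{histograms}{tibble `subject_id`, `side`, `bin_center`, `count`
#'       (`NULL` when `sampling_mass = 0`).}
#'     \item{truncated}{number of HU draws redrawn for falling outside the
#'       soft-tissue range.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 20, sampling_mass = 0, seed = 1)
#' coh <- generate_cohort(cfg)
#' coh$cohort
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ntra_cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  pn <- ntra_parameter_names()
  ids <- sprintf("S%04d", seq_len(n))
  ages <- sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE)
  sex <- ifelse(runif(n) < 0.58, "female", "male")

  # amplitude rescaling so histogram mass tracks sampling_mass
  base <- config$base_params
  jit <- config$jitter_sd
  trend <- config$asymmetry_trend
  n_par <- c("N_fat", "N_con", "N_mus")
  if (config$sampling_mass > 0) {
    f <- config$sampling_mass / sum(base[n_par])
    base[n_par] <- base[n_par] * f
    jit[n_par] <- jit[n_par] * f
    trend[n_par] <- purrr::map(trend[n_par], ~ .x * f)
  }

  left <- purrr::map(pn, function(p) {
    draw_valid(rep(base[p], n), jit[p], p)
  }) |> setNames(pn)
  right <- purrr::map(pn, function(p) {
    e_abs <- trend_value(trend[[p]], ages, config$age_range)
    s <- e_abs * sqrt(pi / 2)   # E|N(0, s)| = s * sqrt(2/pi)
    if (all(s == 0)) left[[p]] else draw_valid(left[[p]], s, p)
  }) |> setNames(pn)

  truth <- dplyr::bind_rows(
    tibble::tibble(subject_id = ids, side = "L", !!!left),
    tibble::tibble(subject_id = ids, side = "R", !!!right)) |>
    dplyr::arrange(.data$subject_id, .data$side)

  # outcomes, linked to the true muscle-width asymmetry
  d_sigma_mus <- abs(left$sigma_mus - right$sigma_mus)
  om <- config$outcome_model
  lin <- function(m) {
    m$intercept + m$age_coef * (ages - config$age_range[1]) +
      m$asym_coef * d_sigma_mus + rnorm(n, 0, m$sd)
  }
  bmi <- rnorm(n, om$bmi$intercept, om$bmi$sd)
  while (any(bmi < 13))   # keep BMI physiologically plausible
    bmi[bmi < 13] <- rnorm(sum(bmi < 13), om$bmi$intercept, om$bmi$sd)
  v_norm <- pmax(lin(om$v_norm), 0.05)
  v_fast <- pmax(lin(om$v_fast), 0.05)
  tug <- exp(lin(om$tug))
  miss <- function(x, rate) {
    x[runif(n) < rate] <- NA_real_
    x
  }
  v_norm <- miss(v_norm, config$missingness[["v_norm"]])
  v_fast <- miss(v_fast, config$missingness[["v_fast"]])
  tug <- miss(tug, config$missingness[["tug"]])

  cohort <- tibble::tibble(subject_id = ids, age = as.integer(ages),
                           sex = sex, bmi = bmi, v_norm = v_norm,
                           v_fast = v_fast, tug = tug) |>
    add_class_labels()

  # histograms
  histograms <- NULL
  truncated <- 0L
  if (config$sampling_mass > 0) {
    modes <- list(
      fat = c("N_fat", "mu_fat", "sigma_fat", "alpha_fat"),
      con = c("N_con", "mu_con", "sigma_con", NA),
      mus = c("N_mus", "mu_mus", "sigma_mus", "alpha_mus"))
    histograms <- truth |>
      dplyr::group_by(.data$subject_id, .data$side) |>
      dplyr::group_modify(function(d, key) {
        vals <- purrr::map(modes, function(m) {
          k <- rpois(1, d[[m[1]]])
          rmode_truncated(k, d[[m[2]]], d[[m[3]]],
                          if (is.na(m[4])) 0 else d[[m[4]]])
        })
        truncated <<- truncated + sum(purrr::map_int(vals, "truncated"))
        bin_hu(unlist(purrr::map(vals, "x")))
      }) |>
      dplyr::ungroup()
  }

  structure(list(cohort = cohort, truth = truth, histograms = histograms,
                 truncated = truncated, config = config),
            class = "ntra_cohort")
}

#' @export
print.ntra_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "subjects, ages",
      min(x$cohort$age), "-", max(x$cohort$age), "\n")
  cat("  histograms:",
      if (is.null(x$histograms)) "none (parameter-level cohort)"
      else paste0("sampled (", x$truncated, " HU draws redrawn at truncation)"),
      "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Ground-truth ledger of a synthetic cohort
#'
#' One row per subject with the true parameters of both legs, the true
#' asymmetry vector and the generated class labels — the oracle that
#' recovery tests compare pipeline output against.
#'
#' @param cohort An `ntra_cohort` from [generate_cohort()].
#' @return Tibble: `subject_id`, `age`, `sex`, `L_<parameter>` and
#'   `R_<parameter>` for the 11 parameters, `delta_<parameter>` true
#'   asymmetry, and the four class-label columns.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "ntra_cohort"))
  pn <- ntra_parameter_names()
  wide <- cohort$truth |>
    tidyr::pivot_longer(dplyr::all_of(pn), names_to = "parameter") |>
    tidyr::pivot_wider(names_from = c("side", "parameter"),
                       values_from = "value", names_glue = "{side}_{parameter}")
  for (p in pn) wide[[paste0("delta_", p)]] <-
      abs(wide[[paste0("L_", p)]] - wide[[paste0("R_", p)]])
  cohort$cohort |>
    dplyr::select("subject_id", "age", "sex", "bmi_class",
                  "gait_normal_class", "gait_fast_class", "tug_class") |>
    dplyr::inner_join(wide, by = "subject_id")
}
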