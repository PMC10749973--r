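#' Paired left-right t-test for one model parameter
#'
#' Two-sided paired t-test on per-subject differences `d = left - right`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, p-value from Student's t with `n - 1`
#' degrees of freedom, plus side-wise means and sample SDs for tabular
#' reporting.  If every difference is zero the statistic is undefined; the
#' result row is returned with `t_stat` and `p_value` set to `NA` and
#' `undefined = TRUE` rather than raising an error.
#'
#' @param left,right Numeric vectors of equal length (n >= 2), one value per
#'   subject.
#' @return One-row tibble: `mean_left`, `sd_left`, `mean_right`, `sd_right`,
#'   `t_stat`, `p_value`, `n`, `undefined`.
#' @export
#' @examples
#' paired_ttest(c(1, 2, 3, 4), c(1.1, 2.4, 2.9, 4.2))
paired_ttest <- function(left, right) {
  if (length(left) != length(right))
    stop("left and right must have equal length", call. = FALSE)
  ok <- is.finite(left) & is.finite(right)
  left <- left[ok]; right <- right[ok]
  n <- length(left)
  if (n < 2L) stop("paired t-test needs at least 2 complete pairs",
                   call. = FALSE)
  d <- left - right
  base <- tibble::tibble(
    mean_left = mean(left), sd_left = sd(left),
    mean_right = mean(right), sd_right = sd(right), n = n)
  if (sd(d) == 0) {
    dplyr::mutate(base, t_stat = NA_real_, p_value = NA_real_,
                  undefined = TRUE) |>
      dplyr::select("mean_left", "sd_left", "mean_right", "sd_right",
                    "t_stat", "p_value", "n", "undefined")
  } else {
    tt <- t.test(left, right, paired = TRUE)
    dplyr::mutate(base, t_stat = unname(tt$statistic),
                  p_value = tt$p.value, undefined = FALSE) |>
      dplyr::select("mean_left", "sd_left", "mean_right", "sd_right",
                    "t_stat", "p_value", "n", "undefined")
  }
}

#' Paired left-right tests for all 11 model parameters
#'
#' Runs [paired_ttest()] on each canonical parameter of a per-leg parameter
#' table, producing the tissue-by-parameter summary layout (mean and SD per
#' side, t, p).  P-values are reported raw, without multiple-testing
#' correction.
#'
#' @param fits Per-leg parameter table (as for [compute_asymmetry()]).
#' @return Tibble with one row per parameter: `tissue`, `parameter`, the
#'   [paired_ttest()] columns.
#' @export
ntra_paired_tests <- function(fits) {
  pn <- ntra_parameter_names()
  stopifnot(all(c("subject_id", "side", pn) %in% names(fits)))
  wide <- fits |>
    dplyr::select(dplyr::all_of(c("subject_id", "side", pn))) |>
    tidyr::pivot_longer(dplyr::all_of(pn), names_to = "parameter") |>
    tidyr::pivot_wider(names_from = "side", values_from = "value")
  purrr::map_dfr(pn, function(p) {
    d <- dplyr::filter(wide, .data$parameter == p)
    dplyr::mutate(paired_ttest(d$L, d$R), parameter = p, .before = 1)
  }) |>
    dplyr::inner_join(ntra_parameter_tissues(), by = "parameter") |>
    dplyr::select("tissue", "parameter", dplyr::everything())
}

#' BMI class (1-4)
#'
#' Body-mass-index classes: below-normal (< 18.5), normal (18.5-25),
#' above-normal (25-30), overweight (>= 30 kg/m^2).  Boundary values are
#' assigned to the upper class (lower-inclusive intervals).
#'
#' @param bmi Numeric vector, kg/m^2, positive; `NA` stays `NA`.
#' @return Integer vector of classes 1-4.
#' @export
#' @examples
#' classify_bmi(c(17, 22, 27, 33, 25))   # 1 2 3 4 3
classify_bmi <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE))
    stop("BMI must be positive", call. = FALSE)
  cls <- ifelse(bmi < 18.5, 1L, ifelse(bmi < 25, 2L, ifelse(bmi < 30, 3L, 4L)))
  as.integer(cls)
}

#' Normal gait-speed class
#'
#' Self-selected 6-m walking speed, thresholded at 1.0 m/s: `"slow"` below,
#' `"normal"` at or above (boundary assigned upward).
#'
#' @param v Numeric vector of speeds (m/s, non-negative); `NA` stays `NA`
#'   (unclassified, excluded from stratifications).
#' @return Character vector `"slow"`/`"normal"`.
#' @export
#' @examples
#' classify_gait_normal(c(0.9, 1.0, 1.2))   # "slow" "normal" "normal"
classify_gait_normal <- function(v) {
  if (any(v < 0, na.rm = TRUE)) stop("gait speed must be >= 0", call. = FALSE)
  ifelse(is.na(v), NA_character_, ifelse(v < 1.0, "slow", "normal"))
}

#' Fast gait-speed class
#'
#' Maximum 6-m walking speed, thresholded at 1.3 m/s: `"slow"` below,
#' `"normal"` at or above.
#'
#' @inheritParams classify_gait_normal
#' @return Character vector `"slow"`/`"normal"`.
#' @export
#' @examples
#' classify_gait_fast(c(1.2, 1.3, 1.4))   # "slow" "normal" "normal"
classify_gait_fast <- function(v) {
  if (any(v < 0, na.rm = TRUE)) stop("gait speed must be >= 0", call. = FALSE)
  ifelse(is.na(v), NA_character_, ifelse(v < 1.3, "slow", "normal"))
}

#' Timed-up-and-go class (1-4)
#'
#' TUG completion time classes: fast (< 10 s), average (10-13 s), slow
#' (13-29 s), very slow (>= 29 s); boundaries lower-inclusive.
#'
#' @param tug Numeric vector of times (seconds, positive); `NA` stays `NA`.
#' @return Integer vector of classes 1-4.
#' @export
#' @examples
#' classify_tug(c(9, 11, 15, 35, 13, 29))   # 1 2 3 4 3 4
classify_tug <- function(tug) {
  if (any(tug <= 0, na.rm = TRUE)) stop("TUG time must be positive",
                                        call. = FALSE)
  cls <- ifelse(tug < 10, 1L, ifelse(tug < 13, 2L, ifelse(tug < 29, 3L, 4L)))
  as.integer(cls)
}

#' Attach all mobility and BMI class labels to a cohort table
#'
#' @param cohort Cohort table with columns `bmi`, `v_norm`, `v_fast`, `tug`
#'   (any may hold `NA`).
#' @return The cohort with added columns `bmi_class`, `gait_normal_class`,
#'   `gait_fast_class`, `tug_class`.
#' @export
add_class_labels <- function(cohort) {
  dplyr::mutate(
    cohort,
    bmi_class = classify_bmi(.data$bmi),
    gait_normal_class = classify_gait_normal(.data$v_norm),
    gait_fast_class = classify_gait_fast(.data$v_fast),
    tug_class = classify_tug(.data$tug))
}

#' Demographic summary per class
#'
#' Per class of the chosen grouping: subject count, mean and sample SD of
#' age, and counts per sex — the usual cohort-characteristics table shape.
#' Subjects with a missing class label are summarised as their own `NA` row.
#'
#' @param cohort Cohort table with `age`, `sex` and the grouping column.
#' @param group Name of the class-label column (string).
#' @return Tibble: `group` value, `n`, `age_mean`, `age_sd`, `n_male`,
#'   `n_female`.
#' @export
cohort_summary <- function(cohort, group) {
  stopifnot(group %in% names(cohort))
  cohort |>
    dplyr::group_by(group = .data[[group]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mean(.data$age),
      age_sd = sd(.data$age),
      n_male = sum(.data$sex == "male"),
      n_female = sum(.data$sex == "female"),
      .groups = "drop")
}
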