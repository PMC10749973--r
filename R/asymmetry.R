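#' Left-right asymmetry indicators from per-leg model parameters
#'
#' For each subject with both legs fitted, the 11 asymmetry indicators are
#' the absolute left-minus-right differences of the canonical parameters.
#' They are symmetric in leg order by construction.  Subjects lacking one
#' side are dropped with a message.
#'
#' @param fits Per-leg parameter table: columns `subject_id`, `side`
#'   (`"L"`/`"R"`) and the 11 canonical parameters, e.g. from
#'   [fit_ntra_cohort()] or the `truth` table of [generate_cohort()].
#' @return A tibble with `subject_id` and the 11 indicator columns (named as
#'   the parameters; all values are non-negative absolute differences).
#' @export
#' @examples
#' fits <- tibble::tribble(
#'   ~subject_id, ~side, ~N_fat, ~mu_fat, ~sigma_fat, ~alpha_fat,
#'     ~N_con, ~mu_con, ~sigma_con, ~N_mus, ~mu_mus, ~sigma_mus, ~alpha_mus,
#'   "s1", "L", 135.16, -65, 30, 0.5, 90, 20, 15, 184.84, 55, 12, 3.09,
#'   "s1", "R", 137.48, -64, 31, 0.5, 91, 20, 15, 186.41, 55, 12, 3.15)
#' compute_asymmetry(fits)   # N_fat indicator = |135.16 - 137.48| = 2.32
compute_asymmetry <- function(fits) {
  pn <- ntra_parameter_names()
  stopifnot(all(c("subject_id", "side", pn) %in% names(fits)))
  sides <- fits |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n != 2L)
  if (nrow(sides))
    message("dropping ", nrow(sides),
            " subject(s) without exactly one histogram per side: ",
            paste(utils::head(sides$subject_id, 5), collapse = ", "),
            if (nrow(sides) > 5) ", ..." else "")
  fits |>
    dplyr::filter(!.data$subject_id %in% sides$subject_id) |>
    dplyr::select(dplyr::all_of(c("subject_id", "side", pn))) |>
    tidyr::pivot_longer(dplyr::all_of(pn), names_to = "parameter") |>
    tidyr::pivot_wider(names_from = "side", values_from = "value") |>
    dplyr::mutate(delta = abs(.data$L - .data$R)) |>
    dplyr::select("subject_id", "parameter", "delta") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "delta") |>
    dplyr::select(dplyr::all_of(c("subject_id", pn)))
}

#' Min-max rescale one indicator across the cohort
#'
#' Maps values to `(v - min) / (max - min)`, so the least asymmetric subject
#' scores 0 and the most asymmetric 1.  A constant indicator (max equal to
#' min) is degenerate: all outputs are defined as 0 and a warning is raised,
#' so a perfectly symmetric cohort still flows through the pipeline.
#'
#' @param x Numeric vector (at least 2 values; `NA`s propagate).
#' @return Numeric vector in `[0, 1]` with attributes `min` and `max`
#'   recording the scale used.
#' @export
#' @examples
#' minmax_scale(c(2, 4, 6))   # 0, 0.5, 1
minmax_scale <- function(x) {
  if (sum(is.finite(x)) < 2L)
    stop("min-max normalization needs at least 2 finite values",
         call. = FALSE)
  lo <- min(x, na.rm = TRUE)
  hi <- max(x, na.rm = TRUE)
  if (hi == lo) {
    warning("degenerate indicator: max equals min; normalized values set to 0",
            call. = FALSE)
    out <- ifelse(is.na(x), NA_real_, 0)
  } else {
    out <- (x - lo) / (hi - lo)
  }
  attr(out, "min") <- lo
  attr(out, "max") <- hi
  out
}

#' Normalize all 11 asymmetry indicators across the cohort
#'
#' Applies [minmax_scale()] column-wise.  Normalization is computed once on
#' the full analysis cohort; stratified analyses reuse this cohort-wide
#' scale rather than re-normalizing within groups.
#'
#' @param asymmetry Indicator table from [compute_asymmetry()].
#' @return A tibble like `asymmetry` with values in `[0, 1]`, carrying a
#'   `scale` attribute (tibble of `parameter`, `min`, `max`) for
#'   reproducibility.
#' @export
normalize_indicators <- function(asymmetry) {
  pn <- ntra_parameter_names()
  stopifnot(all(c("subject_id", pn) %in% names(asymmetry)))
  scaled <- purrr::map(asymmetry[pn], minmax_scale)
  out <- tibble::tibble(subject_id = asymmetry$subject_id,
                        !!!purrr::map(scaled, as.numeric))
  attr(out, "scale") <- tibble::tibble(
    parameter = pn,
    min = purrr::map_dbl(scaled, attr, "min"),
    max = purrr::map_dbl(scaled, attr, "max"))
  out
}

#' Average normalized indicators within each year of age
#'
#' For each indicator and each integer age present in the cohort, the
#' arithmetic mean over the subjects of that age.  Ages with no subjects are
#' absent from the output, not zero-filled.
#'
#' @param normalized Normalized indicator table ([normalize_indicators()]),
#'   or any table with `subject_id` plus indicator columns.
#' @param cohort Table with `subject_id` and integer `age` (years).
#' @return Long tibble: `parameter`, `age`, `value` (mean), `n` (subjects of
#'   that age contributing).
#' @export
age_average <- function(normalized, cohort) {
  pn <- intersect(ntra_parameter_names(), names(normalized))
  stopifnot(length(pn) > 0, all(c("subject_id", "age") %in% names(cohort)))
  if (any(cohort$age %% 1 != 0, na.rm = TRUE))
    stop("ages must be integer years", call. = FALSE)
  normalized |>
    dplyr::inner_join(dplyr::select(cohort, "subject_id", "age"),
                      by = "subject_id") |>
    tidyr::pivot_longer(dplyr::all_of(pn), names_to = "parameter") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$parameter, .data$age) |>
    dplyr::summarise(value = mean(.data$value), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$parameter, pn), .data$age)
}

#' Cubic age-trend fit of age-averaged indicator series
#'
#' Ordinary least-squares third-order polynomial of mean indicator value on
#' age, fitted separately per indicator, unweighted.  `r_squared` is
#' `1 - SSE/SST`; a constant series (SST = 0) gets `r_squared = 0` with a
#' warning.  Fewer than 4 distinct ages cannot identify a cubic and is an
#' error.
#'
#' @param series Long series from [age_average()] (columns `age`, `value`,
#'   optionally `parameter`; a `parameter` column triggers per-indicator
#'   fits).
#' @return A tibble with one row per indicator: `parameter` (if present),
#'   coefficients `b0`..`b3` (ascending degree), `r_squared`, `n_points`.
#' @export
#' @examples
#' s <- tibble::tibble(age = 71:98, value = 1 + 0.001 * (71:98)^3)
#' fit_cubic_trend(s)$r_squared   # 1
fit_cubic_trend <- function(series) {
  stopifnot(all(c("age", "value") %in% names(series)))
  fit_one <- function(d) {
    if (length(unique(d$age)) < 4L)
      stop("cubic trend needs at least 4 distinct ages", call. = FALSE)
    m <- lm(value ~ age + I(age^2) + I(age^3), data = d)
    sse <- sum(residuals(m)^2)
    sst <- sum((d$value - mean(d$value))^2)
    r2 <- if (sst == 0) {
      warning("constant series: total sum of squares is 0; R^2 set to 0",
              call. = FALSE)
      0
    } else 1 - sse / sst
    tibble::tibble(b0 = unname(coef(m)[1]), b1 = unname(coef(m)[2]),
                   b2 = unname(coef(m)[3]), b3 = unname(coef(m)[4]),
                   r_squared = r2, n_points = nrow(d))
  }
  if ("parameter" %in% names(series)) {
    series |>
      dplyr::group_by(.data$parameter) |>
      dplyr::group_modify(~ fit_one(.x)) |>
      dplyr::ungroup() |>
      dplyr::arrange(match(.data$parameter, ntra_parameter_names()))
  } else {
    fit_one(series)
  }
}

#' Evaluate a fitted cubic age trend
#'
#' @param trend One row of a [fit_cubic_trend()] table.
#' @param ages Numeric vector of ages (years).
#' @return Trend values at `ages`.
#' @export
eval_cubic <- function(trend, ages) {
  trend$b0 + trend$b1 * ages + trend$b2 * ages^2 + trend$b3 * ages^3
}

#' Pick the most age-varying indicator per tissue
#'
#' Among each tissue's indicators (four for fat and muscle, three for
#' connective tissue), selects the one whose cubic age trend has the highest
#' coefficient of determination.  Exact ties are broken by the canonical
#' parameter order (N, mu, sigma, alpha) and flagged.
#'
#' @param trends Trend table from [fit_cubic_trend()] with a `parameter`
#'   column covering all 11 indicators.
#' @return A tibble with one row per tissue: `tissue`, `parameter`,
#'   `r_squared`, `tie` (logical: was the maximum attained more than once).
#' @export
select_top_indicators <- function(trends) {
  stopifnot(all(ntra_parameter_names() %in% trends$parameter))
  trends |>
    dplyr::inner_join(ntra_parameter_tissues(), by = "parameter") |>
    dplyr::mutate(rank = match(.data$parameter, ntra_parameter_names())) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::arrange(dplyr::desc(.data$r_squared), .data$rank,
                   .by_group = TRUE) |>
    dplyr::summarise(tie = sum(.data$r_squared == max(.data$r_squared)) > 1L,
                     parameter = .data$parameter[1],
                     r_squared = .data$r_squared[1],
                     .groups = "drop") |>
    dplyr::select("tissue", "parameter", "r_squared", "tie") |>
    dplyr::arrange(match(.data$tissue, c("fat", "con", "mus")))
}

#' Stratified age trends of selected indicators
#'
#' Splits the cohort by a class-label column (BMI, gait or TUG classes from
#' [add_class_labels()]), then age-averages and cubic-fits the selected
#' indicators within each stratum.  The cohort-wide normalization is reused:
#' strata are compared on a common `[0, 1]` scale.  Subjects with a missing
#' class label are excluded from this stratification only.  A stratum with
#' fewer than 4 distinct ages is kept in the series output but marked
#' unfittable.
#'
#' @param cohort Cohort table with `subject_id`, `age` and the grouping
#'   column.
#' @param normalized Cohort-wide normalized indicators
#'   ([normalize_indicators()]).
#' @param group Name of the class-label column in `cohort` (string).
#' @param parameters Indicator names to analyse; defaults to all present.
#' @return An object of class `ntra_grouped_trends`: list with `series`
#'   (tibble `group`, `parameter`, `age`, `value`, `n`) and `trends` (tibble
#'   `group`, `parameter`, `b0`..`b3`, `r_squared`, `n_points`, `fittable`).
#' @export
grouped_trends <- function(cohort, normalized, group,
                           parameters = intersect(ntra_parameter_names(),
                                                  names(normalized))) {
  stopifnot(group %in% names(cohort))
  keep <- cohort |>
    dplyr::filter(!is.na(.data[[group]])) |>
    dplyr::select("subject_id", "age", group_label = dplyr::all_of(group))
  n_dropped <- nrow(cohort) - nrow(keep)
  if (n_dropped > 0)
    message(n_dropped, " subject(s) missing '", group,
            "' excluded from this stratification")
  norm_sel <- normalized[, c("subject_id", parameters)]
  series <- keep |>
    dplyr::group_by(.data$group_label) |>
    dplyr::group_modify(function(d, key) {
      age_average(norm_sel, dplyr::select(d, "subject_id", "age"))
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(group = "group_label")
  trends <- series |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$age)) < 4L)
        return(tibble::tibble(b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                              b3 = NA_real_, r_squared = NA_real_,
                              n_points = nrow(d), fittable = FALSE))
      dplyr::mutate(fit_cubic_trend(d), fittable = TRUE)
    }) |>
    dplyr::ungroup()
  structure(list(series = series, trends = trends, group = group),
            class = "ntra_grouped_trends")
}

#' @export
print.ntra_grouped_trends <- function(x, ...) {
  cat("Stratified age trends by '", x$group, "' (",
      length(unique(x$series$group)), " strata)\n", sep = "")
  print(x$trends)
  invisible(x)
}

#' @rdname grouped_trends
#' @param object An `ntra_grouped_trends` object.
#' @param ... Unused.
#' @export
autoplot.ntra_grouped_trends <- function(object, ...) {
  ages <- seq(min(object$series$age), max(object$series$age), by = 0.25)
  curves <- object$trends |>
    dplyr::filter(.data$fittable) |>
    purrr::pmap_dfr(function(group, parameter, b0, b1, b2, b3, ...) {
      tibble::tibble(group = group, parameter = parameter, age = ages,
                     value = b0 + b1 * ages + b2 * ages^2 + b3 * ages^3)
    })
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$age, y = .data$value,
                               colour = factor(.data$group))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curves) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "mean normalized asymmetry",
                  colour = object$group)
}
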