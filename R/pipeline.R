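#' Run the full left-right asymmetry workflow
#'
#' Chains the analysis blocks end to end: (1) per-leg model parameters —
#' either supplied directly or fitted from histograms with [fit_ntra_cohort()];
#' (2) paired left-right t-tests per parameter; (3) the 11 absolute
#' asymmetry indicators; (4) cohort-wide min-max normalization; (5) per-age
#' averaging; (6) cubic age-trend fits; (7) R-squared based selection of the
#' most age-varying indicator per tissue; (8) stratified trends of the
#' selected indicators across the requested class labels.  Class labels are
#' (re)computed from `bmi`, `v_norm`, `v_fast`, `tug` if absent.
#'
#' @param cohort Cohort table (`subject_id`, `age`, `sex`, `bmi`, `v_norm`,
#'   `v_fast`, `tug`, optional class labels), or an `ntra_cohort` object
#'   from [generate_cohort()] — in which case its histograms (if sampled)
#'   or ground-truth parameters are used automatically.
#' @param histograms Optional long histogram table (see
#'   [fit_ntra_cohort()]); ignored when `params` is given.
#' @param params Optional per-leg parameter table (skips fitting).
#' @param groupings Class-label columns to stratify by.
#' @param out_dir Optional directory: all artifacts (fit results, t-tests,
#'   indicators, trends JSON, per-grouping trends JSON, run configuration)
#'   are written there as CSV/JSON.
#' @param fit_options Named list passed to [fit_ntra()].
#' @return An object of class `ntra_analysis`: list with `fits`, `ttests`,
#'   `asymmetry`, `normalized`, `series`, `trends`, `selected`, `grouped`
#'   (named list of [grouped_trends()] results), and `cohort` (with class
#'   labels).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 60, sampling_mass = 0,
#'                                      seed = 7))
#' res <- run_asymmetry_pipeline(coh, groupings = "gait_fast_class")
#' res$selected
run_asymmetry_pipeline <- function(cohort, histograms = NULL, params = NULL,
                                   groupings = c("bmi_class",
                                                 "gait_normal_class",
                                                 "gait_fast_class",
                                                 "tug_class"),
                                   out_dir = NULL, fit_options = list()) {
  if (inherits(cohort, "ntra_cohort")) {
    if (is.null(params) && is.null(histograms)) {
      if (!is.null(cohort$histograms)) histograms <- cohort$histograms
      else params <- cohort$truth
    }
    cohort <- cohort$cohort
  }
  stopifnot(all(c("subject_id", "age") %in% names(cohort)))
  if (!all(groupings %in% names(cohort)) &&
      all(c("bmi", "v_norm", "v_fast", "tug") %in% names(cohort)))
    cohort <- add_class_labels(cohort)
  missing_groups <- setdiff(groupings, names(cohort))
  if (length(missing_groups))
    stop("grouping column(s) not in cohort: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)

  if (is.null(params)) {
    if (is.null(histograms))
      stop("supply either histograms or a per-leg parameter table",
           call. = FALSE)
    unknown <- setdiff(unique(histograms$subject_id), cohort$subject_id)
    if (length(unknown))
      stop("histogram subject id(s) absent from cohort table: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    params <- do.call(fit_ntra_cohort, c(list(histograms), fit_options))
  }

  ttests <- ntra_paired_tests(params)
  asym <- compute_asymmetry(params)
  normalized <- normalize_indicators(asym)
  series <- age_average(normalized, cohort)
  trends <- fit_cubic_trend(series)
  selected <- select_top_indicators(trends)
  grouped <- purrr::map(setNames(groupings, groupings), function(g) {
    grouped_trends(cohort, normalized, g, parameters = selected$parameter)
  })

  res <- structure(
    list(fits = params, ttests = ttests, asymmetry = asym,
         normalized = normalized, series = series, trends = trends,
         selected = selected, grouped = grouped, cohort = cohort),
    class = "ntra_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fit_results(params, file.path(out_dir, "fit_results.csv"))
    readr::write_csv(ttests, file.path(out_dir, "paired_ttests.csv"))
    sc <- attr(normalized, "scale")
    ind <- dplyr::inner_join(
      asym,
      dplyr::rename_with(normalized, ~ paste0("n_", .x),
                         dplyr::all_of(ntra_parameter_names())),
      by = "subject_id")
    write_indicators(ind, file.path(out_dir, "indicators.csv"))
    readr::write_csv(sc, file.path(out_dir, "normalization_scale.csv"))
    readr::write_csv(series, file.path(out_dir, "age_series.csv"))
    write_trends_json(trends, file.path(out_dir, "trends.json"))
    readr::write_csv(selected, file.path(out_dir, "selected_indicators.csv"))
    for (g in groupings)
      write_trends_json(res$grouped[[g]],
                        file.path(out_dir, paste0("trends_", g, ".json")))
    write_cohort(cohort, file.path(out_dir, "cohort_labelled.csv"))
  }
  res
}

#' @export
print.ntra_analysis <- function(x, ...) {
  cat("Left-right asymmetry analysis of", nrow(x$asymmetry), "subjects\n")
  cat("Selected indicators (highest cubic-trend R^2 per tissue):\n")
  print(x$selected)
  invisible(x)
}

#' @rdname run_asymmetry_pipeline
#' @param object An `ntra_analysis` object.
#' @param ... Unused.
#' @export
autoplot.ntra_analysis <- function(object, ...) {
  sel <- object$series |>
    dplyr::filter(.data$parameter %in% object$selected$parameter)
  ages <- seq(min(sel$age), max(sel$age), by = 0.25)
  curves <- object$trends |>
    dplyr::filter(.data$parameter %in% object$selected$parameter) |>
    purrr::pmap_dfr(function(parameter, b0, b1, b2, b3, ...) {
      tibble::tibble(parameter = parameter, age = ages,
                     value = b0 + b1 * ages + b2 * ages^2 + b3 * ages^3)
    })
  ggplot2::ggplot(sel, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves, colour = "red") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "mean normalized asymmetry")
}
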