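#' Read and write the pipeline's tabular artifacts
#'
#' All artifacts are plain UTF-8, comma-separated, header-row CSV with `.`
#' decimal and empty fields for missing values.
#'
#' * **Histogram CSV** — `subject_id`, `side` (`L`/`R`), `bin_center`
#'   (integer HU), `count`.
#' * **Cohort CSV** — `subject_id`, `age`, `sex`, `bmi`, `v_norm`, `v_fast`,
#'   `tug` (class-label columns are accepted and preserved).
#' * **Fit-result CSV** — `subject_id`, `side`, the 11 canonical parameters,
#'   `residual_sse`, `converged`.
#' * **Indicator CSV** — `subject_id` plus the 11 raw and/or normalized
#'   indicator columns.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name ntrasym-io
NULL

# internal: read a CSV and insist on named columns
read_checked <- function(path, required, col_types) {
  out <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop(basename(path), ": missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  out
}

#' @rdname ntrasym-io
#' @export
read_histograms <- function(path) {
  h <- read_checked(path, c("subject_id", "side", "bin_center", "count"),
                    readr::cols(subject_id = "c", side = "c",
                                bin_center = "i", count = "d"))
  bad <- !h$side %in% c("L", "R")
  if (any(bad))
    stop(basename(path), ": side must be 'L' or 'R' (first bad row: ",
         which(bad)[1], ")", call. = FALSE)
  h
}

#' @rdname ntrasym-io
#' @export
write_histograms <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname ntrasym-io
#' @export
read_cohort <- function(path) {
  read_checked(path, c("subject_id", "age", "sex", "bmi",
                       "v_norm", "v_fast", "tug"),
               readr::cols(subject_id = "c", age = "i", sex = "c",
                           .default = "d"))
}

#' @rdname ntrasym-io
#' @export
write_cohort <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname ntrasym-io
#' @export
read_fit_results <- function(path) {
  read_checked(path, c("subject_id", "side", ntra_parameter_names()),
               readr::cols(subject_id = "c", side = "c",
                           converged = "l", .default = "d"))
}

#' @rdname ntrasym-io
#' @export
write_fit_results <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname ntrasym-io
#' @export
read_indicators <- function(path) {
  read_checked(path, "subject_id",
               readr::cols(subject_id = "c", .default = "d"))
}

#' @rdname ntrasym-io
#' @export
write_indicators <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Write cubic-trend fits (optionally stratified) as JSON
#'
#' Per indicator: ascending-degree coefficients, R-squared and the number of
#' age points; stratified results are nested by group label.
#'
#' @param trends A trend tibble from [fit_cubic_trend()] or an
#'   `ntra_grouped_trends` object.
#' @param path Output path.
#' @return `trends`, invisibly.
#' @export
write_trends_json <- function(trends, path) {
  row_to_list <- function(d) {
    list(coefficients = c(d$b0, d$b1, d$b2, d$b3),
         r_squared = d$r_squared, n_points = d$n_points)
  }
  tab_to_list <- function(tab) {
    out <- lapply(seq_len(nrow(tab)), function(i) row_to_list(tab[i, ]))
    names(out) <- tab$parameter
    out
  }
  obj <- if (inherits(trends, "ntra_grouped_trends")) {
    split(trends$trends, trends$trends$group) |> lapply(tab_to_list)
  } else {
    tab_to_list(trends)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(trends)
}

#' @rdname write_trends_json
#' @export
read_trends_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_tab <- function(lst) {
    purrr::imap_dfr(lst, function(d, p) {
      cf <- unlist(d$coefficients)
      tibble::tibble(parameter = p, b0 = cf[1], b1 = cf[2], b2 = cf[3],
                     b3 = cf[4], r_squared = d$r_squared,
                     n_points = d$n_points)
    })
  }
  if (all(purrr::map_lgl(raw, ~ is.list(.x) && !"coefficients" %in% names(.x))))
    purrr::imap_dfr(raw, function(g, nm) dplyr::mutate(to_tab(g), group = nm,
                                                       .before = 1))
  else to_tab(raw)
}
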