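#' Fit the trimodal radiodensity model to one HU histogram
#'
#' Minimizes the sum over the 401 unit-width bins of squared residuals
#' between the histogram counts and [dntra()] evaluated at the bin centers,
#' by box-constrained Levenberg-Marquardt nonlinear least squares
#' ([minpack.lm::nls.lm()]).  Ten parameters are free; the connective-mode
#' skewness is fixed at 0.  Box constraints keep each location inside its
#' tissue window, widths in `[sigma_min, sigma_max]`, skewness in
#' `[-alpha_max, alpha_max]` and amplitudes in `[0, 10 * total mass]`.
#'
#' When a tissue window holds no mass (e.g. very lean or very obese
#' extremes) the fit still proceeds and that mode's amplitude is free to
#' reach 0.  A histogram with fewer than three occupied bins cannot identify
#' the model; the fit returns with `converged = FALSE` and a warning.
#'
#' @param hist Histogram table with columns `bin_center` (integer HU,
#'   subset of -200..200) and `count` (non-negative), e.g. from [bin_hu()].
#' @param init Optional named vector of 11 starting parameters.  By default,
#'   deterministic window-local moments: per tissue window, the window mass,
#'   mass centroid and mass standard deviation (floored at 2 HU), with zero
#'   skewness.
#' @param normalize If `TRUE`, fit counts divided by total mass; locations,
#'   widths and skewness are unchanged and amplitudes are rescaled by the
#'   total mass (then summing to about 1).
#' @param sigma_min,sigma_max,alpha_max Box constraints (HU / dimensionless).
#' @param maxiter Iteration cap of the optimizer.
#' @param ftol Relative objective-change tolerance declaring convergence.
#' @return An object of class `ntra_fit`: a list with `params` (named
#'   11-vector), `residual_sse`, `converged`, `n_iter`, `message`, `init`,
#'   `total_mass` and the fitted curve.  Use [tidy()] / [glance()] /
#'   [autoplot()] to inspect it.
#' @seealso [fit_ntra_cohort()] to fit a whole cohort of histograms.
#' @export
#' @examples
#' truth <- ntra_params(135, -65, 30, 0.5, 90, 20, 15, 185, 55, 12, 3)
#' h <- tibble::tibble(bin_center = hu_grid(), count = 1e5 * dntra(hu_grid(), truth))
#' fit <- fit_ntra(h)
#' glance(fit)
fit_ntra <- function(hist, init = NULL, normalize = FALSE,
                     sigma_min = 0.5, sigma_max = 120, alpha_max = 10,
                     maxiter = 500, ftol = 1e-10) {
  counts <- check_histogram(hist)
  grid <- as.numeric(hu_grid())
  total <- sum(counts)
  y <- if (normalize) counts / total else counts
  y_total <- sum(y)

  if (is.null(init)) {
    # two deterministic starts: skewness-seeded and symmetric window moments;
    # the lower-SSE basin wins
    starts <- list(default_init(grid, y, use_skewness = TRUE),
                   default_init(grid, y, use_skewness = FALSE))
  } else {
    init <- as_param_vector(init)
    if (normalize && sum(init[c("N_fat", "N_con", "N_mus")]) > 2 * y_total)
      init[c("N_fat", "N_con", "N_mus")] <-
        init[c("N_fat", "N_con", "N_mus")] / total
    starts <- list(init)
  }

  w <- tissue_windows()
  lower <- c(0, w$lo[1], sigma_min, -alpha_max,
             0, w$lo[2], sigma_min,
             0, w$lo[3], sigma_min, -alpha_max)
  upper <- c(10 * y_total, w$hi[1], sigma_max, alpha_max,
             10 * y_total, w$hi[2], sigma_max,
             10 * y_total, w$hi[3], sigma_max, alpha_max)
  names(lower) <- names(upper) <- ntra_parameter_names()

  # the 11 canonical parameters are the free ones; the connective skewness is
  # structurally absent (dntra evaluates that mode with alpha = 0)
  free <- ntra_parameter_names()
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  degenerate <- sum(y > 0) < 3L
  if (degenerate)
    warning("histogram mass is concentrated in fewer than 3 bins; ",
            "trimodal fit is not identifiable", call. = FALSE)

  residual_fun <- function(p) {
    names(p) <- free
    y - dntra(grid, p)
  }
  sse <- function(p) sum(residual_fun(p)^2)

  run_one <- function(start) {
    init_sse <- sse(start)
    res <- tryCatch(
      suppressWarnings(   # iteration-cap chatter; status is kept in `converged`
        minpack.lm::nls.lm(
          par = start, lower = lower, upper = upper, fn = residual_fun,
          control = minpack.lm::nls.lm.control(
            maxiter = maxiter, ftol = ftol, ptol = 1e-12, gtol = 0,
            maxfev = 100000))),
      error = function(e) e)
    if (inherits(res, "error"))
      return(list(params = start, sse = init_sse, converged = FALSE,
                  n_iter = 0L, msg = conditionMessage(res), start = start,
                  init_sse = init_sse))
    params <- setNames(as.numeric(res$par), free)
    out_sse <- sum(res$fvec^2)
    if (out_sse > init_sse) {       # never return worse than the start
      params <- start
      out_sse <- init_sse
    }
    list(params = params, sse = out_sse,
         converged = res$info %in% 1:4 && !degenerate,
         n_iter = res$niter, msg = res$message, start = start,
         init_sse = init_sse)
  }

  runs <- lapply(starts, run_one)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "sse"))]]
  params <- best$params
  out_sse <- best$sse
  converged <- best$converged
  n_iter <- best$n_iter
  msg <- best$msg
  start <- best$start
  init_sse <- best$init_sse
  structure(
    list(params = params[ntra_parameter_names()],
         residual_sse = out_sse,
         converged = converged,
         n_iter = n_iter,
         message = msg,
         init = start,
         init_sse = init_sse,
         normalize = normalize,
         total_mass = total,
         bin_center = grid,
         counts = y,
         fitted = dntra(grid, params[ntra_parameter_names()])),
    class = "ntra_fit")
}

# internal: deterministic window-moment starting values.  With
# use_skewness = TRUE the window's third central moment is inverted by the
# skew-normal method of moments to seed (mu, sigma, alpha); otherwise the
# raw centroid / SD with alpha = 0.  Both variants are tried by fit_ntra.
default_init <- function(grid, counts, use_skewness = TRUE) {
  one <- function(tis) {
    wb <- window_bounds(tis)
    in_w <- grid >= wb["lo"] & grid <= wb["hi"]
    m <- sum(counts[in_w])
    if (m <= 0) return(c(N = 0, mu = mean(wb), sigma = 10, alpha = 0))
    g <- grid[in_w]; cts <- counts[in_w]
    mu <- sum(g * cts) / m
    s <- sqrt(sum(cts * (g - mu)^2) / m)
    if (!use_skewness || tis == "con" || s == 0)
      return(c(N = m, mu = mu, sigma = max(s, 2), alpha = 0))
    g1 <- sum(cts * (g - mu)^3) / m / max(s, 1e-8)^3
    g1 <- max(min(g1, 0.99), -0.99)     # attainable skew-normal skewness
    a <- abs(g1)^(2/3)
    d2 <- pi / 2 * a / (a + ((4 - pi) / 2)^(2/3))
    delta <- sign(g1) * sqrt(d2)
    alpha0 <- -delta / sqrt(1 - d2)     # our alpha skews opposite to delta
    s0 <- s / sqrt(1 - 2 * d2 / pi)
    mu0 <- mu - s0 * delta * sqrt(2 / pi)
    c(N = m, mu = mu0, sigma = max(s0, 2), alpha = alpha0)
  }
  f <- one("fat"); cn <- one("con"); ms <- one("mus")
  ntra_params(f["N"], f["mu"], f["sigma"], f["alpha"],
              cn["N"], cn["mu"], cn["sigma"],
              ms["N"], ms["mu"], ms["sigma"], ms["alpha"],
              validate = FALSE)
}

#' @export
print.ntra_fit <- function(x, ...) {
  cat("Trimodal radiodensity fit (", if (x$converged) "converged"
      else "NOT converged", ", ", x$n_iter, " iterations)\n", sep = "")
  cat("  residual SSE:", format(x$residual_sse), " total mass:",
      format(x$total_mass), "\n")
  print(round(x$params, 4))
  invisible(x)
}

#' @rdname fit_ntra
#' @param x An `ntra_fit` object.
#' @param ... Unused.
#' @export
tidy.ntra_fit <- function(x, ...) {
  dplyr::inner_join(
    tibble::tibble(parameter = ntra_parameter_names(),
                   estimate = unname(x$params[ntra_parameter_names()])),
    ntra_parameter_tissues(), by = "parameter") |>
    dplyr::select("tissue", "parameter", "estimate")
}

#' @rdname fit_ntra
#' @export
glance.ntra_fit <- function(x, ...) {
  tibble::tibble(residual_sse = x$residual_sse, converged = x$converged,
                 n_iter = x$n_iter, total_mass = x$total_mass,
                 n_bins = sum(x$counts > 0))
}

#' @rdname fit_ntra
#' @param object An `ntra_fit` object.
#' @export
autoplot.ntra_fit <- function(object, ...) {
  grid <- object$bin_center
  p <- object$params
  modes <- tibble::tibble(
    hu = rep(grid, 3),
    tissue = factor(rep(c("fat", "con", "mus"), each = length(grid)),
                    levels = c("fat", "con", "mus")),
    density = c(dntra_mode(grid, p["N_fat"], p["mu_fat"], p["sigma_fat"], p["alpha_fat"]),
                dntra_mode(grid, p["N_con"], p["mu_con"], p["sigma_con"], 0),
                dntra_mode(grid, p["N_mus"], p["mu_mus"], p["sigma_mus"], p["alpha_mus"])))
  obs <- tibble::tibble(hu = grid, count = object$counts)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$hu)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), width = 1,
                      fill = "grey80") +
    ggplot2::geom_line(data = modes,
                       ggplot2::aes(y = .data$density, colour = .data$tissue)) +
    ggplot2::geom_line(data = tibble::tibble(hu = grid, fitted = object$fitted),
                       ggplot2::aes(y = .data$fitted), linewidth = 0.8) +
    ggplot2::labs(x = "Hounsfield units", y = "counts per HU bin",
                  colour = "tissue mode")
}

#' Fit the trimodal model to every leg histogram of a cohort
#'
#' @param histograms Long table with columns `subject_id`, `side`
#'   (`"L"`/`"R"`), `bin_center`, `count` — the histogram-CSV dialect written
#'   by [write_histograms()] and emitted by [generate_cohort()].
#' @param ... Passed on to [fit_ntra()].
#' @return A tibble with one row per subject and side: `subject_id`, `side`,
#'   the 11 canonical parameter columns, `residual_sse`, `converged`.
#' @export
fit_ntra_cohort <- function(histograms, ...) {
  stopifnot(all(c("subject_id", "side", "bin_center", "count") %in%
                  names(histograms)))
  histograms |>
    dplyr::group_by(.data$subject_id, .data$side) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_ntra(d, ...)
      tibble::as_tibble(as.list(fit$params)) |>
        dplyr::mutate(residual_sse = fit$residual_sse,
                      converged = fit$converged)
    }) |>
    dplyr::ungroup()
}
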