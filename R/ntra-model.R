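#' Construct the 11-parameter vector of the trimodal radiodensity model
#'
#' The model describes a mid-thigh HU histogram as the sum of three
#' skewed-Gaussian modes (fat, connective, muscle), each with an amplitude
#' `N` (integrated mass of the mode), a location `mu` (HU), a width `sigma`
#' (HU) and, for fat and muscle, a skewness `alpha`; the connective mode is
#' symmetric by construction.  Parameters are stored as a named numeric
#' vector in the canonical order of [ntra_parameter_names()].
#'
#' @param N_fat,mu_fat,sigma_fat,alpha_fat Fat-mode parameters.
#' @param N_con,mu_con,sigma_con Connective-mode parameters (no skewness).
#' @param N_mus,mu_mus,sigma_mus,alpha_mus Muscle-mode parameters.
#' @param validate Check the parameter invariants (default `TRUE`).
#' @return Named numeric vector of length 11.
#' @export
#' @examples
#' ntra_params(135, -65, 30, 0.5, 90, 20, 15, 185, 55, 12, 3)
ntra_params <- function(N_fat, mu_fat, sigma_fat, alpha_fat,
                        N_con, mu_con, sigma_con,
                        N_mus, mu_mus, sigma_mus, alpha_mus,
                        validate = TRUE) {
  p <- c(N_fat = N_fat, mu_fat = mu_fat, sigma_fat = sigma_fat,
         alpha_fat = alpha_fat,
         N_con = N_con, mu_con = mu_con, sigma_con = sigma_con,
         N_mus = N_mus, mu_mus = mu_mus, sigma_mus = sigma_mus,
         alpha_mus = alpha_mus)
  if (validate) validate_ntra_params(p)
  p
}

#' Validate a trimodal parameter vector
#'
#' Checks that all 11 canonical parameters are present and finite, widths are
#' strictly positive, amplitudes non-negative, and each location lies inside
#' its tissue window.
#'
#' @param params Named numeric vector (or single-row data frame) with the
#'   11 canonical parameters.
#' @return The parameters, invisibly, as a named numeric vector.
#' @export
validate_ntra_params <- function(params) {
  p <- as_param_vector(params)
  if (any(!is.finite(p))) stop("NTRA parameters must be finite", call. = FALSE)
  for (tis in c("fat", "con", "mus")) {
    if (p[paste0("sigma_", tis)] <= 0)
      stop("sigma_", tis, " must be strictly positive", call. = FALSE)
    if (p[paste0("N_", tis)] < 0)
      stop("N_", tis, " must be non-negative", call. = FALSE)
    w <- window_bounds(tis)
    mu <- p[paste0("mu_", tis)]
    if (mu < w["lo"] || mu > w["hi"])
      stop("mu_", tis, " = ", mu, " lies outside the ", tis,
           " window [", w["lo"], ", ", w["hi"], "] HU", call. = FALSE)
  }
  invisible(p)
}

# internal: coerce named vector / 1-row data frame to canonical named vector
as_param_vector <- function(params) {
  nm <- ntra_parameter_names()
  if (is.data.frame(params)) {
    if (nrow(params) != 1L)
      stop("expected a single-row parameter table", call. = FALSE)
    params <- unlist(params[intersect(names(params), nm)])
  }
  if (is.null(names(params)) && length(params) == 11L) names(params) <- nm
  missing <- setdiff(nm, names(params))
  if (length(missing))
    stop("missing NTRA parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  as.numeric(params[nm]) |> setNames(nm)
}

# complementary error function via the exact base-R identity
erfc_ <- function(x) 2 * pnorm(-x * sqrt(2))

#' Density of a single skewed-Gaussian tissue mode
#'
#' Evaluates `N / (sigma * sqrt(2*pi)) * exp(-(x - mu)^2 / (2*sigma^2)) *
#' erfc(alpha * (x - mu) / (sigma * sqrt(2)))`.  With this normalization the
#' mode integrates to `N` over the real line for any skewness `alpha`
#' (see [ntra_mode_mass()]); `alpha = 0` reduces to a Gaussian scaled by `N`.
#'
#' @param x Numeric vector of HU values.
#' @param N Amplitude (non-negative; the mode's integrated mass).
#' @param mu Location (HU).
#' @param sigma Width (HU, strictly positive).
#' @param alpha Skewness (dimensionless, default 0).
#' @return Numeric vector of non-negative density values.
#' @export
#' @examples
#' dntra_mode(0, N = 1, mu = 0, sigma = 1)        # 1 / sqrt(2 * pi)
#' dntra_mode(-150:-50, N = 135, mu = -65, sigma = 30, alpha = 0.5)
dntra_mode <- function(x, N, mu, sigma, alpha = 0) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be strictly positive", call. = FALSE)
  if (!is.finite(N) || N < 0)
    stop("N must be non-negative and finite", call. = FALSE)
  z <- (x - mu) / sigma
  N / (sigma * sqrt(2 * pi)) * exp(-z^2 / 2) * erfc_(alpha * z / sqrt(2))
}

#' Trimodal radiodensity curve
#'
#' Pointwise sum of the fat, connective and muscle mode densities.
#'
#' @param x Numeric vector of HU values.
#' @param params The 11 parameters, as from [ntra_params()] or a single-row
#'   data frame carrying the canonical columns.
#' @return Numeric vector of model density values at `x`.
#' @export
#' @examples
#' p <- ntra_params(135, -65, 30, 0.5, 90, 20, 15, 185, 55, 12, 3)
#' y <- dntra(hu_grid(), p)
dntra <- function(x, params) {
  p <- as_param_vector(params)
  dntra_mode(x, p["N_fat"], p["mu_fat"], p["sigma_fat"], p["alpha_fat"]) +
    dntra_mode(x, p["N_con"], p["mu_con"], p["sigma_con"], 0) +
    dntra_mode(x, p["N_mus"], p["mu_mus"], p["sigma_mus"], p["alpha_mus"])
}

#' Integrated mass of one tissue mode
#'
#' The skewed-Gaussian mode used here satisfies
#' `erfc(a z / sqrt(2)) = 2 * pnorm(-a * z)`, so the density equals
#' `N * 2 * dnorm(z) * pnorm(-alpha * z) / sigma` -- a skew-normal density
#' scaled by `N` -- and its integral over the real line is exactly `N` for
#' every `alpha`.  A tissue's "quantity" is therefore read directly off the
#' fitted amplitude.
#'
#' @inheritParams dntra_mode
#' @return The analytic integral, i.e. `N`.
#' @export
#' @examples
#' ntra_mode_mass(N = 7, mu = -50, sigma = 20, alpha = 3)  # 7
ntra_mode_mass <- function(N, mu, sigma, alpha = 0) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be strictly positive", call. = FALSE)
  if (!is.finite(N) || N < 0)
    stop("N must be non-negative and finite", call. = FALSE)
  N
}
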