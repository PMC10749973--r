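#' Fixed Hounsfield-unit windows of the three soft-tissue modes
#'
#' The soft-tissue range \[-200, 200\] HU of a mid-thigh CT cross-section is
#' partitioned into three fixed radiodensity windows: adipose (fat) tissue
#' \[-200, -10\] HU, loose connective tissue \[-9, 40\] HU and lean muscle
#' \[41, 200\] HU.  Each window hosts one mode of the trimodal model and
#' constrains that mode's location parameter during fitting.
#'
#' @return A tibble with columns `tissue` (`"fat"`, `"con"`, `"mus"`),
#'   `lo` and `hi` (integer HU bounds, both inclusive).
#' @export
#' @examples
#' tissue_windows()
tissue_windows <- function() {
  tibble::tibble(
    tissue = c("fat", "con", "mus"),
    lo = c(-200L, -9L, 41L),
    hi = c(-10L, 40L, 200L)
  )
}

#' Integer HU bin centers of the soft-tissue histogram support
#'
#' @return Integer vector `-200:200` (401 unit-width bins).
#' @export
hu_grid <- function() -200L:200L

#' Canonical order of the 11 trimodal model parameters
#'
#' Amplitude `N`, location `mu`, width `sigma` and (for the skewed fat and
#' muscle modes) skewness `alpha`, ordered fat, connective, muscle.  The
#' connective mode is constrained symmetric, so it contributes no `alpha`.
#'
#' @return Character vector of the 11 parameter names.
#' @export
#' @examples
#' ntra_parameter_names()
ntra_parameter_names <- function() {
  c("N_fat", "mu_fat", "sigma_fat", "alpha_fat",
    "N_con", "mu_con", "sigma_con",
    "N_mus", "mu_mus", "sigma_mus", "alpha_mus")
}

#' Map each of the 11 parameters to its tissue
#' @return A tibble with columns `parameter` and `tissue`.
#' @export
ntra_parameter_tissues <- function() {
  p <- ntra_parameter_names()
  tibble::tibble(parameter = p, tissue = sub("^.*_", "", p))
}

# internal: window bounds for one tissue
window_bounds <- function(tissue) {
  w <- tissue_windows()
  i <- match(tissue, w$tissue)
  c(lo = w$lo[i], hi = w$hi[i])
}
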