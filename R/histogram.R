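#' Bin raw HU pixel values into the 401-bin soft-tissue histogram
#'
#' Values are assigned to unit-width bins centered on the integers -200..200;
#' bin `k` covers `[k - 0.5, k + 0.5)`.  Values outside `[-200.5, 200.5)` —
#' bone, air, contrast — are discarded and their count reported in the
#' `discarded` attribute.
#'
#' @param hu_values Numeric vector of HU pixel values (non-empty).
#' @return A tibble with columns `bin_center` (integer, -200..200) and
#'   `count`, with attribute `discarded` (number of out-of-range values).
#' @export
#' @examples
#' h <- bin_hu(c(0.2, -0.3, 0.4, 250))
#' h$count[h$bin_center == 0]   # 3
#' attr(h, "discarded")         # 1
bin_hu <- function(hu_values) {
  if (length(hu_values) == 0L) stop("no HU values supplied", call. = FALSE)
  if (any(!is.finite(hu_values)))
    stop("HU values must be finite", call. = FALSE)
  bins <- floor(hu_values + 0.5)       # nearest integer, ties up
  keep <- bins >= -200 & bins <= 200
  n_out <- sum(!keep)
  if (!any(keep))
    stop("all HU values fall outside [-200.5, 200.5): empty histogram",
         call. = FALSE)
  counts <- tabulate(bins[keep] + 201L, nbins = 401L)
  out <- tibble::tibble(bin_center = hu_grid(), count = as.numeric(counts))
  attr(out, "discarded") <- n_out
  out
}

# internal: check a histogram table and return counts aligned to hu_grid()
check_histogram <- function(hist) {
  if (!is.data.frame(hist) || !all(c("bin_center", "count") %in% names(hist)))
    stop("histogram must have columns bin_center and count", call. = FALSE)
  if (any(!is.finite(hist$count)))
    stop("histogram counts must be finite", call. = FALSE)
  if (any(hist$count < 0))
    stop("histogram counts must be non-negative", call. = FALSE)
  grid <- hu_grid()
  counts <- numeric(401L)
  idx <- match(hist$bin_center, grid)
  if (any(is.na(idx)))
    stop("bin_center values must be integers in [-200, 200]", call. = FALSE)
  counts[idx] <- hist$count
  if (sum(counts) <= 0)
    stop("histogram has zero total mass", call. = FALSE)
  counts
}
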