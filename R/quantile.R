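#' Empirical quantile with averaging at discontinuities (type 2)
#'
#' Inverse of the empirical CDF with averaging at discontinuities: with the
#' `n` values sorted, let `j = floor(n p)` and `g = n p - j`; the estimate is
#' the average of order statistics `j` and `j + 1` when `g = 0`, and order
#' statistic `j + 1` otherwise. This is the convention used for every
#' percentile in the workflow: the 5th percentile of AC50 sets, the 95th
#' percentile of population steady-state concentrations, the 5th percentile
#' of NOAEL collections and all reported medians.
#'
#' @param values Numeric vector (non-empty, no NAs).
#' @param p Probability strictly between 0 and 1.
#' @return The type-2 empirical quantile.
#' @examples
#' quantile_type2(1:20, 0.05)  # 1.5
#' quantile_type2(1:21, 0.05)  # 2
#' @export
quantile_type2 <- function(values, p) {
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (anyNA(values)) stop("'values' must not contain NAs")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("'p' must be a single probability strictly between 0 and 1")
  }
  x <- sort(as.numeric(values))
  n <- length(x)
  np <- n * p
  j <- floor(np + 1e-9)
  g <- np - j
  if (abs(g) < 1e-9) {
    if (j == 0L) return(x[1L])
    if (j >= n) return(x[n])
    (x[j] + x[j + 1L]) / 2
  } else {
    x[min(j + 1L, n)]
  }
}
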