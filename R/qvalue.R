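#' Storey q-values with Benjamini-Hochberg fallback
#'
#' Estimates the null proportion pi0 from the flat right tail of the
#' p-value distribution over a lambda grid, smooths the pi0(lambda) curve
#' with a cubic smoothing spline and takes its value at the largest lambda,
#' then scales the Benjamini-Hochberg step-up quantities by pi0 with the
#' usual monotone (cumulative-minimum) adjustment. If the pi0 estimate is
#' unstable (outside (0, 1], or the spline fails, or too few p-values) the
#' conservative BH correction (pi0 = 1) is used instead.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda_grid tuning grid for the pi0 estimate.
#' @return q-value vector (same order as `p`), with attributes `pi0` and
#'   `method` (`"storey"` or `"BH"`).
#' @export
storey_qvalue <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  pi0 <- tryCatch({
    if (m < 20L) stop("too few p-values for a stable pi0 estimate")
    pi0l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lambda_grid, pi0l, df = 3)
    stats::predict(sp, max(lambda_grid))$y
  }, error = function(e) NA_real_)
  method <- "storey"
  if (is.na(pi0) || pi0 <= 0 || pi0 > 1) {
    pi0 <- 1
    method <- "BH"
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]))[ro]
  attr(q, "pi0") <- pi0
  attr(q, "method") <- method
  q
}
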