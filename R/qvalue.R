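#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 from the lambda grid
#' \code{0, 0.05, ..., 0.95}: pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))
#' is smoothed with a cubic smoothing spline (df = 3) and evaluated at the
#' largest lambda, then clipped to (0, 1]. Q-values follow the step-up
#' construction q(p_(i)) = min_{j >= i} pi0 m p_(j) / j, capped at 1. With
#' pi0 = 1 this reduces exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p Vector of p-values in [0, 1].
#' @param lambda Grid for pi0 estimation.
#' @param pi0 Optional fixed pi0 overriding the estimate (e.g. 1 for BH).
#' @return list with \code{qvalues} (same order as \code{p}) and \code{pi0}.
#' @export
storey_qvalues <- function(p, lambda = seq(0, 0.95, by = 0.05), pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    if (length(unique(pi0_lambda)) == 1L || m < 2) {
      pi0 <- pi0_lambda[length(lambda)]
    } else {
      sp <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
    }
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) {
      warning("estimated pi0 <= 0; clipping to a small positive value")
      pi0 <- 1e-8
    }
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(qvalues = q, pi0 = pi0)
}
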