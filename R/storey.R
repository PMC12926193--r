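#' Storey q-values and pi1 statistics
#'
#' Estimates the null proportion pi0 by Storey's smoother — the natural
#' cubic-spline fit of \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} /
#' (m(1-\lambda))} over a lambda grid, evaluated at the largest lambda and
#' clipped to (0, 1] — and converts p-values to q-values
#' \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j}.
#' With fewer than 20 p-values the pi0 estimate is unstable and the function
#' falls back to pi0 = 1 (Benjamini-Hochberg) with a warning.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param lambda_grid grid for the pi0 smoother (default 0.05 to 0.95 by
#'   0.05).
#' @return `storeyQvalue`: list with `pi0` and `q` (same order as `p`).
#'   `storeyPi1`: the scalar \eqn{\pi_1 = 1 - \hat\pi_0}, the estimated
#'   fraction of true signals.
#' @examples
#' set.seed(1)
#' p <- c(runif(900), rbeta(100, 0.1, 1))
#' storeyQvalue(p)$pi0
#' storeyPi1(p)
#' @export
storeyQvalue <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  m <- length(p)
  if (m < 20L) {
    warning("fewer than 20 p-values; falling back to pi0 = 1 (BH)")
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda_grid,
                    function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda_grid))$y
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  o <- order(p)
  q_ord <- pi0 * m * p[o] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[o] <- pmin(q_ord, 1)
  list(pi0 = pi0, q = q)
}

#' @rdname storeyQvalue
#' @export
storeyPi1 <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  1 - storeyQvalue(p, lambda_grid)$pi0
}
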