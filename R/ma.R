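# Moving-average residual machinery: innovations filtering, conditional
# least-squares estimation, and the closed-form MA autocorrelation.

# Innovations (whitening) filter: given z_t = e_t + sum_k theta_k e_{t-k},
# recover e_t recursively with zero pre-sample innovations.  Applied
# per trip so the process restarts at trip boundaries.  `z` may be a
# matrix (each column filtered with the same recursion).
ma_whiten <- function(z, trip, theta) {
  z <- as.matrix(z)
  if (length(theta) == 0L || all(theta == 0)) return(z)
  e <- z
  idx <- split(seq_len(nrow(z)), factor(trip, levels = unique(trip)))
  for (rows in idx) {
    for (col in seq_len(ncol(z))) {
      # e_t = z_t - sum_k theta_k e_{t-k}: a pure AR recursion
      e[rows, col] <- as.numeric(
        stats::filter(z[rows, col], -theta, method = "recursive"))
    }
  }
  e
}

# Conditional least squares for MA(q) on per-trip ordered residuals.
# Minimizes the sum of squared innovations; a barrier keeps the
# coefficients in the invertible region.
css_ma <- function(r, trip, q, init = NULL) {
  stopifnot(q >= 1)
  obj <- function(theta) {
    if (!ma_invertible(theta)) return(1e12 * (1 + sum(theta^2)))
    e <- ma_whiten(r, trip, theta)
    sum(e^2)
  }
  init <- init %||% rep(0, q)
  if (!ma_invertible(init)) init <- rep(0, q)
  opt <- optim(init, obj, method = "BFGS", hessian = TRUE,
               control = list(maxit = 200, reltol = 1e-10))
  n <- length(r)
  sigma2 <- opt$value / n
  vc <- tryCatch({
    h <- opt$hessian / 2  # hessian of SSE/2 approximates X'X of the score
    solve(h) * sigma2
  }, error = function(e) matrix(NA_real_, q, q))
  list(theta = opt$par, vcov = vc, sigma = sqrt(sigma2),
       converged = opt$convergence == 0)
}

ma_invertible <- function(theta) {
  if (all(theta == 0)) return(TRUE)
  roots <- polyroot(c(1, theta))
  all(Mod(roots) > 1.0001)
}

#' Theoretical autocorrelation of an MA(q) process
#'
#' Closed form `rho_k = (theta_k + sum_i theta_i theta_{i+k}) /
#' (1 + sum_i theta_i^2)` with `theta_0 = 1`, zero beyond lag `q`.
#'
#' @param theta MA coefficients.
#' @param lag_max Largest lag to return.
#' @return Numeric vector of autocorrelations at lags `1..lag_max`.
#' @examples
#' ma_acf(c(0.61, 0.20, 0.08))
#' @export
ma_acf <- function(theta, lag_max = length(theta)) {
  th <- c(1, theta)
  q <- length(theta)
  denom <- sum(th^2)
  sapply(seq_len(lag_max), function(k) {
    if (k > q) return(0)
    sum(th[seq_len(q + 1 - k)] * th[seq_len(q + 1 - k) + k]) / denom
  })
}
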