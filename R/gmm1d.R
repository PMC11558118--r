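# Small deterministic 1D Gaussian-mixture EM used by trace segmentation
# (two extension levels) and by the bimodality test on critical-force
# samples. Initialisation is by quantiles, so the fit is a pure function of
# the data: no RNG is consumed.

#' Fit a 1D Gaussian mixture by EM with deterministic quantile initialisation
#'
#' @param x numeric vector
#' @param k number of components (1 or 2 supported)
#' @param max_iter,tol EM stopping controls
#' @param min_sd lower bound on component standard deviations (guards
#'   against degenerate spikes)
#' @return list with `mean`, `sd`, `weight` (sorted by mean), `loglik`,
#'   `bic`, `n_params`, `converged`, `responsibility` (n x k matrix)
#' @export
fit_gmm1d <- function(x, k = 2, max_iter = 300, tol = 1e-9, min_sd = NULL) {
  stopifnot(is.numeric(x), length(x) >= k, k %in% c(1L, 2L))
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(min_sd)) min_sd <- max(1e-8, 1e-6 * (stats::sd(x) + 1e-12))

  if (k == 1L) {
    mu <- mean(x)
    sd1 <- max(stats::sd(x) * sqrt((n - 1) / n), min_sd)
    ll <- sum(stats::dnorm(x, mu, sd1, log = TRUE))
    return(list(
      mean = mu, sd = sd1, weight = 1, loglik = ll,
      bic = -2 * ll + 2 * log(n), n_params = 2L, converged = TRUE,
      responsibility = matrix(1, n, 1)
    ))
  }

  # deterministic init: split at the median, component moments per half
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  mu <- qs
  s0 <- max(stats::sd(x) / 2, min_sd)
  sd2 <- c(s0, s0)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  converged <- FALSE
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd2[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd2[2])
    tot <- d1 + d2
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    gamma <- cbind(d1 / tot, d2 / tot)
    ll <- sum(log(tot))
    nk <- colSums(gamma)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(gamma * x) / nk
    sd2 <- sqrt(pmax(colSums(gamma * (x - rep(mu, each = n))^2) / nk, min_sd^2))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  list(
    mean = mu[ord], sd = sd2[ord], weight = w[ord], loglik = ll_old,
    bic = -2 * ll_old + 5 * log(n), n_params = 5L, converged = converged,
    responsibility = gamma[, ord, drop = FALSE]
  )
}
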