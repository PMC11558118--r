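# Null-force binding free energies from critical forces, and the
# classification of salt conditions into one- and two-mode behaviour.
#
# At the critical force the observed binding and unbinding rates balance
# (K_obs/[L] = 1), so the zero-force binding free energy is the negative of
# the force-induced free-energy bias: dG0 = -ddG(F_c), with ddG from the
# WLC stretch-work bookkeeping in polymer_mechanics.

#' Null-force binding free energy from a critical force
#'
#' @param f_c critical force in pN (>= 0)
#' @param n_released_nt nucleotides released on unbinding (default 20, the
#'   probe length)
#' @param wlc a [wlc_params()] object
#' @return dG0 in kBT; negative (favourable) for any `f_c > 0`
#' @export
binding_free_energy <- function(f_c, n_released_nt = 20, wlc = wlc_params()) {
  stopifnot(is.numeric(f_c), all(f_c >= 0))
  vapply(f_c, function(f) -delta_delta_g(f, n_released_nt, wlc)$delta_delta_g,
         numeric(1))
}

#' Classify critical-force samples into one or two interaction modes
#'
#' Fits one- and two-component Gaussian mixtures (deterministic quantile
#' initialisation) to per-trace critical-force samples. Two modes are
#' reported when the two-component fit improves BIC by at least
#' `bic_improvement` and the component means are separated by at least
#' `min_separation_sd` pooled standard deviations.
#'
#' @param f_c_samples critical-force samples in pN (>= `min_n` values)
#' @param bic_improvement required BIC gain for the two-mode model
#' @param min_separation_sd required mean separation in pooled SDs
#' @param min_n minimum number of samples
#' @return list with `ok`, `mode_count`, `means`, `sds`, `weights`,
#'   `bic_1`, `bic_2`, `assignment` (per-sample hard labels)
#' @export
classify_modes <- function(f_c_samples, bic_improvement = 6,
                           min_separation_sd = 2, min_n = 10L) {
  x <- as.numeric(f_c_samples)
  x <- x[is.finite(x)]
  if (length(x) < min_n) {
    return(list(ok = FALSE, reason = "insufficient samples"))
  }
  if (stats::sd(x) < 1e-12) {
    return(list(ok = TRUE, mode_count = 1L, means = mean(x), sds = 0,
                weights = 1, bic_1 = NA_real_, bic_2 = NA_real_,
                assignment = rep(1L, length(x))))
  }
  g1 <- fit_gmm1d(x, k = 1)
  g2 <- fit_gmm1d(x, k = 2)
  pooled_sd <- sqrt(sum(g2$weight * g2$sd^2))
  two <- (g1$bic - g2$bic >= bic_improvement) &&
    (diff(g2$mean) >= min_separation_sd * pooled_sd) &&
    min(g2$weight) > 1e-3
  if (two) {
    list(ok = TRUE, mode_count = 2L, means = g2$mean, sds = g2$sd,
         weights = g2$weight, bic_1 = g1$bic, bic_2 = g2$bic,
         assignment = max.col(g2$responsibility))
  } else {
    list(ok = TRUE, mode_count = 1L, means = g1$mean, sds = g1$sd,
         weights = 1, bic_1 = g1$bic, bic_2 = g2$bic,
         assignment = rep(1L, length(x)))
  }
}

# Common-slope mixture of lines y = b*F + a_m fitted by EM.
# Used to turn per-trace log rate ratios into per-trace critical forces
# when a condition may host two interaction modes with shared Bell
# distances (parallel ratio lines, different intercepts).
.fit_parallel_lines <- function(F, y, n_modes = 2L, max_iter = 300, tol = 1e-10) {
  n <- length(y)
  stopifnot(length(F) == n, n >= 4L)
  if (n_modes == 1L) {
    fit <- stats::lm(y ~ F)
    sig <- sqrt(mean(stats::resid(fit)^2))
    ll <- sum(stats::dnorm(y, stats::fitted(fit), max(sig, 1e-12), log = TRUE))
    return(list(slope = unname(stats::coef(fit)[2]),
                intercepts = unname(stats::coef(fit)[1]),
                weights = 1, sigma = sig, loglik = ll,
                bic = -2 * ll + 3 * log(n),
                responsibility = matrix(1, n, 1)))
  }
  # init: split on residuals from the single-line fit
  f0 <- stats::lm(y ~ F)
  r0 <- stats::resid(f0)
  grp <- as.integer(r0 > stats::median(r0)) + 1L
  b <- unname(stats::coef(f0)[2])
  a <- c(unname(stats::coef(f0)[1]) + stats::median(r0[grp == 1L]),
         unname(stats::coef(f0)[1]) + stats::median(r0[grp == 2L]))
  w <- c(0.5, 0.5)
  sig <- max(stats::sd(r0) / 2, 1e-6)
  ll_old <- -Inf
  gamma <- NULL
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(y, b * F + a[1], sig)
    d2 <- w[2] * stats::dnorm(y, b * F + a[2], sig)
    tot <- pmax(d1 + d2, .Machine$double.xmin)
    gamma <- cbind(d1 / tot, d2 / tot)
    ll <- sum(log(tot))
    nk <- pmax(colSums(gamma), 1e-12)
    w <- nk / n
    # weighted LS for (b, a1, a2): stack both component regressions
    sw <- sqrt(c(gamma[, 1], gamma[, 2]))
    X <- rbind(cbind(F, 1, 0), cbind(F, 0, 1)) * sw
    Y <- c(y, y) * sw
    beta <- stats::coef(stats::lm.fit(X, Y))
    b <- beta[1]; a <- beta[2:3]
    res2 <- gamma[, 1] * (y - b * F - a[1])^2 + gamma[, 2] * (y - b * F - a[2])^2
    sig <- max(sqrt(sum(res2) / n), 1e-9)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  ord <- order(a)
  list(slope = unname(b), intercepts = unname(a[ord]), weights = w[ord],
       sigma = sig, loglik = ll_old, bic = -2 * ll_old + 6 * log(n),
       responsibility = gamma[, ord, drop = FALSE])
}

#' Per-trace kinetic fits
#'
#' Segments each trace individually and fits its binding and unbinding
#' rates (no pooling). Traces without detected transitions or with too few
#' events are dropped with a warning.
#'
#' @param traces list of [force_extension_trace()] objects
#' @param settings a [segmentation_settings()]
#' @param min_events minimum uncensored events per rate per trace
#' @param dwell_sets optional precomputed [trace_dwell_sets()] output
#' @return data frame with one row per usable trace: `trace`, `force_pN`,
#'   `k_bind`, `k_unbind`, `n_bind`, `n_unbind`
#' @export
per_trace_rates <- function(traces, settings = segmentation_settings(),
                            min_events = 5L, dwell_sets = NULL) {
  per <- if (is.null(dwell_sets)) trace_dwell_sets(traces, settings) else dwell_sets
  rows <- lapply(seq_along(per), function(i) {
    p <- per[[i]]
    if (is.null(p)) return(NULL)
    fu <- fit_rate(p$ds$unbound_dwells, p$ds$unbound_censored, min_events)
    fb <- fit_rate(p$ds$bound_dwells, p$ds$bound_censored, min_events)
    if (!fu$ok || !fb$ok) return(NULL)
    data.frame(trace = i, force_pN = p$force,
               k_bind = fu$rate, k_unbind = fb$rate,
               n_bind = fu$n_events, n_unbind = fb$n_events)
  })
  drop <- vapply(rows, is.null, logical(1))
  if (any(drop)) warning(sum(drop), " trace(s) unusable for per-trace rates")
  out <- do.call(rbind, rows[!drop])
  if (is.null(out) || nrow(out) == 0L) stop("no usable traces")
  out
}

#' Per-trace critical-force samples
#'
#' For Bell kinetics the log rate ratio y = ln(k_unbind / k_bind) is linear
#' in force with slope s = (dx_bind + dx_unbind)/kBT shared by interaction
#' modes that differ only in their zero-force rates. The slope is estimated
#' by a common-slope mixture-of-lines EM (1 vs 2 intercepts chosen by BIC),
#' and each trace is converted to a critical-force sample
#' F_c,i = F_i - y_i / s (the force at which its own rates would balance).
#'
#' @param per_trace data frame from [per_trace_rates()]
#' @return list with `f_c_samples`, `slope` (1/pN), `n_intercepts`, `fit`
#' @export
per_trace_fc <- function(per_trace) {
  stopifnot(is.data.frame(per_trace), nrow(per_trace) >= 4L)
  y <- log(per_trace$k_unbind / per_trace$k_bind)
  F <- per_trace$force_pN
  f1 <- .fit_parallel_lines(F, y, 1L)
  f2 <- .fit_parallel_lines(F, y, 2L)
  best <- if (f2$bic < f1$bic - 6) f2 else f1
  s <- best$slope
  if (!is.finite(s) || s <= 0) {
    stop("no crossover: log rate-ratio does not increase with force")
  }
  list(f_c_samples = F - y / s, slope = s,
       n_intercepts = length(best$intercepts), fit = best)
}

#' Full thermodynamic analysis of one salt condition
#'
#' Runs the complete trace pipeline: segmentation, per-force pooled rates,
#' critical force from the rate crossover, per-trace critical-force samples,
#' mode classification, and null-force binding free energies per mode.
#'
#' @param traces list of [force_extension_trace()] objects at several forces
#' @param condition_label,salt_mM condition metadata
#' @param n_released_nt nucleotides released on unbinding (enters dG0)
#' @param wlc a [wlc_params()] object
#' @param settings a [segmentation_settings()]
#' @param seed bootstrap seed
#' @return a `binding_energy_result` list: pooled `f_c` (+ `f_c_se`),
#'   `mode_count`, per-mode `mode_fc` and `delta_g0` (kBT, signed negative),
#'   sample diagnostics
#' @export
analyze_condition <- function(traces, condition_label = "", salt_mM = NA_real_,
                              n_released_nt = 20, wlc = wlc_params(),
                              settings = segmentation_settings(), seed = 1L) {
  ds <- trace_dwell_sets(traces, settings)
  fits <- rates_vs_force(traces, settings, dwell_sets = ds)
  cf <- critical_force(fits, seed = seed)
  pt <- per_trace_rates(traces, settings, dwell_sets = ds)
  fc_samp <- per_trace_fc(pt)
  modes <- classify_modes(fc_samp$f_c_samples)
  if (!modes$ok) {
    modes <- list(ok = TRUE, mode_count = 1L,
                  means = if (cf$ok) cf$f_c else NA_real_,
                  sds = NA_real_, weights = 1)
  }
  mode_fc <- modes$means
  dg0 <- binding_free_energy(pmax(mode_fc, 0), n_released_nt, wlc)
  structure(list(
    condition_label = condition_label,
    salt_mM = salt_mM,
    f_c = if (cf$ok) cf$f_c else NA_real_,
    f_c_se = if (cf$ok) cf$se else NA_real_,
    crossover = cf,
    rate_fits = fits,
    mode_count = modes$mode_count,
    mode_fc = mode_fc,
    mode_weights = modes$weights,
    delta_g0 = dg0,
    f_c_samples = fc_samp$f_c_samples,
    ratio_slope = fc_samp$slope,
    n_released_nt = n_released_nt
  ), class = "binding_energy_result")
}

#' @export
print.binding_energy_result <- function(x, ...) {
  cat(sprintf("Condition %s (%.3g mM NaCl)\n", x$condition_label, x$salt_mM))
  cat(sprintf("  pooled F_c = %.3f +/- %.3f pN (%d modes)\n",
              x$f_c, x$f_c_se, x$mode_count))
  for (m in seq_along(x$mode_fc)) {
    cat(sprintf("  mode %d: F_c = %.3f pN, dG0 = %.3f kBT (weight %.2f)\n",
                m, x$mode_fc[m], x$delta_g0[m], x$mode_weights[m]))
  }
  invisible(x)
}

#' Binding free energy versus salt, with the inter-mode jump
#'
#' Orders per-condition results by salt and reports the free-energy jump
#' between the two interaction modes: at a bimodal condition the jump is
#' the difference between its two per-mode dG0 values; with no bimodal
#' condition it is the largest consecutive |dG0| difference across the salt
#' ladder (the regime midpoint).
#'
#' @param results list of `binding_energy_result` objects
#' @return list with `profile` (data frame, one row per condition-mode) and
#'   `jump_kbt` (magnitude; `NA` with a single condition)
#' @export
energy_salt_profile <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      condition_label = r$condition_label,
      salt_mM = r$salt_mM,
      mode = seq_along(r$mode_fc),
      mode_count = r$mode_count,
      f_c_pN = r$mode_fc,
      delta_g0_kbt = r$delta_g0,
      weight = r$mode_weights
    )
  }))
  rows <- rows[order(rows$salt_mM, rows$mode), ]
  bim <- rows[rows$mode_count == 2L, ]
  if (nrow(bim) >= 2L) {
    # jump between the two modes at the (first) bimodal condition
    s <- bim$salt_mM[1L]
    dg <- bim$delta_g0_kbt[bim$salt_mM == s]
    jump <- abs(diff(range(dg)))
  } else if (length(unique(rows$salt_mM)) >= 2L) {
    dg <- rows$delta_g0_kbt[rows$mode == 1L]
    jump <- max(abs(diff(dg)))
  } else {
    jump <- NA_real_
  }
  list(profile = rows, jump_kbt = jump)
}
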