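# Turning constant-force extension traces into dwell times, force-dependent
# binding/unbinding rates, and the critical force at which they balance.
#
# Convention: state 1 = bound (short extension, ssDNA wrapped on the protein),
# state 0 = unbound (long extension). Unbound dwells end in a binding event
# and estimate the observed binding rate k_bind_obs = [L] k+; bound dwells
# end in an unbinding event and estimate k_unbind.

#' Constant-force extension trace
#'
#' @param time time stamps in s (uniform, strictly increasing)
#' @param extension extension in nm
#' @param force constant applied force in pN (> 0)
#' @param sampling_rate sampling rate in Hz; defaults to `1 / dt` of `time`
#' @param condition_label free-text label (e.g. salt condition)
#' @return a `force_extension_trace` data frame with attributes
#' @export
force_extension_trace <- function(time, extension, force,
                                  sampling_rate = NULL,
                                  condition_label = "") {
  stopifnot(is.numeric(time), is.numeric(extension), length(time) == length(extension),
            length(time) >= 2L, is.numeric(force), length(force) == 1L, force > 0)
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("time must be strictly increasing on a uniform grid")
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(dt)
  out <- data.frame(time_s = time, extension_nm = extension, force_pN = force)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "condition_label") <- condition_label
  class(out) <- c("force_extension_trace", "data.frame")
  out
}

#' Segmentation settings for two-state trace analysis
#'
#' @param filter_width_s width of the running-median prefilter, s. Measurement
#'   noise is reduced by ~sqrt of the window length before level detection;
#'   the window must stay well below the typical dwell time.
#' @param hysteresis_low,hysteresis_high positions of the dual thresholds as
#'   fractions of the level separation above the lower level
#' @param min_separation_sd minimum level separation in units of the pooled
#'   level SD below which the trace is declared transition-free
#' @param min_dwell_s dwells shorter than this are merged into their
#'   neighbours (instrument-style dead time against noise-induced flickers)
#' @return a `segmentation_settings` list
#' @export
segmentation_settings <- function(filter_width_s = 0.11,
                                  hysteresis_low = 0.3,
                                  hysteresis_high = 0.7,
                                  min_separation_sd = 2,
                                  min_dwell_s = 0.15) {
  stopifnot(filter_width_s >= 0, hysteresis_low < hysteresis_high,
            hysteresis_low > 0, hysteresis_high < 1, min_dwell_s >= 0)
  structure(list(
    filter_width_s = filter_width_s,
    hysteresis_low = hysteresis_low,
    hysteresis_high = hysteresis_high,
    min_separation_sd = min_separation_sd,
    min_dwell_s = min_dwell_s
  ), class = "segmentation_settings")
}

#' Segment a two-state extension trace into bound/unbound labels
#'
#' Median-prefilters the extension, fits a two-component Gaussian level
#' mixture, and labels samples by dual-threshold hysteresis at
#' `mu_low + 0.3 * Delta` and `mu_low + 0.7 * Delta` where `Delta` is the
#' fitted level separation. Runs shorter than the dead time are merged.
#' Deterministic given trace and settings.
#'
#' @param trace a [force_extension_trace()]
#' @param settings a [segmentation_settings()]
#' @return list with `ok`; when `ok`, integer `states` (1 = bound = low
#'   extension, 0 = unbound), fitted `levels`, `separation`, `thresholds`;
#'   when the extension histogram is effectively unimodal, `ok = FALSE` with
#'   `reason = "no transitions detected"` (not an error).
#' @export
segment_trace <- function(trace, settings = segmentation_settings()) {
  stopifnot(inherits(trace, "force_extension_trace"))
  fs <- attr(trace, "sampling_rate")
  ext <- trace$extension_nm
  n <- length(ext)

  kwin <- max(1L, round(settings$filter_width_s * fs))
  if (kwin %% 2L == 0L) kwin <- kwin + 1L
  filt <- if (kwin >= 3L && n > kwin) as.numeric(stats::runmed(ext, kwin)) else ext

  if (stats::sd(filt) < 1e-12) {
    return(list(ok = FALSE, reason = "no transitions detected"))
  }
  sub <- if (n > 4000L) filt[seq(1L, n, length.out = 4000L)] else filt
  fit <- fit_gmm1d(sub, k = 2)
  delta <- fit$mean[2] - fit$mean[1]
  pooled_sd <- sqrt(sum(fit$weight * fit$sd^2))
  if (!is.finite(delta) || delta < settings$min_separation_sd * pooled_sd ||
      min(fit$weight) < 0.02) {
    return(list(ok = FALSE, reason = "no transitions detected"))
  }

  thr_lo <- fit$mean[1] + settings$hysteresis_low * delta
  thr_hi <- fit$mean[1] + settings$hysteresis_high * delta
  # hysteresis: definite labels outside the band, carry the last state inside
  lab <- rep(NA_integer_, n)
  lab[filt < thr_lo] <- 1L  # low extension = bound
  lab[filt > thr_hi] <- 0L
  if (all(is.na(lab))) {
    return(list(ok = FALSE, reason = "no transitions detected"))
  }
  lab <- .fill_forward(lab)

  # dead-time merge: flip sub-minimum runs into their surroundings,
  # shortest first
  min_run <- max(1L, round(settings$min_dwell_s * fs))
  if (min_run > 1L) lab <- .merge_short_runs(lab, min_run)

  list(
    ok = TRUE,
    states = lab,
    levels = fit$mean,
    level_sds = fit$sd,
    separation = delta,
    thresholds = c(low = thr_lo, high = thr_hi),
    filter_width_samples = kwin
  )
}

# forward-fill NAs; leading NAs take the first observed label
.fill_forward <- function(lab) {
  idx <- which(!is.na(lab))
  first <- idx[1L]
  if (first > 1L) lab[seq_len(first - 1L)] <- lab[first]
  idx <- which(!is.na(lab))
  # index of the most recent non-NA at each position
  filled <- cumsum(!is.na(lab))
  lab <- lab[idx][filled]
  lab
}

.merge_short_runs <- function(lab, min_run) {
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    # never flip the (censored) boundary runs: they are truncated, not noise
    short <- setdiff(short, c(1L, length(r$lengths)))
    if (length(short) == 0L) break
    j <- short[which.min(r$lengths[short])]
    r$values[j] <- 1L - r$values[j]
    lab <- inverse.rle(r)
  }
  lab
}

#' Dwell times from a state sequence
#'
#' Run lengths times the sampling interval. The first and last dwell of a
#' trace are right/left-truncated and flagged censored; they contribute
#' observation time but no event to the rate estimate.
#'
#' @param states integer vector of per-sample labels (1 = bound, 0 = unbound)
#' @param sampling_rate sampling rate in Hz
#' @return a `dwell_set` list with `bound_dwells`, `unbound_dwells` (s),
#'   matching `bound_censored`/`unbound_censored` flags and `n_transitions`.
#'   With no state change, empty dwell vectors are returned with a warning.
#' @export
dwell_times <- function(states, sampling_rate) {
  stopifnot(is.numeric(states) || is.integer(states), sampling_rate > 0)
  r <- rle(as.integer(states))
  k <- length(r$lengths)
  if (k == 1L) {
    warning("no state change in trace: returning empty dwell set")
    return(structure(list(
      bound_dwells = numeric(0), unbound_dwells = numeric(0),
      bound_censored = logical(0), unbound_censored = logical(0),
      n_transitions = 0L
    ), class = "dwell_set"))
  }
  dw <- r$lengths / sampling_rate
  censored <- seq_len(k) %in% c(1L, k)
  is_bound <- r$values == 1L
  structure(list(
    bound_dwells = dw[is_bound],
    unbound_dwells = dw[!is_bound],
    bound_censored = censored[is_bound],
    unbound_censored = censored[!is_bound],
    n_transitions = k - 1L
  ), class = "dwell_set")
}

#' Exponential rate from dwell times with censoring
#'
#' Maximum-likelihood estimate for an exponential dwell distribution with
#' right-censored boundary dwells: k = (uncensored events) / (total observed
#' time, censored dwells included). SE = k / sqrt(n_events).
#'
#' @param dwells dwell times in s (> 0)
#' @param censored logical flags, same length
#' @param min_events minimum number of uncensored events required
#' @return list with `ok`, `rate` (1/s), `se`, `n_events`, `total_time`
#' @export
fit_rate <- function(dwells, censored = rep(FALSE, length(dwells)),
                     min_events = 5L) {
  stopifnot(length(dwells) == length(censored))
  if (any(dwells <= 0)) stop("dwell times must be positive")
  n_events <- sum(!censored)
  total_time <- sum(dwells)
  if (n_events < min_events) {
    return(list(ok = FALSE, reason = "insufficient events",
                rate = NA_real_, se = NA_real_,
                n_events = n_events, total_time = total_time))
  }
  k <- n_events / total_time
  list(ok = TRUE, rate = k, se = k / sqrt(n_events),
       n_events = n_events, total_time = total_time)
}

#' Binding/unbinding rates for a set of traces, pooled per force
#'
#' Segments each trace, extracts dwells and pools them across traces sharing
#' the same force before the exponential MLE. Traces that fail segmentation
#' are skipped with a warning.
#'
#' @param traces list of [force_extension_trace()] objects
#' @param settings a [segmentation_settings()]
#' @param min_events per-force minimum uncensored events
#' @param dwell_sets optional precomputed [trace_dwell_sets()] output
#' @return `kinetic_fit` data frame: one row per force with `force_pN`,
#'   `k_bind`, `k_bind_se`, `n_bind`, `k_unbind`, `k_unbind_se`, `n_unbind`
#' @export
rates_vs_force <- function(traces, settings = segmentation_settings(),
                           min_events = 5L, dwell_sets = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  per <- if (is.null(dwell_sets)) trace_dwell_sets(traces, settings) else dwell_sets
  drop <- vapply(per, is.null, logical(1))
  if (any(drop)) warning(sum(drop), " trace(s) without detected transitions skipped")
  per <- per[!drop]
  if (length(per) == 0L) stop("no traces with detected transitions")
  forces <- vapply(per, `[[`, numeric(1), "force")
  out <- lapply(sort(unique(forces)), function(f) {
    sel <- per[forces == f]
    bd <- unlist(lapply(sel, function(p) p$ds$bound_dwells))
    bc <- unlist(lapply(sel, function(p) p$ds$bound_censored))
    ud <- unlist(lapply(sel, function(p) p$ds$unbound_dwells))
    uc <- unlist(lapply(sel, function(p) p$ds$unbound_censored))
    fu <- fit_rate(ud, uc, min_events) # unbound dwells end by binding
    fb <- fit_rate(bd, bc, min_events) # bound dwells end by unbinding
    data.frame(force_pN = f,
               k_bind = fu$rate, k_bind_se = fu$se, n_bind = fu$n_events,
               k_unbind = fb$rate, k_unbind_se = fb$se, n_unbind = fb$n_events)
  })
  res <- do.call(rbind, out)
  class(res) <- c("kinetic_fit", "data.frame")
  res
}

#' Segment a list of traces and extract their dwell sets
#'
#' Shared first stage of the pooled and per-trace analyses, so each trace is
#' segmented only once.
#'
#' @param traces list of [force_extension_trace()] objects
#' @param settings a [segmentation_settings()]
#' @return list (one element per trace) of `list(force, ds)`; `NULL` for
#'   traces without detected transitions
#' @export
trace_dwell_sets <- function(traces, settings = segmentation_settings()) {
  lapply(traces, function(tr) {
    seg <- segment_trace(tr, settings)
    if (!seg$ok) return(NULL)
    ds <- suppressWarnings(dwell_times(seg$states, attr(tr, "sampling_rate")))
    if (ds$n_transitions == 0L) return(NULL)
    list(force = tr$force_pN[1L], ds = ds)
  })
}

#' Critical force from the crossover of Bell-model rate-force lines
#'
#' Fits weighted least-squares lines `ln k_bind = a1 + b1 F` and
#' `ln k_unbind = a2 + b2 F` (weights from the delta-method SEs of ln k,
#' i.e. 1/n_events) and solves `F_c = (a1 - a2) / (b2 - b1)`. The SE of
#' `F_c` comes from a seeded parametric bootstrap of the per-force log-rates.
#'
#' @param fits a `kinetic_fit` data frame from [rates_vs_force()]
#' @param n_boot bootstrap resamples
#' @param seed bootstrap seed
#' @return list with `ok`, `f_c` (pN), `se`, `slope_bind`, `slope_unbind`,
#'   `intercept_bind`, `intercept_unbind`, `n_forces_used`, `extrapolated`
#' @export
critical_force <- function(fits, n_boot = 1000L, seed = 1L) {
  stopifnot(is.data.frame(fits))
  ok_rows <- stats::complete.cases(fits[, c("force_pN", "k_bind", "k_unbind")]) &
    fits$k_bind > 0 & fits$k_unbind > 0
  d <- fits[ok_rows, , drop = FALSE]
  if (nrow(d) < 3L) {
    return(list(ok = FALSE, reason = "need >= 3 forces with both rates"))
  }
  solve_fc <- function(lkb, lku) {
    fb <- stats::lm(lkb ~ d$force_pN, weights = d$n_bind)
    fu <- stats::lm(lku ~ d$force_pN, weights = d$n_unbind)
    a1 <- stats::coef(fb)[1]; b1 <- stats::coef(fb)[2]
    a2 <- stats::coef(fu)[1]; b2 <- stats::coef(fu)[2]
    if (abs(b2 - b1) < 1e-6) return(c(NA_real_, b1, b2, a1, a2))
    c((a1 - a2) / (b2 - b1), b1, b2, a1, a2)
  }
  pt <- solve_fc(log(d$k_bind), log(d$k_unbind))
  if (is.na(pt[1])) {
    return(list(ok = FALSE, reason = "no crossover: rate-force lines parallel"))
  }
  se <- NA_real_
  if (n_boot > 0L) {
    se_lkb <- 1 / sqrt(d$n_bind)
    se_lku <- 1 / sqrt(d$n_unbind)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        lkb <- log(d$k_bind) + stats::rnorm(nrow(d), 0, se_lkb)
        lku <- log(d$k_unbind) + stats::rnorm(nrow(d), 0, se_lku)
        solve_fc(lkb, lku)[1]
      }, numeric(1))
    })
    se <- stats::sd(boots, na.rm = TRUE)
  }
  fr <- range(d$force_pN)
  list(
    ok = TRUE,
    f_c = unname(pt[1]), se = se,
    slope_bind = unname(pt[2]), slope_unbind = unname(pt[3]),
    intercept_bind = unname(pt[4]), intercept_unbind = unname(pt[5]),
    n_forces_used = nrow(d),
    extrapolated = pt[1] < fr[1] || pt[1] > fr[2]
  )
}
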