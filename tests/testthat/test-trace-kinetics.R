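# Two-state segmentation, dwell extraction, rate fitting and the
# critical-force crossover.

test_that("noiseless square wave is labelled exactly", {
  tr <- square_wave_trace(low = 600, high = 630, half_period_s = 5,
                          duration_s = 100, fs = 1)
  seg <- segment_trace(tr)
  expect_true(seg$ok)
  truth <- as.integer(tr$extension_nm == 600)  # low extension = bound
  expect_identical(seg$states, truth)
  # determinism / idempotence
  expect_identical(segment_trace(tr)$states, seg$states)
  # invariance to a constant extension offset
  tr2 <- force_extension_trace(tr$time_s, tr$extension_nm + 250,
                               tr$force_pN[1], attr(tr, "sampling_rate"))
  expect_identical(segment_trace(tr2)$states, seg$states)
})

test_that("degenerate traces yield a no-transitions signal, not an error", {
  tconst <- force_extension_trace(0:99, rep(600, 100), 5, 1)
  seg <- segment_trace(tconst)
  expect_false(seg$ok)
  expect_match(seg$reason, "no transitions")
  # pure noise around one level is also transition-free
  set.seed(1)
  tnoise <- force_extension_trace(0:999, rnorm(1000, 600, 5), 5, 1)
  expect_false(segment_trace(tnoise)$ok)
})

test_that("segmentation of noisy telegraph traces matches generator truth", {
  # two levels 30 nm apart, 5 nm measurement noise
  spec <- condition_spec(
    label = "seg", salt_mM = 50,
    modes = data.frame(fc_pN = 10, rate_at_fc = 0.5, dx_bind_nm = 0.6,
                       dx_unbind_nm = 0.6, weight = 1),
    noise_sd = 5, n_released_nt = 82
  )
  acc <- vapply(1:10, function(i) {
    tr <- make_telegraph_trace(spec, force = 10, duration = 100,
                               seed = 7000 + i)
    seg <- segment_trace(tr)
    mean(seg$states == attr(tr, "truth")$states)
  }, numeric(1))
  expect_gt(mean(acc), 0.99)
})

test_that("dwell times are counted and censored correctly", {
  ds <- dwell_times(c(0L, 0L, 1L, 1L, 1L, 0L), sampling_rate = 1)
  expect_equal(ds$bound_dwells, 3)
  expect_false(ds$bound_censored)
  expect_equal(sort(ds$unbound_dwells), c(1, 2))
  expect_true(all(ds$unbound_censored))
  expect_equal(ds$n_transitions, 2L)

  # square wave: every interior dwell is one half period
  tr <- square_wave_trace(half_period_s = 5, duration_s = 100, fs = 1)
  seg <- segment_trace(tr)
  ds2 <- dwell_times(seg$states, 1)
  interior <- c(ds2$bound_dwells[!ds2$bound_censored],
                ds2$unbound_dwells[!ds2$unbound_censored])
  expect_equal(length(interior), 18L)
  expect_true(all(interior == 5))

  expect_warning(dwell_times(rep(1L, 10), 1), "no state change")
})

test_that("exponential rate MLE handles censoring and recovers the truth", {
  f <- fit_rate(rep(2, 4), rep(FALSE, 4), min_events = 1L)
  expect_equal(f$rate, 0.5)
  expect_equal(f$se, 0.25)
  # censored dwells add time but no events: estimate must drop
  f2 <- fit_rate(c(rep(2, 4), 3), c(rep(FALSE, 4), TRUE), min_events = 1L)
  expect_lt(f2$rate, f$rate)
  # too few events
  expect_false(fit_rate(c(1, 2), c(FALSE, FALSE))$ok)
  # Monte-Carlo recovery within 3 SE
  set.seed(3)
  d <- rexp(1000, 2)
  f3 <- fit_rate(d, rep(FALSE, 1000))
  expect_lt(abs(f3$rate - 2), 3 * f3$se)
})

test_that("critical force solves the rate crossover", {
  forces <- c(0, 1, 2, 3)
  fits <- data.frame(
    force_pN = forces,
    k_bind = exp(-forces), k_bind_se = 0.01, n_bind = 1000,
    k_unbind = exp(forces - 2), k_unbind_se = 0.01, n_unbind = 1000
  )
  cf <- critical_force(fits, n_boot = 200, seed = 1)
  expect_true(cf$ok)
  expect_equal(cf$f_c, 1, tolerance = 1e-9)
  expect_lt(cf$slope_bind, 0)
  expect_gt(cf$slope_unbind, 0)
  expect_false(cf$extrapolated)

  # doubling the ligand concentration lifts ln k_bind by ln 2 and moves the
  # crossover by ln2 / (b2 - b1)
  fits2 <- fits
  fits2$k_bind <- 2 * fits$k_bind
  cf2 <- critical_force(fits2, n_boot = 0)
  expect_equal(cf2$f_c - cf$f_c,
               log(2) / (cf$slope_unbind - cf$slope_bind), tolerance = 1e-9)

  # parallel lines cannot cross
  fits3 <- fits
  fits3$k_unbind <- 3 * fits$k_bind
  cf3 <- critical_force(fits3, n_boot = 0)
  expect_false(cf3$ok)
  expect_match(cf3$reason, "parallel|crossover")

  expect_false(critical_force(fits[1:2, ])$ok)
})

test_that("pooled rates are invariant to trace order", {
  spec <- fixture_condition("75mM")
  b <- make_condition_dataset(spec, forces = c(6, 8), n_traces = 3,
                              duration = 100, seed = 11)
  f1 <- rates_vs_force(b$traces)
  f2 <- rates_vs_force(rev(b$traces))
  expect_equal(f1, f2)
})
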