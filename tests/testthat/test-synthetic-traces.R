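# Telegraph-trace generator and the shipped salt-condition fixtures.

test_that("Bell rates and analytic crossovers follow from the mode spec", {
  spec <- condition_spec(
    label = "x", salt_mM = 50,
    modes = data.frame(fc_pN = 7, rate_at_fc = 1, dx_bind_nm = 0.6,
                       dx_unbind_nm = 0.6, weight = 1)
  )
  r <- bell_rates(spec, 7)
  expect_equal(unname(r["k_bind"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["k_unbind"]), 1, tolerance = 1e-12)
  expect_equal(crossover_force(spec), 7, tolerance = 1e-12)
  # zero Bell distances: rates are force-independent
  spec0 <- condition_spec(
    label = "x0", salt_mM = 50,
    modes = data.frame(fc_pN = 0, rate_at_fc = 2, dx_bind_nm = 0,
                       dx_unbind_nm = 0, weight = 1)
  )
  expect_equal(bell_rates(spec0, 3), bell_rates(spec0, 17))
})

test_that("shipped fixtures encode the printed critical-force ladder", {
  f75 <- fixture_condition("75mM")
  f20 <- fixture_condition("20mM")
  f42 <- fixture_condition("42mM")
  expect_equal(crossover_force(f75, 1), 7, tolerance = 1e-9)
  expect_equal(crossover_force(f20, 1), 15, tolerance = 1e-9)
  expect_equal(vapply(1:2, function(m) crossover_force(f42, m), numeric(1)),
               c(10, 15), tolerance = 1e-9)
  # truth record is consistent with the thermodynamic conversion
  tr <- condition_truth(f42)
  expect_equal(tr$dg0_star_kbt,
               binding_free_energy(c(10, 15), f42$n_released_nt, f42$wlc),
               tolerance = 1e-9)
  expect_error(fixture_condition("999mM"), "unknown condition")
})

test_that("telegraph traces have the right stationary occupancy", {
  spec <- condition_spec(
    label = "sym", salt_mM = 50,
    modes = data.frame(fc_pN = 5, rate_at_fc = 1, dx_bind_nm = 0.6,
                       dx_unbind_nm = 0.6, weight = 1),
    noise_sd = 0
  )
  # at the crossover both rates are 1/s: half the time bound
  tr <- make_telegraph_trace(spec, force = 5, duration = 2000, seed = 21)
  frac <- mean(attr(tr, "truth")$states)
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- fixture_condition("75mM")
  t1 <- make_telegraph_trace(spec, 7, 50, seed = 5)
  t2 <- make_telegraph_trace(spec, 7, 50, seed = 5)
  expect_identical(t1$extension_nm, t2$extension_nm)
  t3 <- make_telegraph_trace(spec, 7, 50, seed = 6)
  expect_false(identical(t3$extension_nm, t1$extension_nm))

  b1 <- make_condition_dataset(spec, forces = c(6, 8), n_traces = 2,
                               duration = 50, seed = 9)
  b2 <- make_condition_dataset(spec, forces = c(6, 8), n_traces = 2,
                               duration = 50, seed = 9)
  expect_identical(lapply(b1$traces, `[[`, "extension_nm"),
                   lapply(b2$traces, `[[`, "extension_nm"))
})

test_that("two-mode bundles draw traces from both modes by weight", {
  spec <- fixture_condition("42mM")
  b <- make_condition_dataset(spec, n_traces = 10, duration = 30, seed = 2)
  tab <- table(b$modes)
  expect_equal(length(tab), 2L)
  expect_gt(min(tab), 0.25 * length(b$modes))
  # a warning flags forces that do not bracket the crossover
  expect_warning(
    make_condition_dataset(spec, forces = c(1, 2), n_traces = 1,
                           duration = 30, seed = 2),
    "bracket"
  )
})
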