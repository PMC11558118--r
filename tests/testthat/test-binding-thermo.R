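# Critical force -> null-force binding free energy, and the detection of
# one versus two interaction modes.

test_that("binding free energy is minus the extension-jump free energy", {
  p <- wlc_params()
  expect_equal(binding_free_energy(0, 20, p), 0)
  dg7 <- binding_free_energy(7, 20, p)
  expect_lt(dg7, 0)
  kbt <- kBT_pN_nm(p$temperature)
  work_oracle <- 7 * 20 * p$contour_length_per_nt * wlc_extension(7, p) / kbt
  expect_equal(dg7, -(work_oracle - trapz_stretch_oracle(7, 20, p)),
               tolerance = 1e-4)
  # stronger binding <=> larger critical force <=> more negative dG0
  dg <- binding_free_energy(1:20, 20, p)
  expect_true(all(diff(abs(dg)) > 0))
  expect_true(all(diff(dg) < 0))
})

test_that("mode classification separates one from two Gaussian modes", {
  x1 <- withr::with_seed(11, rnorm(50, 15, 0.5))
  m1 <- classify_modes(x1)
  expect_true(m1$ok)
  expect_equal(m1$mode_count, 1L)
  expect_equal(m1$means, 15, tolerance = 0.3)

  x2 <- withr::with_seed(11, c(rnorm(25, 10, 0.5), rnorm(25, 15, 0.5)))
  m2 <- classify_modes(x2)
  expect_equal(m2$mode_count, 2L)
  expect_equal(m2$means[1], 10, tolerance = 0.5)
  expect_equal(m2$means[2], 15, tolerance = 0.5)

  # independent mixture-fit cross-check on the bimodal sample
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(x2, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(as.numeric(mc$parameters$mean)), sort(m2$means),
               tolerance = 0.3)

  expect_equal(classify_modes(rep(12, 20))$mode_count, 1L)
  expect_false(classify_modes(1:5)$ok)
})

test_that("per-trace critical forces recover noiseless Bell-mixture truth", {
  kbt <- kBT_pN_nm(300)
  forces <- rep(c(8, 10, 12, 14, 16), each = 6)
  mode <- rep(c(1, 2), length.out = length(forces))
  fc_true <- c(10, 15)[mode]
  s <- 1.2 / kbt  # (dx_bind + dx_unbind)/kBT
  y <- s * (forces - fc_true)  # ln(k_unbind / k_bind)
  pt <- data.frame(trace = seq_along(forces), force_pN = forces,
                   k_bind = exp(-y / 2), k_unbind = exp(y / 2),
                   n_bind = 100, n_unbind = 100)
  res <- per_trace_fc(pt)
  expect_equal(res$slope, s, tolerance = 1e-6)
  expect_equal(res$n_intercepts, 2L)
  expect_equal(sort(unique(round(res$f_c_samples, 6))), c(10, 15),
               tolerance = 1e-6)
})

test_that("salt profile reports the inter-mode free-energy jump", {
  p <- wlc_params()
  mk <- function(label, salt, fc, w = 1) {
    structure(list(condition_label = label, salt_mM = salt,
                   f_c = mean(fc), f_c_se = 0.1,
                   mode_count = length(fc), mode_fc = fc,
                   mode_weights = rep(w, length(fc)) / sum(rep(w, length(fc))),
                   delta_g0 = binding_free_energy(fc, 20, p),
                   n_released_nt = 20), class = "binding_energy_result")
  }
  # two unimodal conditions: jump across the regime midpoint
  prof <- energy_salt_profile(list(mk("a", 20, 15), mk("b", 75, 7)))
  expect_equal(prof$jump_kbt,
               abs(binding_free_energy(15, 20, p) - binding_free_energy(7, 20, p)),
               tolerance = 1e-10)
  # identical conditions: no jump
  prof0 <- energy_salt_profile(list(mk("a", 20, 15), mk("b", 75, 15)))
  expect_equal(prof0$jump_kbt, 0)
  # a bimodal condition defines the jump by its two modes
  prof2 <- energy_salt_profile(list(mk("a", 20, 15), mk("m", 42, c(10, 15)),
                                    mk("b", 75, 7)))
  expect_equal(prof2$jump_kbt,
               abs(diff(binding_free_energy(c(10, 15), 20, p))),
               tolerance = 1e-10)
  # single condition: profile only
  expect_true(is.na(energy_salt_profile(list(mk("a", 20, 15)))$jump_kbt))
})

test_that("pipeline recovers generator truth on a scaled-down condition", {
  # scaled replicates of the high-salt fixture: median recovered crossover
  # within 0.5 pN of the generator's analytic value
  spec <- fixture_condition("75mM")
  truth <- condition_truth(spec)
  fcs <- vapply(1:5, function(r) {
    b <- make_condition_dataset(spec, n_traces = 5, duration = 150,
                                seed = 100 + r)
    fits <- suppressWarnings(rates_vs_force(b$traces))
    critical_force(fits, n_boot = 0)$f_c
  }, numeric(1))
  expect_lt(abs(median(fcs) - truth$fc_star_pN[1]), 0.5)
  # end-to-end free energy within 0.5 kBT of the generator value
  dg <- binding_free_energy(median(fcs), spec$n_released_nt, spec$wlc)
  expect_lt(abs(dg - truth$dg0_star_kbt[1]), 0.5)
})
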