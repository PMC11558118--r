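# BAOAB Langevin integrator, restraints, and the merge/anchor plumbing.

test_that("zero-friction integration conserves energy on a stretched bond", {
  xyz <- rbind(c(0, 0, 0), c(4.3, 0, 0))  # bond stretched from r0 = 3.8
  topo <- bare_topology(
    xyz, bonds = data.frame(i = 1L, j = 2L, r0 = 3.8, k = 100)
  )
  p <- sim_params(friction = 0, wall_k = 0, exv_eps = 0, temperature = 1e-12,
                  dt = 5e-4)
  tr <- run_langevin(topo, p, n_steps = 1e5, stride = 100, seed = 1)
  etot <- tr$energy$total + tr$kinetic
  expect_lt((max(etot) - min(etot)) / etot[1], 1e-4)
  expect_false(tr$diverged)
})

test_that("a thermostatted bead in a harmonic well obeys equipartition", {
  topo <- bare_topology(rbind(c(0, 0, 0)))
  topo$anchors <- data.frame(i = 1L, x = 0, y = 0, z = 0, k = 1, r0 = 0)
  p <- sim_params(friction = 0.5, wall_k = 0, exv_eps = 0, dt = 0.05,
                  temperature = 300)
  tr <- run_langevin(topo, p, n_steps = 1e6, stride = 20L, seed = 2)
  xs <- tr$frames[1, , ]  # 3 x n_frames
  v <- mean(apply(xs, 1, function(u) mean(u^2)))
  expect_equal(v, kBT_kcal(300) / 1, tolerance = 0.03)
  # kinetic-energy temperature estimator within 2%
  expect_equal(tr$temperature_estimate, 300, tolerance = 0.02)
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  cx <- make_toy_tetramer(seed = 1)
  p <- sim_params(salt_molar = 0.1)
  topo <- build_complex_topology(cx, "bridged", p)
  t1 <- run_langevin(topo, p, n_steps = 2000, stride = 100, seed = 7)
  t2 <- run_langevin(topo, p, n_steps = 2000, stride = 100, seed = 7)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energy, t2$energy)
  t3 <- run_langevin(topo, p, n_steps = 2000, stride = 100, seed = 8)
  expect_false(identical(t3$frames, t1$frames))
})

test_that("anchor restraints store the right energy and suppress motion", {
  topo <- bare_topology(rbind(c(0, 0, 0)))
  topo <- apply_anchor(topo, rbind(c(0, 0, 0)), bead_idx = 1L, k = 0.3)
  p <- sim_params(wall_k = 0, exv_eps = 0)
  # displaced 2 A: U = 0.5 * 0.3 * 4 = 0.6 kcal/mol
  e <- total_energy_and_forces(rbind(c(2, 0, 0)), topo, p)
  expect_equal(e$terms[["anchors"]], 0.6, tolerance = 1e-12)
  expect_equal(e$total, 0.6, tolerance = 1e-12)
  expect_error(apply_anchor(topo, bead_idx = integer(0)), "empty")
  expect_error(apply_anchor(topo, bead_idx = 5L), "out of range")

  # anchored bead fluctuates less than a free one (paired seeds)
  free <- bare_topology(rbind(c(0, 0, 0)))
  rmsf <- function(tp) {
    tr <- run_langevin(tp, p, n_steps = 2e4, stride = 10, seed = 5)
    mean(apply(tr$frames[1, , ], 1, stats::sd))
  }
  expect_lt(rmsf(topo), rmsf(free))
})

test_that("the equivalent-length spring adds exactly one energy term", {
  cx <- make_toy_tetramer(seed = 1)
  p <- sim_params(salt_molar = 0.1)
  t_no <- build_complex_topology(cx, "bridged", p, anchor = FALSE,
                                 length_spring = FALSE)
  t_sp <- equivalent_length_spring(t_no)
  # at the reference the spring sits at its rest length: zero energy
  e_no <- total_energy_and_forces(t_no$xyz, t_no, p)
  e_sp <- total_energy_and_forces(t_sp$xyz, t_sp, p)
  expect_equal(e_sp$terms[["anchors"]], 0, tolerance = 1e-10)
  expect_equal(e_sp$total, e_no$total, tolerance = 1e-10)
  # off the reference only the anchors term differs
  others <- setdiff(names(e_no$terms), "anchors")
  s_idx <- t_no$nt_index$S
  x2 <- t_no$xyz
  x2[s_idx[length(s_idx)], ] <- x2[s_idx[length(s_idx)], ] + c(3, 0, 0)
  d2_no <- total_energy_and_forces(x2, t_no, p)
  d2_sp <- total_energy_and_forces(x2, t_sp, p)
  expect_gt(d2_sp$terms[["anchors"]], 0)
  expect_equal(d2_sp$terms[others], d2_no$terms[others], tolerance = 1e-12)
  # the spring extends the effective tether by about one backbone rise
  an <- t_sp$anchors[nrow(t_sp$anchors), ]
  expect_equal(an$r0, 6.3)
})

test_that("uncharged, uncoupled molecules only interact through exclusion", {
  cx <- make_toy_tetramer(seed = 1)
  p <- sim_params(salt_molar = 0.1)
  p$epsilon_interface <- 1e-300   # switch the interface term off
  topo <- build_complex_topology(cx, "bridged", p, anchor = FALSE,
                                 length_spring = FALSE)
  topo$charge[] <- 0
  x <- topo$xyz + 0.3
  ef <- total_energy_and_forces(x, topo, p)
  expect_equal(ef$terms[["elec"]], 0)
  expect_lt(abs(ef$terms[["interface"]]), 1e-250)
})
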