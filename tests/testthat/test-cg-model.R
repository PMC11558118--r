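# Topology builders and the individual energy terms of the coarse-grained
# model.

test_that("an extended chain gives the expected bonded terms and no contacts", {
  df <- data.frame(chain = "A", resno = 1:10, resid = "GLY",
                   x = 3.8 * (0:9), y = 0, z = 0)
  topo <- build_protein_topology(df)
  expect_equal(nrow(topo$bonds), 9L)
  expect_equal(nrow(topo$angles), 8L)
  expect_equal(nrow(topo$dihedrals), 7L)
  expect_equal(nrow(topo$contacts), 0L)
  expect_equal(topo$bonds$r0, rep(3.8, 9))
  expect_equal(topo$angles$theta0, rep(pi, 8))
})

test_that("native contact detection equals a brute-force scan", {
  cx <- make_toy_tetramer(n_res_per_subunit = 60, seed = 5)
  one <- cx$protein[cx$protein$chain == "A", ]
  topo <- build_protein_topology(one)
  xyz <- as.matrix(one[, c("x", "y", "z")])
  brute <- 0L
  for (i in 1:(nrow(xyz) - 1)) {
    for (j in (i + 1):nrow(xyz)) {
      if (abs(one$resno[j] - one$resno[i]) >= 4 &&
          sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 6.5) {
        brute <- brute + 1L
      }
    }
  }
  expect_gt(brute, 0L)
  expect_equal(nrow(topo$contacts), brute)
})

test_that("ssDNA topology has the 3N-1 bead layout with phosphate charges", {
  tt <- build_ssdna_topology("TT")
  expect_equal(nrow(tt$xyz), 5L)
  expect_equal(nrow(tt$bonds), 4L)
  expect_equal(nrow(tt$contacts), 1L)  # one stacking pair
  t19 <- build_ssdna_topology(strrep("T", 19))
  expect_equal(nrow(t19$xyz), 56L)
  expect_equal(sum(t19$charge != 0), 18L)
  expect_true(all(t19$charge[t19$kind == "P"] == -0.6))
  t70 <- build_ssdna_topology(strrep("T", 70))
  expect_equal(nrow(t70$xyz), 209L)
  expect_error(build_ssdna_topology("TXT"), "invalid nucleotide")
})

test_that("charge overlays replace protein charges and shift energies", {
  cx <- make_toy_tetramer(seed = 3)
  params <- sim_params(salt_molar = 0.1)
  topo <- build_complex_topology(cx, "unbridged", params,
                                 anchor = FALSE, length_spring = FALSE)
  # equal overlays for both states give identical energies
  ov_same <- cx$overlays
  ov_same$charge_e <- 0.3
  t_a <- assign_charge_state(topo, "unbridged", ov_same)
  t_b <- assign_charge_state(topo, "bridged", ov_same)
  x <- topo$xyz + 0.1
  expect_equal(total_energy_and_forces(x, t_a, params)$total,
               total_energy_and_forces(x, t_b, params)$total)
  # DNA charges are untouched
  expect_equal(t_a$charge[t_a$molecule == 2L], topo$charge[topo$molecule == 2L])
  # +0.2 e on 8 pocket residues per subunit = +6.4 e in total
  ovu <- cx$overlays[cx$overlays$state == "unbridged", ]
  ovb <- ovu
  ovb$state <- "bridged"
  pocket <- paste(cx$groove_residues$subunit, cx$groove_residues$residue_index)
  is_pocket <- paste(ovb$subunit, ovb$residue_index) %in% pocket
  ovb$charge_e[is_pocket] <- ovb$charge_e[is_pocket] + 0.2
  t_u <- assign_charge_state(topo, "unbridged", rbind(ovu, ovb))
  t_v <- assign_charge_state(topo, "bridged", rbind(ovu, ovb))
  expect_equal(sum(t_v$charge) - sum(t_u$charge), 6.4, tolerance = 1e-9)
  # a -0.6 e phosphate 10 A above the pocket is more attracted in the
  # more positive bridged state
  pk <- which(t_u$molecule == 1L & paste(t_u$subunit, t_u$resno) %in% pocket)
  probe <- colMeans(t_u$xyz[pk[1:8], , drop = FALSE])
  probe <- probe + 10 * probe / sqrt(sum(probe^2))
  lam <- debye_length(0.1)
  e_u <- electrostatic_energy(t_u$xyz[pk, , drop = FALSE], t_u$charge[pk],
                              rbind(probe), -0.6, lam)
  e_v <- electrostatic_energy(t_v$xyz[pk, , drop = FALSE], t_v$charge[pk],
                              rbind(probe), -0.6, lam)
  expect_lt(e_v, e_u)
  # overlays must cover every charged residue
  expect_error(assign_charge_state(topo, "bridged", ovu[-1, ]),
               "misses charged|no rows")
})

test_that("interface reference distances follow the nearest-base rule", {
  prot <- rbind(c(0, 0, 5), c(0, 0, 11))
  bases <- rbind(c(0, 0, 0), c(30, 0, 0))
  tab <- interface_reference_distances(prot, bases, cutoff = 10)
  expect_equal(tab$i, 1L)         # the 11 A residue is excluded
  expect_equal(tab$r0, 5)
  expect_warning(interface_reference_distances(rbind(c(100, 0, 0)), bases, 10),
                 "no protein residue")
  # brute-force oracle on the toy complex
  cx <- make_toy_tetramer(seed = 2)
  pxyz <- as.matrix(cx$protein[, c("x", "y", "z")])
  tab2 <- interface_reference_distances(pxyz, cx$dna$B, cutoff = 10)
  for (r in sample(nrow(tab2), 10)) {
    i <- tab2$i[r]
    dmin <- min(sqrt(rowSums(sweep(cx$dna$B, 2, pxyz[i, ])^2)))
    expect_equal(tab2$r0[r], dmin, tolerance = 1e-12)
  }
})

test_that("the 12-10 interface potential has depth -epsilon at r_i0", {
  iface <- data.frame(i = 1L, r0 = 6)
  prot <- rbind(c(0, 0, 0))
  expect_equal(interface_contact_energy(prot, rbind(c(6, 0, 0)), iface),
               -0.2325, tolerance = 1e-12)
  # r = 2 r0: eps * (5/4096 - 6/1024)
  expect_equal(interface_contact_energy(prot, rbind(c(12, 0, 0)), iface),
               0.2325 * (5 / 4096 - 6 / 1024), tolerance = 1e-12)
  expect_lt(abs(interface_contact_energy(prot, rbind(c(6000, 0, 0)), iface)),
            1e-10)
  expect_error(interface_contact_energy(prot, rbind(c(0, 0, 0)), iface),
               "singular")
  # the isolated-pair minimum sits exactly at r_i0
  rr <- seq(5, 7, by = 0.01)
  en <- vapply(rr, function(r) {
    interface_contact_energy(prot, rbind(c(r, 0, 0)), iface)
  }, numeric(1))
  expect_equal(rr[which.min(en)], 6, tolerance = 0.011)
})

test_that("Debye length scales with salt and matches physical constants", {
  expect_equal(debye_length(0.04) / debye_length(0.16), 2, tolerance = 1e-12)
  # hand evaluation: sqrt(eps0 * 78 * kB * 300 / (2 e^2 N_A * 150 mol/m^3))
  # = 0.7854 nm (approximately the textbook 0.304/sqrt(I) rule)
  expect_equal(debye_length(0.150, 300, 78), 0.7854, tolerance = 1e-3)
  expect_gt(debye_length(0.01), debye_length(0.3))
  expect_error(debye_length(0), "salt")
})

test_that("screened electrostatics matches a hand-evaluated pair", {
  a <- rbind(c(0, 0, 0)); b <- rbind(c(7.8, 0, 0))
  expect_equal(electrostatic_energy(a, 0, b, -1, 0.78), 0)
  e <- electrostatic_energy(a, 1, b, -1, 0.78, relative_permittivity = 78)
  hand <- 332.0637 * (-1) / 78 * (exp(-1) / 7.8 - exp(-5) / 39)
  expect_equal(e, hand, tolerance = 1e-12)
  # stronger screening (higher salt, shorter lambda) weakens the pair energy
  e_hi <- electrostatic_energy(a, 1, b, -1, debye_length(0.3))
  e_lo <- electrostatic_energy(a, 1, b, -1, debye_length(0.01))
  expect_lt(abs(e_hi), abs(e_lo))
})

test_that("total energy: native reference, linearity in epsilon, invariance", {
  cx <- make_toy_tetramer(seed = 1)
  params <- sim_params(salt_molar = 0.15)
  topo <- build_complex_topology(cx, "bridged", params,
                                 anchor = FALSE, length_spring = FALSE)
  ef <- total_energy_and_forces(topo$xyz, topo, params)
  expect_lt(abs(ef$terms[["bonds"]]), 1e-18)
  expect_lt(abs(ef$terms[["angles"]]), 1e-18)
  expect_lt(abs(ef$terms[["dihedrals"]]), 1e-18)
  # every native contact sits at its minimum: contact term = -sum(eps)
  expect_equal(ef$terms[["contacts"]], -sum(topo$contacts$eps),
               tolerance = 1e-9)

  # doubling the interface coupling doubles that term only
  p2 <- params
  p2$epsilon_interface <- 2 * params$epsilon_interface
  x <- topo$xyz + withr::with_seed(13, matrix(rnorm(length(topo$xyz), 0, 0.2),
                                              ncol = 3))
  e1 <- total_energy_and_forces(x, topo, params)
  e2 <- total_energy_and_forces(x, topo, p2)
  expect_equal(e2$terms[["interface"]], 2 * e1$terms[["interface"]],
               tolerance = 1e-12)
  others <- setdiff(names(e1$terms), "interface")
  expect_equal(e2$terms[others], e1$terms[others], tolerance = 1e-12)

  # rigid rotation + translation leaves the energy unchanged (no anchors)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xr <- sweep(x %*% t(R), 2, c(5, -3, 2), "+")
  p_nowall <- params
  p_nowall$wall_k <- 0
  er <- total_energy_and_forces(xr, topo, p_nowall)
  e0 <- total_energy_and_forces(x, topo, p_nowall)
  expect_equal(er$total, e0$total, tolerance = 1e-9)
})

test_that("analytic gradients match central finite differences", {
  cx <- make_toy_tetramer(seed = 4)
  params <- sim_params(salt_molar = 0.05)
  topo <- build_complex_topology(cx, "unbridged", params)
  worst <- 0
  withr::with_seed(13, {
    for (cfg in 1:10) {
      x <- topo$xyz + matrix(rnorm(length(topo$xyz), 0, 0.2), ncol = 3)
      worst <- max(worst, max_fd_gradient_error(x, topo, params))
    }
  })
  expect_lt(worst, 1e-5)
})
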