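# Local frame, projection, 2D PMF and subunit occupancy.

test_that("the local frame is orthonormal, right-handed and equivariant", {
  cx <- make_toy_tetramer(seed = 1)
  xyz <- as.matrix(cx$protein[, c("x", "y", "z")])
  fr <- local_frame(xyz)
  R <- fr$rotation
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(det(R), 1, tolerance = 1e-12)
  # D2-symmetric tetramer: origin at the symmetry centre
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(local_frame(cbind(0:9, 0, 0)), "degenerate|not unique")
})

test_that("projection is invariant under rigid motion of the whole system", {
  cx <- make_toy_tetramer(seed = 1)
  p <- sim_params()
  topo <- build_complex_topology(cx, "bridged", p, anchor = FALSE,
                                 length_spring = FALSE)
  prot_xyz <- topo$xyz[topo$molecule == 1L, , drop = FALSE]
  fr <- local_frame(prot_xyz)
  sel <- topo$nt_index$B[1L]
  base <- project_dna(topo$xyz, fr, topo, sel)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- sweep(topo$xyz %*% t(R), 2, c(12, -7, 30), "+")
  expect_equal(project_dna(moved, fr, topo, sel), base, tolerance = 1e-8)
  # pure Z translation in particular
  ztrans <- sweep(topo$xyz, 2, c(0, 0, 55), "+")
  expect_equal(project_dna(ztrans, fr, topo, sel), base, tolerance = 1e-8)
})

test_that("projection reproduces a constructed circular path", {
  cx <- make_toy_tetramer(seed = 1)
  p <- sim_params()
  topo <- build_complex_topology(cx, "bridged", p, anchor = FALSE,
                                 length_spring = FALSE)
  prot <- which(topo$molecule == 1L)
  fr <- local_frame(topo$xyz[prot, , drop = FALSE])
  sel <- topo$nt_index$B[1L]
  Rr <- 17
  nfr <- 60
  frames <- array(rep(topo$xyz, nfr), dim = c(nrow(topo$xyz), 3, nfr))
  for (f in seq_len(nfr)) {
    ang <- 2 * pi * f / nfr
    # place the selected bead on a circle of radius Rr in the frame plane
    pos <- fr$origin + Rr * cos(ang) * fr$rotation[, 1] +
      Rr * sin(ang) * fr$rotation[, 2]
    frames[sel, , f] <- pos
  }
  traj <- structure(list(frames = frames), class = "cg_trajectory")
  xy <- project_dna(traj, fr, topo, sel)
  expect_equal(sqrt(rowSums(xy^2)), rep(Rr, nfr), tolerance = 1e-6)
})

test_that("PMF of uniform samples is flat and of a Gaussian is quadratic", {
  u <- withr::with_seed(10, cbind(runif(2e5, -10, 10), runif(2e5, -10, 10)))
  pu <- pmf2d(u, bin_width = 2)
  expect_equal(min(pu$free_energy, na.rm = TRUE), 0)
  expect_lt(max(pu$free_energy, na.rm = TRUE), 0.5)

  sigma <- 5
  g <- withr::with_seed(4, matrix(rnorm(2e5, 0, sigma), ncol = 2))
  pg <- pmf2d(g, bin_width = 1)
  grid <- expand.grid(x = pg$x_mid, y = pg$y_mid)
  f <- as.numeric(pg$free_energy)
  w <- as.numeric(pg$counts)
  ok <- !is.na(f) & w > 20
  fit <- stats::lm(f[ok] ~ I((grid$x[ok]^2 + grid$y[ok]^2) / 2),
                   weights = w[ok])
  curv <- unname(stats::coef(fit)[2])
  expect_equal(curv, 1 / sigma^2, tolerance = 0.05)

  expect_error(pmf2d(g[1:10, , drop = FALSE]), "at least")
})

test_that("subunit occupancy counts constructed geometries correctly", {
  cx <- make_toy_tetramer(seed = 1)
  p <- sim_params()
  topo <- build_complex_topology(cx, "bridged", p, anchor = FALSE,
                                 length_spring = FALSE)
  dna <- which(topo$molecule == 2L)
  # DNA far away: nothing occupied
  far <- topo$xyz
  far[dna, ] <- far[dna, ] + 500
  expect_equal(subunit_occupancy(far, topo), 0L)
  # native wrapped reference touches all four subunits
  expect_equal(subunit_occupancy(topo$xyz, topo), 4L)
  # brute-force oracle at an intermediate displacement
  half <- topo$xyz
  half[dna, ] <- half[dna, ] + 12
  got <- subunit_occupancy(half, topo, cutoff = 10, min_nt = 3)
  prot <- which(topo$molecule == 1L)
  brute <- 0L
  for (s in sort(unique(topo$subunit[prot]))) {
    sres <- prot[topo$subunit[prot] == s]
    nts <- unique(topo$resno[dna])
    n_touch <- 0L
    for (nt in nts) {
      beads <- dna[topo$resno[dna] == nt]
      mind <- min(vapply(beads, function(b) {
        min(sqrt(rowSums(sweep(half[sres, , drop = FALSE], 2, half[b, ])^2)))
      }, numeric(1)))
      if (mind <= 10) n_touch <- n_touch + 1L
    }
    if (n_touch >= 3L) brute <- brute + 1L
  }
  expect_equal(got, brute)
  # occupancy is invariant under rigid motion
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  expect_equal(subunit_occupancy(sweep(half %*% t(R), 2, c(3, 4, 5), "+"), topo),
               got)
})

test_that("a constructed thread through three subunits counts three", {
  cx <- make_toy_tetramer(seed = 1)
  p <- sim_params()
  topo <- build_complex_topology(cx, "bridged", p, anchor = FALSE,
                                 length_spring = FALSE)
  dna <- which(topo$molecule == 2L)
  prot <- which(topo$molecule == 1L)
  x <- topo$xyz
  x[dna, ] <- x[dna, ] + 500  # park everything far away
  # plant 4 nucleotides on each of subunits 1-3
  nts <- unique(topo$resno[dna])
  for (s in 1:3) {
    cen <- colMeans(topo$xyz[prot[topo$subunit[prot] == s], , drop = FALSE])
    for (q in 1:4) {
      nt <- nts[(s - 1) * 4 + q]
      beads <- dna[topo$resno[dna] == nt]
      for (b in beads) x[b, ] <- cen + runif(3, -2, 2)
    }
  }
  expect_equal(subunit_occupancy(x, topo, cutoff = 10, min_nt = 3), 3L)
})
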