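# Shared helpers for building small in-code fixtures.

# minimal bead topology with only the supplied term tables filled in
bare_topology <- function(xyz, charge = numeric(nrow(xyz)),
                          molecule = rep(1L, nrow(xyz)),
                          subunit = rep(1L, nrow(xyz)),
                          resno = seq_len(nrow(xyz)),
                          kind = rep("CA", nrow(xyz)),
                          bonds = NULL, angles = NULL, dihedrals = NULL,
                          contacts = NULL, interface = NULL,
                          base_idx = integer(0)) {
  empty <- list(
    bonds = data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                       k = numeric(0)),
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0), kth = numeric(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), phi0 = numeric(0), kphi = numeric(0)),
    contacts = data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                          eps = numeric(0)),
    interface = data.frame(i = integer(0), r0 = numeric(0))
  )
  structure(list(
    xyz = xyz, kind = kind, molecule = molecule, chain = molecule,
    subunit = subunit, resno = resno, resid = rep("GLY", nrow(xyz)),
    charge = charge,
    bonds = if (is.null(bonds)) empty$bonds else bonds,
    angles = if (is.null(angles)) empty$angles else angles,
    dihedrals = if (is.null(dihedrals)) empty$dihedrals else dihedrals,
    contacts = if (is.null(contacts)) empty$contacts else contacts,
    interface = if (is.null(interface)) empty$interface else interface,
    anchors = data.frame(i = integer(0), x = numeric(0), y = numeric(0),
                         z = numeric(0), k = numeric(0), r0 = numeric(0)),
    base_idx = base_idx
  ), class = "bead_topology")
}

# trapezoid-rule oracle for the WLC stretch energy (kBT), dense grid
trapz_stretch_oracle <- function(force, n_nt, params, n_grid = 1e5) {
  lc <- n_nt * params$contour_length_per_nt
  zmax <- wlc_extension(force, params)
  z <- seq(0, zmax, length.out = n_grid)
  f <- wlc_force(z, params)
  sum((f[-1] + f[-n_grid]) / 2 * diff(z)) * lc / kBT_pN_nm(params$temperature)
}

# square-wave two-level trace
square_wave_trace <- function(low = 600, high = 630, half_period_s = 5,
                              duration_s = 100, fs = 1, force = 5) {
  n <- duration_s * fs
  t <- (seq_len(n) - 1) / fs
  state <- (floor(t / half_period_s) %% 2) == 0
  ext <- ifelse(state, low, high)
  force_extension_trace(t, ext, force, fs)
}

# finite-difference gradient check on a handful of random coordinates
max_fd_gradient_error <- function(coords, topo, params, n_checks = 6,
                                  h = 1e-5) {
  ef <- total_energy_and_forces(coords, topo, params)
  picks <- cbind(sample(seq_len(nrow(coords)), n_checks, replace = TRUE),
                 sample(1:3, n_checks, replace = TRUE))
  worst <- 0
  for (q in seq_len(n_checks)) {
    i <- picks[q, 1]; d <- picks[q, 2]
    xp <- coords; xm <- coords
    xp[i, d] <- xp[i, d] + h
    xm[i, d] <- xm[i, d] - h
    fd <- (total_energy_and_forces(xp, topo, params)$total -
             total_energy_and_forces(xm, topo, params)$total) / (2 * h)
    worst <- max(worst, abs(fd - ef$gradient[i, d]) / max(abs(fd), 1e-6))
  }
  worst
}
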