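# Langevin dynamics driver and restraint plumbing around the compiled
# energy engine.

#' Merge a protein and an ssDNA topology into one simulation system
#'
#' Concatenates the two bead tables (protein first) and computes the
#' interface reference-distance table r_i0 from the reference coordinates of
#' the combined complex.
#'
#' @param protein a protein `bead_topology`
#' @param dna an ssDNA `bead_topology` whose reference coordinates are the
#'   bound (wrapped) pose
#' @param params a [sim_params()]
#' @return a combined `bead_topology` with `interface` and `base_idx` set
#' @export
merge_topologies <- function(protein, dna, params = sim_params()) {
  stopifnot(inherits(protein, "bead_topology"), inherits(dna, "bead_topology"))
  np <- nrow(protein$xyz)
  shift <- function(df, cols) {
    df[cols] <- lapply(df[cols], function(v) v + np)
    df
  }
  topo <- .new_topology(
    xyz = rbind(protein$xyz, dna$xyz),
    kind = c(protein$kind, dna$kind),
    molecule = c(protein$molecule, dna$molecule),
    chain = c(protein$chain, dna$chain + max(protein$chain)),
    subunit = c(protein$subunit, dna$subunit),
    resno = c(protein$resno, dna$resno),
    resid = c(protein$resid, dna$resid),
    charge = c(protein$charge, dna$charge),
    bonds = rbind(protein$bonds, shift(dna$bonds, c("i", "j"))),
    angles = rbind(protein$angles, shift(dna$angles, c("i", "j", "k"))),
    dihedrals = rbind(protein$dihedrals, shift(dna$dihedrals, c("i", "j", "k", "l"))),
    contacts = rbind(protein$contacts, shift(dna$contacts, c("i", "j")))
  )
  base_idx <- np + which(dna$kind == "B")
  topo$base_idx <- base_idx
  topo$interface <- interface_reference_distances(
    protein$xyz, topo$xyz[base_idx, , drop = FALSE],
    cutoff = params$interface_cutoff
  )
  if (!is.null(dna$nt_index)) {
    topo$nt_index <- lapply(dna$nt_index, function(v) v + np)
  }
  topo
}

#' Add harmonic anchor restraints to selected beads
#'
#' Each selected bead gets `U = k/2 * |r - r_ref|^2` toward its reference
#' position.
#'
#' @param topology a `bead_topology`
#' @param reference reference coordinates: full n x 3 matrix (rows picked by
#'   `bead_idx`) or a `length(bead_idx)` x 3 matrix
#' @param bead_idx beads to restrain (1-based, nonempty)
#' @param k spring constant, kcal mol^-1 A^-2
#' @return the topology with added anchors
#' @export
apply_anchor <- function(topology, reference = topology$xyz, bead_idx,
                         k = 0.3) {
  stopifnot(inherits(topology, "bead_topology"))
  if (length(bead_idx) == 0L) stop("empty anchor selection")
  if (any(bead_idx < 1L | bead_idx > nrow(topology$xyz))) {
    stop("anchor selection out of range")
  }
  ref <- if (nrow(reference) == nrow(topology$xyz)) {
    reference[bead_idx, , drop = FALSE]
  } else {
    stopifnot(nrow(reference) == length(bead_idx))
    reference
  }
  add <- data.frame(i = bead_idx, x = ref[, 1], y = ref[, 2], z = ref[, 3],
                    k = k, r0 = 0)
  if (!"r0" %in% names(topology$anchors)) topology$anchors$r0 <- numeric(0)
  topology$anchors <- rbind(topology$anchors, add)
  topology
}

#' Replace a leading nucleotide by an equivalent-length spring
#'
#' Adds a radial harmonic spring of rest length one backbone rise between a
#' fixed anchor point and a terminal sugar bead, so a chain of N simulated
#' nucleotides behaves as N + 1 in total tether length.
#'
#' @param topology a combined `bead_topology` with `nt_index`
#' @param anchor_point fixed point, length-3; default extends the reference
#'   backbone by one rise beyond the 3' terminal sugar
#' @param sugar_idx bead index of the terminal sugar; default the 3'-terminal
#'   sugar
#' @param rise rest length in Angstrom (one backbone rise)
#' @param k spring constant, kcal mol^-1 A^-2
#' @return the topology with one added radial spring
#' @export
equivalent_length_spring <- function(topology, anchor_point = NULL,
                                     sugar_idx = NULL, rise = 6.3, k = 100) {
  stopifnot(inherits(topology, "bead_topology"))
  if (is.null(topology$nt_index)) stop("topology has no ssDNA")
  s_idx <- topology$nt_index$S
  if (is.null(sugar_idx)) sugar_idx <- s_idx[length(s_idx)]
  if (is.null(anchor_point)) {
    last <- topology$xyz[s_idx[length(s_idx)], ]
    prev <- topology$xyz[s_idx[length(s_idx) - 1L], ]
    dirv <- last - prev
    anchor_point <- last + rise * dirv / sqrt(sum(dirv^2))
  }
  add <- data.frame(i = sugar_idx, x = anchor_point[1], y = anchor_point[2],
                    z = anchor_point[3], k = k, r0 = rise)
  if (!"r0" %in% names(topology$anchors)) topology$anchors$r0 <- numeric(0)
  topology$anchors <- rbind(topology$anchors, add)
  topology
}

# Marshal topology + params into the flat list the C++ engine consumes
# (0-based indices, precomputed pair lists).
.engine_topology <- function(topology, params) {
  n <- nrow(topology$xyz)
  an <- topology$anchors
  if (!"r0" %in% names(an)) an$r0 <- rep(0, nrow(an))

  # electrostatics: charged inter-molecular pairs
  qi <- which(topology$charge != 0 & topology$molecule == 1L)
  qj <- which(topology$charge != 0 & topology$molecule == 2L)
  if (length(qi) && length(qj)) {
    eg <- expand.grid(i = qi, j = qj)
    e_qq <- topology$charge[eg$i] * topology$charge[eg$j]
  } else {
    eg <- data.frame(i = integer(0), j = integer(0))
    e_qq <- numeric(0)
  }
  lambda_A <- 10 * debye_length(params$salt_molar, params$temperature,
                                params$relative_permittivity)

  # excluded-volume candidates: all pairs minus 1-2, 1-3, contact/stacking
  # and interface residue-base pairs
  key <- function(i, j) {
    a <- pmin(i, j); b <- pmax(i, j)
    (a - 1) * n + b
  }
  excl <- c(
    key(topology$bonds$i, topology$bonds$j),
    key(topology$angles$i, topology$angles$k),
    key(topology$contacts$i, topology$contacts$j),
    if (nrow(topology$interface) && length(topology$base_idx)) {
      ig <- expand.grid(i = topology$interface$i, j = topology$base_idx)
      key(ig$i, ig$j)
    }
  )
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  allk <- key(ut[, 1], ut[, 2])
  keep <- !(allk %in% excl)
  x_i <- ut[keep, 1]; x_j <- ut[keep, 2]

  iface <- topology$interface
  list(
    n = n,
    b_i = as.integer(topology$bonds$i - 1L), b_j = as.integer(topology$bonds$j - 1L),
    b_r0 = topology$bonds$r0, b_k = topology$bonds$k,
    a_i = as.integer(topology$angles$i - 1L), a_j = as.integer(topology$angles$j - 1L),
    a_k = as.integer(topology$angles$k - 1L),
    a_t0 = topology$angles$theta0, a_kth = topology$angles$kth,
    d_i = as.integer(topology$dihedrals$i - 1L), d_j = as.integer(topology$dihedrals$j - 1L),
    d_k = as.integer(topology$dihedrals$k - 1L), d_l = as.integer(topology$dihedrals$l - 1L),
    d_p0 = topology$dihedrals$phi0, d_kphi = topology$dihedrals$kphi,
    c_i = as.integer(topology$contacts$i - 1L), c_j = as.integer(topology$contacts$j - 1L),
    c_r0 = topology$contacts$r0, c_eps = topology$contacts$eps,
    f_i = as.integer(iface$i - 1L), f_r0 = iface$r0,
    base_idx = as.integer(topology$base_idx - 1L),
    eps_interface = params$epsilon_interface,
    e_i = as.integer(eg$i - 1L), e_j = as.integer(eg$j - 1L), e_qq = e_qq,
    lambda = lambda_A, elec_rc = params$elec_cutoff_factor * lambda_A,
    eps_r = params$relative_permittivity,
    x_i = as.integer(x_i - 1L), x_j = as.integer(x_j - 1L),
    exv_sigma = params$exv_sigma, exv_eps = params$exv_eps,
    an_i = as.integer(an$i - 1L), an_x = an$x, an_y = an$y, an_z = an$z,
    an_k = an$k, an_r0 = an$r0,
    wall_center = colMeans(topology$xyz[topology$molecule == 1L, , drop = FALSE]),
    wall_radius = params$wall_radius, wall_k = params$wall_k
  )
}

#' Energy breakdown and analytic gradient of a configuration
#'
#' @param coords n x 3 coordinates, Angstrom
#' @param topology a `bead_topology`
#' @param params a [sim_params()]
#' @return list with `terms` (named kcal/mol), `total` and `gradient`
#'   (n x 3, dU/dx in kcal mol^-1 A^-1)
#' @export
total_energy_and_forces <- function(coords, topology, params = sim_params()) {
  stopifnot(inherits(topology, "bead_topology"),
            is.matrix(coords), nrow(coords) == nrow(topology$xyz),
            ncol(coords) == 3L)
  cpp_energy_forces(coords, .engine_topology(topology, params))
}

#' Run BAOAB Langevin dynamics
#'
#' Underdamped Langevin dynamics in the BAOAB splitting with an internal
#' counter-based RNG: a fixed `(topology, params, n_steps, stride, seed)`
#' tuple reproduces the trajectory bit for bit. With `friction = 0` the
#' scheme reduces to velocity Verlet (no thermostat).
#'
#' @param topology a `bead_topology` (anchors included)
#' @param params a [sim_params()]
#' @param n_steps number of integration steps
#' @param stride store every `stride`-th frame
#' @param seed RNG seed (integer)
#' @param coords0 starting coordinates; default the topology reference
#' @param energy_abort abort threshold on |total energy|, kcal/mol
#' @return a `cg_trajectory`: `frames` (n x 3 x n_frames), `energy` (per
#'   frame, by term), `kinetic`, `temperature_estimate` (K), `diverged`,
#'   `final_coords`, `dt`, `seed`, `params`
#' @export
run_langevin <- function(topology, params = sim_params(), n_steps = 1e5,
                         stride = 500L, seed = params$seed,
                         coords0 = topology$xyz, energy_abort = 1e8) {
  stopifnot(inherits(topology, "bead_topology"), n_steps >= 1, stride >= 1)
  et <- .engine_topology(topology, params)
  kbt <- kBT_kcal(params$temperature)
  res <- cpp_run_langevin(coords0, et, as.integer(n_steps), as.integer(stride),
                          params$dt, params$friction, kbt, params$mass,
                          as.integer(seed), energy_abort)
  nf <- res$frames_done
  n <- nrow(topology$xyz)
  frames <- res$frames
  if (nf < dim(frames)[3]) frames <- frames[, , seq_len(nf), drop = FALSE]
  ke <- res$kinetic[seq_len(nf)]
  t_est <- mean(2 * ke / (3 * n * .KB_KCAL))
  structure(list(
    frames = frames,
    energy = as.data.frame(res$energy[seq_len(nf), , drop = FALSE]),
    kinetic = ke,
    temperature_estimate = t_est,
    diverged = res$diverged,
    final_coords = res$final_coords,
    n_steps = n_steps, stride = stride, dt = params$dt,
    seed = seed, params = params
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "CG Langevin trajectory: %d frames (%g steps, dt = %.4g, stride %d), T_est = %.1f K%s\n",
    dim(x$frames)[3], x$n_steps, x$dt, x$stride, x$temperature_estimate,
    if (x$diverged) " [DIVERGED]" else ""
  ))
  invisible(x)
}
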