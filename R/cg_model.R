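# Coarse-grained model builders: one bead per protein residue (C-alpha),
# three beads per nucleotide (phosphate P, sugar S, base B), with a
# structure-based (Go-type) intra-protein potential, a 12-10 residue-base
# interface potential anchored at crystal-reference distances r_i0, screened
# Debye-Hueckel electrostatics between protein charges and phosphates, and
# soft excluded volume.
#
# Units: Angstrom, kcal/mol, unit bead masses; time in the reduced unit
# sqrt(mass * A^2 / (kcal/mol)).

#' Simulation and energy-function parameters
#'
#' @param epsilon_interface depth scale of the residue-base 12-10 interface
#'   potential, kcal/mol (default 0.2325)
#' @param salt_molar monovalent salt concentration, M
#' @param relative_permittivity solvent dielectric constant (default 78)
#' @param temperature Kelvin (default 300)
#' @param exv_sigma excluded-volume diameter, Angstrom
#' @param exv_eps excluded-volume strength, kcal/mol
#' @param contact_cutoff native-contact cutoff for intra-protein pairs, Angstrom
#' @param interface_cutoff cutoff defining residues with a native base
#'   contact (enters the r_i0 table), Angstrom
#' @param friction Langevin friction per bead, 1/time
#' @param dt integration step; `NULL` picks 1% of the stiffest bond period
#' @param anchor_spring default anchor restraint constant, kcal mol^-1 A^-2
#' @param k_bond,k_angle,k_dihedral harmonic constants (U = k * dev^2),
#'   kcal/mol per A^2 / rad^2 / rad^2
#' @param contact_eps intra-protein native-contact depth, kcal/mol
#' @param stack_eps nearest-neighbour base-stacking depth, kcal/mol
#' @param wall_radius,wall_k soft spherical confinement (half-harmonic
#'   outside the radius), Angstrom and kcal mol^-1 A^-2; `wall_k = 0` disables
#' @param mass bead mass (all beads identical)
#' @param elec_cutoff_factor electrostatic cutoff in units of the Debye
#'   length (energy shifted to zero there)
#' @param seed default RNG seed for dynamics
#' @return a `sim_params` list
#' @export
sim_params <- function(epsilon_interface = 0.2325,
                       salt_molar = 0.15,
                       relative_permittivity = 78,
                       temperature = 300,
                       exv_sigma = 3.5,
                       exv_eps = 0.2,
                       contact_cutoff = 6.5,
                       interface_cutoff = 10,
                       friction = 0.5,
                       dt = NULL,
                       anchor_spring = 0.3,
                       k_bond = 100,
                       k_angle = 20,
                       k_dihedral = 1,
                       contact_eps = 0.3,
                       stack_eps = 0.5,
                       wall_radius = 85,
                       wall_k = 1,
                       mass = 1,
                       elec_cutoff_factor = 5,
                       seed = 1L) {
  p <- as.list(environment())
  num <- p[!vapply(p, is.null, logical(1))]
  stopifnot(all(vapply(num, function(v) is.numeric(v) && all(v >= 0), logical(1))),
            epsilon_interface > 0, temperature > 0, mass > 0, k_bond > 0)
  if (is.null(p$dt)) {
    # stiffest harmonic term: bond U = k (r - r0)^2, curvature 2k, reduced
    # mass m/2 for a bead pair -> omega = sqrt(4 k / m)
    omega <- sqrt(4 * k_bond / mass)
    p$dt <- 0.01 * 2 * pi / omega
  }
  structure(p, class = "sim_params")
}

.new_topology <- function(xyz, kind, molecule, chain, subunit, resno, resid,
                          charge, bonds, angles, dihedrals, contacts) {
  structure(list(
    xyz = xyz, kind = kind, molecule = molecule, chain = chain,
    subunit = subunit, resno = resno, resid = resid, charge = charge,
    bonds = bonds, angles = angles, dihedrals = dihedrals,
    contacts = contacts,
    interface = data.frame(i = integer(0), r0 = numeric(0)),
    anchors = data.frame(i = integer(0), x = numeric(0), y = numeric(0),
                         z = numeric(0), k = numeric(0))
  ), class = "bead_topology")
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf(
    "Bead topology: %d beads (%s), %d bonds, %d angles, %d dihedrals, %d contacts, %d interface residues, %d anchors\n",
    nrow(x$xyz), paste(names(table(x$kind)), collapse = "/"),
    nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals), nrow(x$contacts),
    nrow(x$interface), nrow(x$anchors)
  ))
  invisible(x)
}

# default residue charges: basic +1, acidic -1, His neutral
.residue_charge <- function(resid) {
  up <- toupper(resid)
  ifelse(up %in% c("LYS", "ARG"), 1,
         ifelse(up %in% c("ASP", "GLU"), -1, 0))
}

#' Build a C-alpha protein topology from a structure
#'
#' Consecutive residues are bonded; angles and dihedrals are harmonic about
#' their native values; residue pairs closer than `contact_cutoff` with
#' sequence separation >= 4 (or on different chains) become native 12-10
#' contacts at their native distance. Deterministic.
#'
#' @param structure a PDB file path, a `bio3d` pdb object, or a data frame
#'   with columns `chain`, `resno`, `resid`, `x`, `y`, `z` (one C-alpha row
#'   per residue)
#' @param params a [sim_params()]
#' @return a `bead_topology`
#' @export
build_protein_topology <- function(structure, params = sim_params()) {
  df <- .as_ca_table(structure)
  n <- nrow(df)
  xyz <- as.matrix(df[, c("x", "y", "z")])
  dimnames(xyz) <- NULL
  chains <- unique(df$chain)
  chain_id <- match(df$chain, chains)

  bonds <- list(); angles <- list(); dihedrals <- list()
  for (cid in seq_along(chains)) {
    idx <- which(chain_id == cid)
    idx <- idx[order(df$resno[idx])]
    if (length(idx) < 2L) next
    consec <- diff(df$resno[idx]) == 1L
    d <- sqrt(rowSums((xyz[idx[-1], , drop = FALSE] -
                         xyz[idx[-length(idx)], , drop = FALSE])^2))
    ok <- consec & d < 4.5
    if (any(consec & !ok)) {
      warning("chain break: ", sum(consec & !ok), " bond(s) skipped in chain ",
              chains[cid])
    }
    bi <- idx[-length(idx)][ok]; bj <- idx[-1][ok]
    bonds[[cid]] <- data.frame(i = bi, j = bj, r0 = d[ok], k = params$k_bond)
    # angles/dihedrals only where every internal bond is present;
    # bonded[t] flags the bond between idx[t] and idx[t+1]
    bonded <- ok
    tri <- which(bonded[-length(bonded)] & bonded[-1])
    if (length(tri)) {
      a_i <- idx[tri]; a_j <- idx[tri + 1L]; a_k <- idx[tri + 2L]
      angles[[cid]] <- data.frame(
        i = a_i, j = a_j, k = a_k,
        theta0 = .vangle(xyz, a_i, a_j, a_k), kth = params$k_angle
      )
    }
    qu <- which(bonded[seq_len(max(0L, length(bonded) - 2L))] &
                  bonded[1L + seq_len(max(0L, length(bonded) - 2L))] &
                  bonded[2L + seq_len(max(0L, length(bonded) - 2L))])
    if (length(qu)) {
      d_i <- idx[qu]; d_j <- idx[qu + 1L]; d_k <- idx[qu + 2L]; d_l <- idx[qu + 3L]
      dihedrals[[cid]] <- data.frame(
        i = d_i, j = d_j, k = d_k, l = d_l,
        phi0 = .vdihedral(xyz, d_i, d_j, d_k, d_l), kphi = params$k_dihedral
      )
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(0), j = integer(0), r0 = numeric(0), k = numeric(0))
  angles <- if (length(angles)) do.call(rbind, angles) else
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               theta0 = numeric(0), kth = numeric(0))
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else
    data.frame(i = integer(0), j = integer(0), k = integer(0), l = integer(0),
               phi0 = numeric(0), kphi = numeric(0))

  # native contacts: all pairs within cutoff, seq sep >= 4 or inter-chain
  contacts <- .native_contacts(xyz, chain_id, df$resno,
                               params$contact_cutoff, params$contact_eps)

  .new_topology(
    xyz = xyz, kind = rep("CA", n), molecule = rep(1L, n),
    chain = chain_id, subunit = chain_id, resno = df$resno,
    resid = df$resid, charge = .residue_charge(df$resid),
    bonds = bonds, angles = angles, dihedrals = dihedrals, contacts = contacts
  )
}

.as_ca_table <- function(structure) {
  if (is.character(structure) && length(structure) == 1L) {
    structure <- bio3d::read.pdb(structure)
  }
  if (inherits(structure, "pdb")) {
    sel <- bio3d::atom.select(structure, elety = "CA", verbose = FALSE)
    at <- structure$atom[sel$atom, ]
    if (nrow(at) == 0L) stop("structure has no C-alpha atoms")
    return(data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      x = at$x, y = at$y, z = at$z))
  }
  stopifnot(is.data.frame(structure),
            all(c("chain", "resno", "resid", "x", "y", "z") %in% names(structure)))
  # every residue must have exactly one CA row
  if (anyNA(structure[, c("x", "y", "z")])) {
    stop("missing C-alpha coordinates for residue(s) ",
         paste(structure$resno[!stats::complete.cases(structure[, c("x", "y", "z")])],
               collapse = ", "))
  }
  structure
}

.native_contacts <- function(xyz, chain_id, resno, cutoff, eps) {
  n <- nrow(xyz)
  if (n < 2L) {
    return(data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                      eps = numeric(0)))
  }
  dmat <- as.matrix(stats::dist(xyz))
  sep_ok <- outer(chain_id, chain_id, "!=") |
    (abs(outer(resno, resno, "-")) >= 4L)
  pick <- upper.tri(dmat) & dmat <= cutoff & sep_ok
  idx <- which(pick, arr.ind = TRUE)
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
             r0 = dmat[pick], eps = rep(eps, nrow(idx)))
}

.vangle <- function(xyz, i, j, k) {
  u <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  v <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  cosv <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(1, pmax(-1, cosv)))
}

.vdihedral <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  b2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  b3 <- xyz[l, , drop = FALSE] - xyz[k, , drop = FALSE]
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  b2h <- b2 / sqrt(rowSums(b2^2))
  atan2(rowSums(.vcross(n1, n2) * b2h), rowSums(n1 * n2))
}

.vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Build a three-bead-per-nucleotide ssDNA topology
#'
#' Each nucleotide contributes phosphate (P), sugar (S) and base (B) beads;
#' the 5' terminal nucleotide lacks its leading phosphate (3N - 1 beads for
#' N nucleotides). Backbone bonds are S-P(next) and P-S; S-B holds the base.
#' Angles cover the backbone and base orientation; nearest-neighbour bases
#' get a 12-10 stacking term at the reference distance. Phosphates carry
#' -0.6 e.
#'
#' @param sequence nucleotide string over A/C/G/T (e.g. `strrep("T", 19)`)
#' @param coords optional reference coordinates, a list with matrices `S`
#'   (N x 3), `B` (N x 3) and `P` ((N-1) x 3, for nucleotides 2..N); when
#'   `NULL` an extended reference geometry is generated
#' @param params a [sim_params()]
#' @param phosphate_charge charge per phosphate bead, e
#' @return a `bead_topology`
#' @export
build_ssdna_topology <- function(sequence, coords = NULL,
                                 params = sim_params(),
                                 phosphate_charge = -0.6) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  nts <- strsplit(toupper(sequence), "")[[1]]
  if (!all(nts %in% c("A", "C", "G", "T"))) {
    stop("invalid nucleotide(s): ",
         paste(unique(nts[!nts %in% c("A", "C", "G", "T")]), collapse = ", "))
  }
  n <- length(nts)
  if (is.null(coords)) {
    s <- cbind(6.3 * (seq_len(n) - 1), 0, 0)
    b <- s + matrix(rep(c(0, 4.3, 0), each = n), n)
    p <- if (n > 1) {
      (s[-n, , drop = FALSE] + s[-1, , drop = FALSE]) / 2 +
        matrix(rep(c(0, -2, 0), each = n - 1), n - 1)
    } else matrix(numeric(0), 0, 3)
    coords <- list(S = s, B = b, P = p)
  }
  stopifnot(nrow(coords$S) == n, nrow(coords$B) == n,
            nrow(coords$P) == max(0L, n - 1L))

  # bead order per nucleotide: [P] S B (P absent for the 5' nucleotide)
  idxS <- idxB <- integer(n); idxP <- rep(NA_integer_, n)
  rows <- list(); kind <- character(0); nt_of <- integer(0)
  cur <- 0L
  for (i in seq_len(n)) {
    if (i > 1L) {
      cur <- cur + 1L; idxP[i] <- cur
      rows[[cur]] <- coords$P[i - 1L, ]; kind[cur] <- "P"; nt_of[cur] <- i
    }
    cur <- cur + 1L; idxS[i] <- cur
    rows[[cur]] <- coords$S[i, ]; kind[cur] <- "S"; nt_of[cur] <- i
    cur <- cur + 1L; idxB[i] <- cur
    rows[[cur]] <- coords$B[i, ]; kind[cur] <- "B"; nt_of[cur] <- i
  }
  xyz <- do.call(rbind, rows)
  dimnames(xyz) <- NULL
  nb <- nrow(xyz)

  dist2 <- function(a, b) sqrt(sum((xyz[a, ] - xyz[b, ])^2))
  bond <- function(i, j) data.frame(i = i, j = j, r0 = dist2(i, j),
                                    k = params$k_bond)
  bonds <- list()
  for (i in seq_len(n)) {
    bonds[[length(bonds) + 1L]] <- bond(idxS[i], idxB[i])
    if (i < n) {
      bonds[[length(bonds) + 1L]] <- bond(idxS[i], idxP[i + 1L])
      bonds[[length(bonds) + 1L]] <- bond(idxP[i + 1L], idxS[i + 1L])
    }
  }
  bonds <- do.call(rbind, bonds)

  ang <- function(i, j, k) data.frame(
    i = i, j = j, k = k, theta0 = .vangle(xyz, i, j, k), kth = params$k_angle)
  angles <- list()
  for (i in seq_len(n)) {
    if (i < n) {
      angles[[length(angles) + 1L]] <- ang(idxS[i], idxP[i + 1L], idxS[i + 1L])
      angles[[length(angles) + 1L]] <- ang(idxB[i], idxS[i], idxP[i + 1L])
    }
    if (i > 1L && i < n) {
      angles[[length(angles) + 1L]] <- ang(idxP[i], idxS[i], idxP[i + 1L])
    }
    if (i > 1L) {
      angles[[length(angles) + 1L]] <- ang(idxP[i], idxS[i], idxB[i])
    }
  }
  angles <- do.call(rbind, angles)

  contacts <- if (n > 1L) {
    data.frame(i = idxB[-n], j = idxB[-1],
               r0 = sqrt(rowSums((xyz[idxB[-n], , drop = FALSE] -
                                    xyz[idxB[-1], , drop = FALSE])^2)),
               eps = params$stack_eps)
  } else {
    data.frame(i = integer(0), j = integer(0), r0 = numeric(0), eps = numeric(0))
  }

  charge <- numeric(nb)
  charge[stats::na.omit(idxP)] <- phosphate_charge

  topo <- .new_topology(
    xyz = xyz, kind = kind, molecule = rep(2L, nb),
    chain = rep(1L, nb), subunit = rep(0L, nb), resno = nt_of,
    resid = nts[nt_of], charge = charge,
    bonds = bonds,
    angles = if (is.null(angles)) data.frame(i = integer(0), j = integer(0),
                                             k = integer(0), theta0 = numeric(0),
                                             kth = numeric(0)) else angles,
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), phi0 = numeric(0), kphi = numeric(0)),
    contacts = contacts
  )
  topo$nt_index <- list(P = idxP, S = idxS, B = idxB)
  topo
}

#' Replace protein bead charges by a per-state charge overlay
#'
#' Overlays emulate the salt-induced redistribution of surface charge: the
#' same residues carry different partial charges in the "unbridged"
#' (low-salt) and "bridged" (high-salt) surface states. DNA charges are
#' untouched.
#'
#' @param topology a combined or protein `bead_topology`
#' @param state `"unbridged"` or `"bridged"`
#' @param overlay data frame with columns `subunit`, `residue_index`,
#'   `state`, `charge_e`, covering every charged protein residue for both
#'   states
#' @return the topology with protein charges replaced
#' @export
assign_charge_state <- function(topology, state = c("unbridged", "bridged"),
                                overlay) {
  state <- match.arg(state)
  stopifnot(inherits(topology, "bead_topology"), is.data.frame(overlay),
            all(c("subunit", "residue_index", "state", "charge_e") %in%
                  names(overlay)))
  ov <- overlay[overlay$state == state, ]
  if (nrow(ov) == 0L) stop("overlay has no rows for state ", state)
  prot <- which(topology$molecule == 1L)
  key_topo <- paste(topology$subunit[prot], topology$resno[prot])
  key_ov <- paste(ov$subunit, ov$residue_index)
  hit <- match(key_topo, key_ov)
  charged_missing <- topology$charge[prot] != 0 & is.na(hit)
  if (any(charged_missing)) {
    stop("overlay (state ", state, ") misses charged residue(s): ",
         paste(utils::head(key_topo[charged_missing], 5), collapse = "; "))
  }
  newq <- topology$charge
  newq[prot[!is.na(hit)]] <- ov$charge_e[hit[!is.na(hit)]]
  topology$charge <- newq
  topology$charge_state <- state
  topology
}

#' Interface reference distances r_i0
#'
#' For every protein residue within `cutoff` of any base bead in the
#' reference complex, the reference distance is the minimum residue-base
#' distance; residues farther than the cutoff from all bases are excluded
#' from the interface term.
#'
#' @param protein_xyz protein C-alpha coordinates (n x 3)
#' @param base_xyz base-bead coordinates in the reference complex (m x 3)
#' @param cutoff interface cutoff, Angstrom
#' @return data frame `i` (protein bead row), `r0` (Angstrom); empty with a
#'   warning when no residue is within the cutoff
#' @export
interface_reference_distances <- function(protein_xyz, base_xyz, cutoff = 10) {
  stopifnot(is.matrix(protein_xyz), is.matrix(base_xyz),
            ncol(protein_xyz) == 3L, ncol(base_xyz) == 3L, cutoff > 0)
  if (nrow(base_xyz) == 0L) stop("reference complex lacks base beads")
  d2 <- outer(rowSums(protein_xyz^2), rep(1, nrow(base_xyz))) +
    outer(rep(1, nrow(protein_xyz)), rowSums(base_xyz^2)) -
    2 * protein_xyz %*% t(base_xyz)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  keep <- which(dmin <= cutoff)
  if (length(keep) == 0L) {
    warning("no protein residue within ", cutoff, " A of any base")
  }
  data.frame(i = keep, r0 = dmin[keep])
}

#' Residue-base 12-10 interface energy
#'
#' Structure-based interface term: for each tabulated residue `i` and every
#' base `j`, `eps * (5 (r_i0 / r_ij)^12 - 6 (r_i0 / r_ij)^10)`. The minimum
#' for an isolated pair is exactly `-eps` at `r_ij = r_i0`.
#'
#' @param protein_xyz protein coordinates (n x 3, full table; rows indexed
#'   by `interface$i`)
#' @param base_xyz base-bead coordinates (m x 3)
#' @param interface data frame from [interface_reference_distances()]
#' @param epsilon coupling strength, kcal/mol
#' @return energy in kcal/mol
#' @export
interface_contact_energy <- function(protein_xyz, base_xyz, interface,
                                     epsilon = 0.2325) {
  stopifnot(nrow(interface) >= 1L)
  pi_xyz <- protein_xyz[interface$i, , drop = FALSE]
  d2 <- outer(rowSums(pi_xyz^2), rep(1, nrow(base_xyz))) +
    outer(rep(1, nrow(pi_xyz)), rowSums(base_xyz^2)) -
    2 * pi_xyz %*% t(base_xyz)
  if (any(d2 < 1e-12)) stop("singular residue-base pair: r_ij = 0")
  ratio2 <- (interface$r0^2) / d2  # rows recycle r_i0 over bases
  r10 <- ratio2^5
  r12 <- ratio2^6
  epsilon * sum(5 * r12 - 6 * r10)
}

#' Debye screening length of a 1:1 salt
#'
#' lambda_D = sqrt(eps0 eps_r kB T / (2 N_A e^2 I)), ionic strength I equal
#' to the molar salt concentration for a monovalent salt.
#'
#' @param salt_molar salt concentration, M (> 0)
#' @param temperature Kelvin
#' @param relative_permittivity dielectric constant
#' @return Debye length in nm
#' @export
debye_length <- function(salt_molar, temperature = 300,
                         relative_permittivity = 78) {
  stopifnot(is.numeric(salt_molar))
  if (any(salt_molar <= 0)) stop("salt_molar must be > 0")
  eps0 <- 8.8541878128e-12   # F/m
  e <- 1.602176634e-19       # C
  na <- 6.02214076e23        # 1/mol
  kb <- 1.380649e-23         # J/K
  i_m3 <- salt_molar * 1000 * na  # ions per m^3 per species
  sqrt(eps0 * relative_permittivity * kb * temperature / (2 * e^2 * i_m3)) * 1e9
}

#' Screened electrostatic energy between two charged bead sets
#'
#' Debye-Hueckel pair energy `C q_i q_j exp(-r/lambda) / (eps_r r)` summed
#' over inter-set pairs, truncated at `cutoff_factor * lambda` with the pair
#' energy shifted to zero at the cutoff.
#'
#' @param xyz_a,q_a coordinates (n x 3, Angstrom) and charges (e) of set A
#' @param xyz_b,q_b coordinates and charges of set B
#' @param lambda_nm Debye length in nm
#' @param relative_permittivity dielectric constant
#' @param cutoff_factor cutoff in Debye lengths
#' @return energy in kcal/mol
#' @export
electrostatic_energy <- function(xyz_a, q_a, xyz_b, q_b, lambda_nm,
                                 relative_permittivity = 78,
                                 cutoff_factor = 5) {
  stopifnot(lambda_nm > 0, nrow(xyz_a) == length(q_a), nrow(xyz_b) == length(q_b))
  lam <- lambda_nm * 10  # Angstrom
  rc <- cutoff_factor * lam
  d2 <- outer(rowSums(xyz_a^2), rep(1, nrow(xyz_b))) +
    outer(rep(1, nrow(xyz_a)), rowSums(xyz_b^2)) - 2 * xyz_a %*% t(xyz_b)
  qq <- outer(q_a, q_b)
  act <- qq != 0
  if (!any(act)) return(0)
  r <- sqrt(d2[act])
  if (any(r < 1e-12)) stop("singular charged pair: r = 0")
  qq <- qq[act]
  inside <- r < rc
  shift <- exp(-cutoff_factor) / rc
  sum(.COULOMB_KCAL_A * qq[inside] / relative_permittivity *
        (exp(-r[inside] / lam) / r[inside] - shift))
}
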