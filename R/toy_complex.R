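# Synthetic reference complex: a compact D2-symmetric four-subunit toy
# protein with a charged surface groove per subunit, plus a poly-dT ssDNA
# path threaded through the grooves of all four subunits as the native
# (wrapped) reference. The toy stands in for a crystal-structure complex so
# the interface table, charge overlays and wrapping analyses are testable
# offline; it makes no claim about real SSB architecture.

# self-avoiding collapsed chain on a cubic lattice (spacing = bond length)
.saw_subunit <- function(n_res, bond = 3.8, rmax = 11, bias_sd = 7,
                         max_restart = 500) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (attempt in seq_len(max_restart)) {
    pos <- matrix(0, n_res, 3)
    seen <- new.env(hash = TRUE)
    assign("0 0 0", TRUE, envir = seen)
    dead <- FALSE
    prev_dir <- c(0, 0, 0)
    for (i in 2:n_res) {
      cand <- sweep(dirs, 2, pos[i - 1L, ] / bond, "+")
      keys <- apply(cand, 1, paste, collapse = " ")
      # no straight steps: collinear triples would make the native angle
      # gradient singular
      straight <- rowSums(abs(sweep(dirs, 2, prev_dir, "-"))) < 1e-9
      free <- !vapply(keys, exists, logical(1), envir = seen) &
        sqrt(rowSums((cand * bond)^2)) <= rmax & !straight
      if (!any(free)) {
        dead <- TRUE
        break
      }
      w <- exp(-rowSums((cand * bond)^2) / (2 * bias_sd^2))[free]
      pick <- which(free)[sample.int(sum(free), 1L, prob = w)]
      prev_dir <- dirs[pick, ]
      pos[i, ] <- cand[pick, ] * bond
      assign(keys[pick], TRUE, envir = seen)
    }
    if (!dead) return(sweep(pos, 2, colMeans(pos)))
  }
  stop("self-avoiding walk failed after ", max_restart, " restarts")
}

.d2_rotations <- function() {
  list(diag(3),
       diag(c(-1, -1, 1)),
       diag(c(-1, 1, -1)),
       diag(c(1, -1, -1)))
}

#' Generate the toy tetramer complex with a wrapped ssDNA reference
#'
#' One compact subunit is generated as a seeded self-avoiding collapsed
#' lattice chain and replicated by 222 (D2) symmetry into a tetramer. A
#' poly-dT path is laid through the surface grooves of all four subunits as
#' the native complex reference, and two per-residue charge overlays are
#' built: "unbridged" (groove charges dispersed, alternating sign) and
#' "bridged" (groove charges concentrated and more positive).
#'
#' @param n_res_per_subunit residues per subunit (>= 30)
#' @param seed RNG seed; assembly retries internally derived seeds on steric
#'   clashes (error after 10 attempts)
#' @param n_nt ssDNA length in nucleotides (poly-dT)
#' @param centroid_shift distance of each subunit centroid from the origin
#'   along the (1,1,1)-type directions, per axis, Angstrom
#' @return a `toy_complex` list: `protein` (data frame chain/resno/resid/
#'   x/y/z), `dna` (list of S/B/P coordinate matrices), `sequence`,
#'   `overlays` (charge overlay data frame), `groove_residues`,
#'   `anchor_subunit`, `seed`
#' @export
make_toy_tetramer <- function(n_res_per_subunit = 40, seed = 1L, n_nt = 19,
                              centroid_shift = 9) {
  stopifnot(n_res_per_subunit >= 30, n_nt >= 4)
  for (try_i in 0:9) {
    out <- withr::with_seed(seed + 1000L * try_i, {
      .build_toy(n_res_per_subunit, n_nt, centroid_shift)
    })
    if (!is.null(out)) {
      out$seed <- seed
      out$attempt <- try_i
      return(out)
    }
  }
  stop("toy tetramer assembly kept clashing after 10 attempts")
}

.build_toy <- function(n_res, n_nt, c0) {
  sub <- .saw_subunit(n_res)
  rots <- .d2_rotations()
  center <- c(c0, c0, c0)
  subs <- lapply(rots, function(R) sweep(sub, 2, center, "+") %*% t(R))
  prot <- do.call(rbind, subs)
  nprot <- nrow(prot)
  subunit <- rep(seq_len(4L), each = n_res)

  # steric check between subunits
  dmin <- min(stats::dist(prot[!duplicated(round(prot, 6)), , drop = FALSE]))
  mind_inter <- Inf
  for (a in 1:3) for (b in (a + 1):4) {
    da <- subs[[a]]; db <- subs[[b]]
    d2 <- outer(rowSums(da^2), rep(1, nrow(db))) +
      outer(rep(1, nrow(da)), rowSums(db^2)) - 2 * da %*% t(db)
    mind_inter <- min(mind_inter, sqrt(max(min(d2), 0)))
  }
  if (mind_inter < 3.5) return(NULL)

  # DNA path: spline through outward-shifted waypoints at each subunit, in
  # the D2 image order 1 -> 2 -> 3 -> 4
  cents <- lapply(subs, colMeans)
  rsub <- max(sqrt(rowSums(sub^2)))
  waypts <- list()
  order4 <- c(1L, 2L, 3L, 4L)
  for (qi in seq_along(order4)) {
    s <- order4[qi]
    cn <- cents[[s]]
    w <- cn * (sqrt(sum(cn^2)) + rsub + 5) / sqrt(sum(cn^2))
    waypts[[length(waypts) + 1L]] <- w
    if (qi < length(order4)) {
      s2 <- order4[qi + 1L]
      mid <- (cn + cents[[s2]]) / 2
      nm <- sqrt(sum(mid^2))
      # keep the connecting leg at wrapping radius
      mid <- if (nm > 1e-6) mid * (sqrt(sum(cn^2)) + rsub + 6) / nm else
        c(0, 0, sqrt(sum(cn^2)) + rsub + 6)
      waypts[[length(waypts) + 1L]] <- mid
    }
  }
  wp <- do.call(rbind, waypts)
  tt <- c(0, cumsum(sqrt(rowSums(diff(wp)^2))))
  dense_t <- seq(0, max(tt), length.out = 600)
  path <- cbind(
    stats::spline(tt, wp[, 1], xout = dense_t)$y,
    stats::spline(tt, wp[, 2], xout = dense_t)$y,
    stats::spline(tt, wp[, 3], xout = dense_t)$y
  )
  # arc-length resample: spread the n_nt sugars over the whole span from the
  # first to the last subunit waypoint, so the reference wraps all four
  # subunits (the toy backbone rise is whatever this spacing implies)
  seglen <- sqrt(rowSums(diff(path)^2))
  arc <- c(0, cumsum(seglen))
  wp_arc <- stats::approx(dense_t, arc, xout = tt)$y
  s_arc <- seq(wp_arc[1], wp_arc[length(wp_arc)], length.out = n_nt)
  S <- cbind(
    stats::approx(arc, path[, 1], xout = s_arc)$y,
    stats::approx(arc, path[, 2], xout = s_arc)$y,
    stats::approx(arc, path[, 3], xout = s_arc)$y
  )

  nearest <- function(p) {
    d2 <- rowSums(sweep(prot, 2, p)^2)
    j <- which.min(d2)
    list(j = j, d = sqrt(d2[j]))
  }
  # smooth inward direction field: toward the nearest subunit centroid
  inward <- function(p) {
    dc <- vapply(cents, function(cn) sum((p - cn)^2), numeric(1))
    u <- cents[[which.min(dc)]] - p
    u / sqrt(sum(u^2))
  }
  # push each sugar to ~9 A from the nearest protein bead (two passes),
  # then re-space the sugars uniformly along the adjusted polyline (the
  # projection can locally bunch them up)
  for (pass in 1:2) {
    for (i in seq_len(n_nt)) {
      nb <- nearest(S[i, ])
      u <- (S[i, ] - prot[nb$j, ]) / nb$d
      S[i, ] <- prot[nb$j, ] + u * 9
    }
  }
  arc2 <- c(0, cumsum(sqrt(rowSums(diff(S)^2))))
  even <- seq(0, max(arc2), length.out = n_nt)
  S <- cbind(
    stats::approx(arc2, S[, 1], xout = even)$y,
    stats::approx(arc2, S[, 2], xout = even)$y,
    stats::approx(arc2, S[, 3], xout = even)$y
  )
  # bases point inward, phosphates outward; a base that would clash with the
  # protein is rotated about its sugar (bond length preserved) until it has
  # at least 3.8 A clearance
  B <- t(vapply(seq_len(n_nt), function(i) {
    u <- inward(S[i, ])
    b <- S[i, ] + 4.3 * u
    for (it in 1:6) {
      nb <- nearest(b)
      if (nb$d >= 3.8) break
      away <- (b - prot[nb$j, ]) / max(nb$d, 1e-6)
      u <- u + 0.6 * away
      u <- u / sqrt(sum(u^2))
      b <- S[i, ] + 4.3 * u
    }
    b
  }, numeric(3)))
  P <- if (n_nt > 1) {
    t(vapply(2:n_nt, function(i) {
      mid <- (S[i - 1L, ] + S[i, ]) / 2
      p <- mid - 3 * inward(mid)
      if (nearest(p)$d < 3.8) p <- mid - 4.5 * inward(mid)
      p
    }, numeric(3)))
  } else matrix(numeric(0), 0, 3)

  dna_all <- rbind(S, B, P)
  d2 <- outer(rowSums(dna_all^2), rep(1, nprot)) +
    outer(rep(1, nrow(dna_all)), rowSums(prot^2)) - 2 * dna_all %*% t(prot)
  if (sqrt(max(min(d2), 0)) < 3.5) return(NULL)
  # no internal DNA clashes beyond bonded neighbours either
  if (min(stats::dist(dna_all)) < 3.5) return(NULL)

  # groove = 8 residues per subunit nearest to any base; rim = next 4
  d2b <- outer(rowSums(prot^2), rep(1, n_nt)) +
    outer(rep(1, nprot), rowSums(B^2)) - 2 * prot %*% t(B)
  dminb <- sqrt(pmax(apply(d2b, 1, min), 0))
  groove <- integer(0); rim <- integer(0)
  for (s in 1:4) {
    ranks <- order(dminb[subunit == s])
    res_local <- ranks[1:8]
    rim_local <- ranks[9:12]
    groove <- c(groove, res_local + (s - 1L) * n_res)
    rim <- c(rim, rim_local + (s - 1L) * n_res)
  }

  resid <- rep("GLY", nprot)
  resid[groove] <- "ARG"
  resid[rim] <- "ASP"
  protein <- data.frame(
    chain = LETTERS[subunit], resno = rep(seq_len(n_res), 4L),
    resid = resid, x = prot[, 1], y = prot[, 2], z = prot[, 3]
  )

  # overlays: in the unbridged (low-salt) state the groove charge is
  # dispersed (alternating weak +/-, zero net) and the rim is acidic, so the
  # groove potential is net repulsive for DNA; in the bridged (high-salt)
  # state cation bridging concentrates positive charge in the groove and
  # neutralises the rim
  local_res <- ((groove - 1L) %% n_res) + 1L
  local_rim <- ((rim - 1L) %% n_res) + 1L
  sub_of <- function(gidx) (gidx - 1L) %/% n_res + 1L
  alt <- rep(c(0.2, -0.2), length.out = 8L)
  overlays <- rbind(
    data.frame(subunit = sub_of(groove), residue_index = local_res,
               state = "unbridged",
               charge_e = rep(alt, times = 4L)),
    data.frame(subunit = sub_of(rim), residue_index = local_rim,
               state = "unbridged", charge_e = -1.0),
    data.frame(subunit = sub_of(groove), residue_index = local_res,
               state = "bridged", charge_e = 1.2),
    data.frame(subunit = sub_of(rim), residue_index = local_rim,
               state = "bridged", charge_e = 0.0)
  )

  # the 3' terminus (last nucleotide) sits at the last visited subunit
  nb_end <- nearest(B[n_nt, ])
  structure(list(
    protein = protein,
    dna = list(S = S, B = B, P = P),
    sequence = strrep("T", n_nt),
    overlays = overlays,
    groove_residues = data.frame(subunit = sub_of(groove), residue_index = local_res),
    anchor_subunit = subunit[nb_end$j],
    subunit_centroids = do.call(rbind, cents)
  ), class = "toy_complex")
}

#' Build the full simulation topology for a toy complex
#'
#' Protein and ssDNA topologies are built from the complex reference
#' coordinates, merged (which fixes the interface r_i0 table), the requested
#' charge-state overlay is applied, the two 3'-terminal base beads are
#' anchored at their reference positions, a few groove residues of the
#' anchored subunit are weakly restrained to keep the complex registered
#' with the spatial DNA anchors, and the equivalent-length spring extends
#' the tether by one nucleotide.
#'
#' @param complex a [make_toy_tetramer()] result
#' @param state `"unbridged"` or `"bridged"`
#' @param params a [sim_params()]
#' @param anchor logical: add the terminal-base anchors and protein
#'   registration restraints
#' @param length_spring logical: add the equivalent-length spring
#' @return a combined, charged, anchored `bead_topology`
#' @export
build_complex_topology <- function(complex, state = c("unbridged", "bridged"),
                                   params = sim_params(), anchor = TRUE,
                                   length_spring = TRUE) {
  state <- match.arg(state)
  stopifnot(inherits(complex, "toy_complex"))
  prot <- build_protein_topology(complex$protein, params)
  dna <- build_ssdna_topology(complex$sequence, coords = complex$dna, params = params)
  topo <- merge_topologies(prot, dna, params)
  topo <- assign_charge_state(topo, state, complex$overlays)
  if (anchor) {
    nb <- length(topo$nt_index$B)
    term_b <- topo$nt_index$B[c(nb - 1L, nb)]
    topo <- apply_anchor(topo, bead_idx = term_b, k = params$anchor_spring)
    reg <- which(topo$molecule == 1L & topo$subunit == complex$anchor_subunit &
                   topo$resid == "ARG")[1:4]
    topo <- apply_anchor(topo, bead_idx = reg, k = params$anchor_spring)
  }
  if (length_spring) topo <- equivalent_length_spring(topo)
  topo
}

#' Write a toy complex as a PDB file
#'
#' Protein C-alpha beads go to chains A-D; DNA beads to chain E with atom
#' names P/S/B on DT residues.
#'
#' @param complex a [make_toy_tetramer()] result
#' @param path output PDB path
#' @return `path`, invisibly
#' @export
write_complex_pdb <- function(complex, path) {
  stopifnot(inherits(complex, "toy_complex"))
  p <- complex$protein
  n_nt <- nrow(complex$dna$S)
  dna_rows <- list()
  for (i in seq_len(n_nt)) {
    if (i > 1L) {
      dna_rows[[length(dna_rows) + 1L]] <-
        c("P", i, complex$dna$P[i - 1L, ])
    }
    dna_rows[[length(dna_rows) + 1L]] <- c("S", i, complex$dna$S[i, ])
    dna_rows[[length(dna_rows) + 1L]] <- c("B", i, complex$dna$B[i, ])
  }
  dm <- do.call(rbind, dna_rows)
  xyz <- rbind(as.matrix(p[, c("x", "y", "z")]),
               matrix(as.numeric(dm[, 3:5]), ncol = 3))
  natom <- nrow(xyz)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", natom),
    resno = c(p$resno, as.integer(dm[, 2])),
    resid = c(p$resid, rep("DT", nrow(dm))),
    chain = c(p$chain, rep("E", nrow(dm))),
    elety = c(rep("CA", nrow(p)), dm[, 1]),
    eleno = seq_len(natom)
  )
  invisible(path)
}

#' Read a toy complex back from a PDB file written by [write_complex_pdb()]
#'
#' @param path PDB path
#' @return a `toy_complex` (without overlays, which travel as CSV)
#' @export
read_complex_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  isp <- at$chain %in% LETTERS[1:4]
  protein <- data.frame(chain = at$chain[isp], resno = at$resno[isp],
                        resid = at$resid[isp], x = at$x[isp], y = at$y[isp],
                        z = at$z[isp])
  dn <- at[!isp, ]
  get <- function(el) {
    r <- dn[dn$elety == el, ]
    r <- r[order(r$resno), ]
    as.matrix(r[, c("x", "y", "z")])
  }
  S <- get("S"); B <- get("B"); P <- get("P")
  dimnames(S) <- dimnames(B) <- dimnames(P) <- NULL
  n_nt <- nrow(S)
  # identify anchor subunit as the one nearest to the 3' terminal base
  prot_xyz <- as.matrix(protein[, c("x", "y", "z")])
  d2 <- rowSums(sweep(prot_xyz, 2, B[n_nt, ])^2)
  structure(list(
    protein = protein, dna = list(S = S, B = B, P = P),
    sequence = strrep("T", n_nt), overlays = NULL,
    anchor_subunit = match(protein$chain[which.min(d2)], LETTERS),
    subunit_centroids = NULL
  ), class = "toy_complex")
}
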