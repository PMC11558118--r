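# Wrapping-mode analysis of CG trajectories: a protein-fixed local frame,
# X-Y projection of DNA beads, 2D potentials of mean force, and per-frame
# subunit occupancy.

#' Protein-fixed local coordinate frame
#'
#' Origin at the protein centre of geometry; axes are the principal axes of
#' the coordinate spread, ordered by decreasing spread, with signs fixed
#' deterministically: the first axis points toward `toward` (by default the
#' first bead), the second axis toward a second reference bead, and the
#' third completes a right-handed system (det = +1).
#'
#' @param protein_xyz n x 3 protein coordinates (>= 3 non-collinear beads)
#' @param toward length-3 point fixing the sign of the first axis (e.g. the
#'   anchored subunit centroid)
#' @return list with `origin` (length 3) and `rotation` (3 x 3, columns =
#'   axes)
#' @export
local_frame <- function(protein_xyz, toward = NULL) {
  stopifnot(is.matrix(protein_xyz), ncol(protein_xyz) == 3L,
            nrow(protein_xyz) >= 3L)
  origin <- colMeans(protein_xyz)
  cen <- sweep(protein_xyz, 2, origin)
  ev <- eigen(stats::cov(cen), symmetric = TRUE)
  if (any(diff(ev$values) > -1e-10 * max(abs(ev$values)) &
          abs(diff(ev$values)) < 1e-10 * max(abs(ev$values)))) {
    stop("degenerate principal axes: frame is not unique")
  }
  e1 <- ev$vectors[, 1]; e2 <- ev$vectors[, 2]
  if (is.null(toward)) toward <- protein_xyz[1, ]
  ref1 <- toward - origin
  if (sum(e1 * ref1) < 0) e1 <- -e1
  # pick a second reference bead not aligned with e1 for the e2 sign
  ref2 <- NULL
  for (i in seq_len(nrow(protein_xyz))) {
    v <- cen[i, ]
    if (abs(sum(e2 * v)) > 1e-8) {
      ref2 <- v
      break
    }
  }
  if (!is.null(ref2) && sum(e2 * ref2) < 0) e2 <- -e2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(origin = origin, rotation = cbind(e1, e2, e3, deparse.level = 0))
}

# Kabsch: rotation + translation mapping P onto Q (both n x 3)
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cq - as.numeric(R %*% cp))
}

#' Project DNA beads onto the local X-Y plane, frame by frame
#'
#' Each trajectory frame is rigid-body aligned (Kabsch) on its protein beads
#' to the reference structure that defined the frame, so the projection is
#' invariant under rigid motion of the whole complex. Selected DNA beads are
#' then expressed in the frame and their X-Y coordinates returned.
#'
#' @param traj a `cg_trajectory` from [run_langevin()], or an n x 3 matrix
#'   (single frame)
#' @param frame a [local_frame()] of the reference protein coordinates
#' @param topology the `bead_topology` (identifies protein rows and bases)
#' @param selection bead indices to project; default the 5'-terminal base
#' @param reference_xyz reference coordinates the frame was computed from;
#'   default the topology reference
#' @return matrix with columns `x`, `y` (one row per frame per selected bead)
#' @export
project_dna <- function(traj, frame, topology, selection = NULL,
                        reference_xyz = topology$xyz) {
  stopifnot(inherits(topology, "bead_topology"))
  if (is.null(selection)) {
    selection <- topology$nt_index$B[1L]
  }
  stopifnot(length(selection) >= 1L)
  prot <- which(topology$molecule == 1L)
  ref_p <- reference_xyz[prot, , drop = FALSE]
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else
    array(traj, dim = c(nrow(traj), 3, 1))
  nf <- dim(frames)[3]
  out <- matrix(NA_real_, nf * length(selection), 2)
  for (f in seq_len(nf)) {
    X <- frames[, , f]
    fit <- .kabsch(X[prot, , drop = FALSE], ref_p)
    sel <- sweep(X[selection, , drop = FALSE] %*% t(fit$R), 2, -fit$t)
    loc <- sweep(sel, 2, frame$origin) %*% frame$rotation
    out[(f - 1) * length(selection) + seq_along(selection), ] <- loc[, 1:2]
  }
  colnames(out) <- c("x", "y")
  out
}

#' 2D potential of mean force from projected samples
#'
#' F(bin) = -kBT log(count / max count); the occupied minimum is 0 kBT and
#' empty bins are NA (missing, not zero).
#'
#' @param samples two-column matrix of X-Y samples (Angstrom)
#' @param bin_width bin width, Angstrom
#' @param min_samples minimum sample count required
#' @return a `pmf2d` list: `x_mid`, `y_mid` bin centres, `free_energy`
#'   (kBT matrix), `counts`, `minimum` (x, y of the deepest bin)
#' @export
pmf2d <- function(samples, bin_width = 2, min_samples = 1000L) {
  stopifnot(is.matrix(samples), ncol(samples) == 2L)
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  if (nrow(samples) < min_samples) {
    stop("need at least ", min_samples, " samples for a PMF")
  }
  rx <- range(samples[, 1]); ry <- range(samples[, 2])
  bx <- seq(floor(rx[1] / bin_width) * bin_width,
            ceiling(rx[2] / bin_width) * bin_width + bin_width, by = bin_width)
  by <- seq(floor(ry[1] / bin_width) * bin_width,
            ceiling(ry[2] / bin_width) * bin_width + bin_width, by = bin_width)
  ix <- findInterval(samples[, 1], bx, rightmost.closed = TRUE)
  iy <- findInterval(samples[, 2], by, rightmost.closed = TRUE)
  counts <- matrix(0L, length(bx) - 1L, length(by) - 1L)
  tab <- table(factor(ix, levels = seq_len(nrow(counts))),
               factor(iy, levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  if (max(counts) == sum(counts)) {
    warning("all samples fall in a single bin: flat PMF")
  }
  fe <- -log(counts / max(counts))
  fe[counts == 0L] <- NA_real_
  mloc <- which(fe == 0, arr.ind = TRUE)[1, ]
  structure(list(
    x_mid = (bx[-1] + bx[-length(bx)]) / 2,
    y_mid = (by[-1] + by[-length(by)]) / 2,
    free_energy = fe, counts = counts,
    minimum = c(x = (bx[mloc[1]] + bx[mloc[1] + 1]) / 2,
                y = (by[mloc[2]] + by[mloc[2] + 1]) / 2),
    bin_width = bin_width, n_samples = nrow(samples)
  ), class = "pmf2d")
}

#' @export
print.pmf2d <- function(x, ...) {
  cat(sprintf(
    "2D PMF: %d x %d bins (%g A), %d samples, minimum at (%.1f, %.1f) A\n",
    length(x$x_mid), length(x$y_mid), x$bin_width, x$n_samples,
    x$minimum[1], x$minimum[2]
  ))
  invisible(x)
}

#' Number of protein subunits occupied by the DNA in one frame
#'
#' A subunit is occupied when at least `min_nt` nucleotides have any of
#' their beads within `cutoff` of any of the subunit's residues.
#'
#' @param coords n x 3 frame coordinates
#' @param topology the `bead_topology` (supplies subunit labels and
#'   nucleotide indices)
#' @param cutoff contact cutoff, Angstrom
#' @param min_nt minimum contacting nucleotides per subunit
#' @return integer occupancy count (0 to number of subunits)
#' @export
subunit_occupancy <- function(coords, topology, cutoff = 10, min_nt = 3L) {
  stopifnot(inherits(topology, "bead_topology"))
  prot <- which(topology$molecule == 1L)
  dna <- which(topology$molecule == 2L)
  if (length(dna) == 0L) stop("topology has no DNA beads")
  subs <- sort(unique(topology$subunit[prot]))
  px <- coords[prot, , drop = FALSE]
  dx <- coords[dna, , drop = FALSE]
  d2 <- outer(rowSums(dx^2), rep(1, length(prot))) +
    outer(rep(1, length(dna)), rowSums(px^2)) - 2 * dx %*% t(px)
  close <- d2 <= cutoff^2
  nt_of <- topology$resno[dna]
  count <- 0L
  for (s in subs) {
    cols <- topology$subunit[prot] == s
    touching <- rowSums(close[, cols, drop = FALSE]) > 0L
    n_nt_touch <- length(unique(nt_of[touching]))
    if (n_nt_touch >= min_nt) count <- count + 1L
  }
  count
}

#' Occupancy statistics over a trajectory
#'
#' @param traj a `cg_trajectory`
#' @param topology the `bead_topology`
#' @param cutoff,min_nt see [subunit_occupancy()]
#' @param burn_in fraction of initial frames discarded before averaging
#' @return an `occupancy_profile` list: per-frame `counts`, `distribution`
#'   over 0..n_subunits (sums to 1) and `mean`
#' @export
occupancy_profile <- function(traj, topology, cutoff = 10, min_nt = 3L,
                              burn_in = 1 / 7) {
  stopifnot(inherits(traj, "cg_trajectory"))
  nf <- dim(traj$frames)[3]
  first <- min(nf, floor(nf * burn_in) + 1L)
  idx <- first:nf
  counts <- vapply(idx, function(f) {
    subunit_occupancy(traj$frames[, , f], topology, cutoff, min_nt)
  }, integer(1))
  n_sub <- length(unique(topology$subunit[topology$molecule == 1L]))
  distribution <- tabulate(counts + 1L, nbins = n_sub + 1L) / length(counts)
  names(distribution) <- 0:n_sub
  structure(list(counts = counts, distribution = distribution,
                 mean = mean(counts), n_frames_used = length(counts)),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("Subunit occupancy over %d frames: mean %.2f\n",
              x$n_frames_used, x$mean))
  print(round(x$distribution, 3))
  invisible(x)
}
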