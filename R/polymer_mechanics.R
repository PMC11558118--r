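# Worm-like-chain elasticity of the released ssDNA segment and the
# stretch-work bookkeeping that converts a critical force into a null-force
# binding free energy.
#
# The released segment is treated as an inextensible WLC in the Marko-Siggia
# interpolation. All energies are returned in units of kBT at the configured
# temperature; forces in pN, lengths in nm.

#' Worm-like-chain parameters for the ssDNA tether
#'
#' @param persistence_length persistence length in nm (> 0). ssDNA default
#'   1.0 nm, a conventional value for moderate salt.
#' @param contour_length_per_nt contour length per nucleotide in nm/nt (> 0).
#'   Default 0.56 nm/nt.
#' @param temperature temperature in Kelvin (> 0).
#' @return an object of class `wlc_params`
#' @export
wlc_params <- function(persistence_length = 1.0,
                       contour_length_per_nt = 0.56,
                       temperature = 300) {
  stopifnot(
    is.numeric(persistence_length), length(persistence_length) == 1L,
    is.finite(persistence_length), persistence_length > 0,
    is.numeric(contour_length_per_nt), length(contour_length_per_nt) == 1L,
    is.finite(contour_length_per_nt), contour_length_per_nt > 0,
    is.numeric(temperature), length(temperature) == 1L,
    is.finite(temperature), temperature > 0
  )
  structure(
    list(
      persistence_length = persistence_length,
      contour_length_per_nt = contour_length_per_nt,
      temperature = temperature
    ),
    class = "wlc_params"
  )
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf(
    "WLC parameters: Lp = %.3g nm, l_nt = %.3g nm/nt, T = %.4g K (kBT = %.4f pN nm)\n",
    x$persistence_length, x$contour_length_per_nt, x$temperature,
    kBT_pN_nm(x$temperature)
  ))
  invisible(x)
}

#' Marko-Siggia WLC force at a relative extension
#'
#' F(z) = (kBT / Lp) * (1 / (4 (1 - z)^2) - 1/4 + z), z = x / Lc.
#' Monotone increasing on [0, 1); diverges as z -> 1.
#'
#' @param relative_extension z = x / Lc, in `[0, 1)` (vectorised)
#' @param params a [wlc_params()] object
#' @return force in pN
#' @export
wlc_force <- function(relative_extension, params = wlc_params()) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(relative_extension))
  z <- relative_extension
  if (any(!is.finite(z)) || any(z < 0) || any(z >= 1)) {
    stop("relative_extension must lie in [0, 1): the Marko-Siggia force diverges at full extension")
  }
  kbt <- kBT_pN_nm(params$temperature)
  (kbt / params$persistence_length) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Relative extension of a WLC at a given force
#'
#' Numerical inverse of [wlc_force()] by bisection/Brent root finding.
#'
#' @param force force in pN (>= 0, vectorised)
#' @param params a [wlc_params()] object
#' @return relative extension z in `[0, 1)`
#' @export
wlc_extension <- function(force, params = wlc_params()) {
  stopifnot(inherits(params, "wlc_params"), is.numeric(force))
  if (any(!is.finite(force)) || any(force < 0)) {
    stop("force must be finite and >= 0")
  }
  vapply(force, function(f) {
    if (f == 0) return(0)
    # upper bracket: z < 1, force diverges as z -> 1 so a root always exists
    upper <- 1 - 1e-12
    stats::uniroot(
      function(z) wlc_force(z, params) - f,
      lower = 0, upper = upper, tol = 1e-14
    )$root
  }, numeric(1))
}

#' Elastic energy of stretching released ssDNA to its equilibrium extension
#'
#' Integrates the WLC force from zero extension to x(F) for a chain of
#' contour length `n_nt * contour_length_per_nt` by adaptive quadrature.
#'
#' @param force force in pN (>= 0)
#' @param n_nt number of released nucleotides (> 0)
#' @param params a [wlc_params()] object
#' @return stretch energy in kBT (nonnegative, increasing in force)
#' @export
stretch_energy <- function(force, n_nt, params = wlc_params()) {
  stopifnot(inherits(params, "wlc_params"),
            is.numeric(force), length(force) == 1L, is.finite(force), force >= 0,
            is.numeric(n_nt), length(n_nt) == 1L, n_nt > 0)
  if (force == 0) return(0)
  lc <- n_nt * params$contour_length_per_nt
  kbt <- kBT_pN_nm(params$temperature)
  zmax <- wlc_extension(force, params)
  # integrate F dx = Lc * int_0^zmax F(z) dz
  q <- stats::integrate(function(z) wlc_force(z, params), lower = 0, upper = zmax,
                        rel.tol = 1e-10, abs.tol = 0)
  if (q$message != "OK") {
    stop("stretch_energy quadrature failed: ", q$message,
         sprintf(" (force = %g pN, zmax = %g, abs.error = %g)", force, zmax, q$abs.error))
  }
  lc * q$value / kbt
}

#' Free-energy bookkeeping of a force-held extension jump
#'
#' When a bound segment of `n_released_nt` nucleotides is released at constant
#' force F, the force does work F * dx(F) over the extension jump
#' dx(F) = n * l_nt * z(F), while the released chain stores the elastic
#' energy returned by [stretch_energy()]. The difference is the net
#' free-energy bias that the force puts on the unbound state.
#'
#' @param force force in pN (>= 0)
#' @param n_released_nt number of nucleotides released by unbinding
#' @param params a [wlc_params()] object
#' @return an `energy_breakdown` list with fields `work_term`, `stretch_term`
#'   and `delta_delta_g` (all in kBT); `delta_delta_g = work_term -
#'   stretch_term` exactly, and is nonnegative for the WLC.
#' @export
delta_delta_g <- function(force, n_released_nt = 20, params = wlc_params()) {
  stopifnot(is.numeric(force), length(force) == 1L, is.finite(force), force >= 0)
  kbt <- kBT_pN_nm(params$temperature)
  z <- wlc_extension(force, params)
  dx <- n_released_nt * params$contour_length_per_nt * z
  work <- force * dx / kbt
  stretch <- stretch_energy(force, n_released_nt, params)
  structure(
    list(
      work_term = work,
      stretch_term = stretch,
      delta_delta_g = work - stretch
    ),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "Extension-jump energy breakdown (kBT): work = %.4f, stretch = %.4f, ddG = %.4f\n",
    x$work_term, x$stretch_term, x$delta_delta_g
  ))
  invisible(x)
}
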