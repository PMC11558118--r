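# Synthetic magnetic-tweezers fixtures: two-state telegraph extension traces
# with Bell-model force-dependent rates, per salt condition.
#
# A condition is specified by one or two interaction modes, each with a
# critical force and a rate scale at that force; the zero-force Bell
# prefactors are derived from these so that the analytic rate crossover sits
# exactly at the requested critical force:
#   k_bind(F)  = k_bind0  * exp(-F * dx_bind / kBT)
#   k_unbind(F)= k_unbind0 * exp(+F * dx_unbind / kBT)

#' Salt-condition specification for the telegraph-trace generator
#'
#' @param label condition label (e.g. "75mM")
#' @param salt_mM NaCl concentration in mM
#' @param ligand_nM protein concentration in nM (the observed binding rate
#'   already contains the factor `[L]`)
#' @param modes data frame with one row per interaction mode and columns
#'   `fc_pN` (target crossover), `rate_at_fc` (both rates at the crossover,
#'   1/s), `dx_bind_nm`, `dx_unbind_nm` (Bell distances), `weight`
#' @param forces default measurement forces in pN
#' @param noise_sd Gaussian measurement noise SD in nm
#' @param sampling_rate sampling rate in Hz
#' @param baseline_nm bound-state extension offset (handles), nm
#' @param n_released_nt nucleotides released on unbinding; sets the
#'   force-dependent extension-level separation through the WLC
#' @param wlc a [wlc_params()] object
#' @return a `condition_spec` list, with derived `k_bind0` / `k_unbind0`
#'   columns added to `modes`
#' @export
condition_spec <- function(label, salt_mM, ligand_nM = 10, modes,
                           forces = NULL, noise_sd = 5, sampling_rate = 100,
                           baseline_nm = 600, n_released_nt = 20,
                           wlc = wlc_params()) {
  stopifnot(is.data.frame(modes),
            all(c("fc_pN", "rate_at_fc", "dx_bind_nm", "dx_unbind_nm",
                  "weight") %in% names(modes)),
            all(modes$rate_at_fc > 0), all(modes$weight > 0))
  modes$weight <- modes$weight / sum(modes$weight)
  kbt <- kBT_pN_nm(wlc$temperature)
  modes$k_bind0 <- modes$rate_at_fc * exp(modes$fc_pN * modes$dx_bind_nm / kbt)
  modes$k_unbind0 <- modes$rate_at_fc * exp(-modes$fc_pN * modes$dx_unbind_nm / kbt)
  structure(list(
    label = label, salt_mM = salt_mM, ligand_nM = ligand_nM,
    modes = modes, forces = forces, noise_sd = noise_sd,
    sampling_rate = sampling_rate, baseline_nm = baseline_nm,
    n_released_nt = n_released_nt, wlc = wlc
  ), class = "condition_spec")
}

#' Bell rates of one mode at a given force
#' @param spec a [condition_spec()]
#' @param force force in pN
#' @param mode mode index
#' @return named vector `c(k_bind =, k_unbind =)` in 1/s
#' @export
bell_rates <- function(spec, force, mode = 1L) {
  kbt <- kBT_pN_nm(spec$wlc$temperature)
  m <- spec$modes[mode, ]
  c(k_bind = m$k_bind0 * exp(-force * m$dx_bind_nm / kbt),
    k_unbind = m$k_unbind0 * exp(force * m$dx_unbind_nm / kbt))
}

#' Analytic rate-crossover force of a mode
#'
#' Solves k_bind(F) = k_unbind(F) on the log scale.
#'
#' @inheritParams bell_rates
#' @return crossover force in pN
#' @export
crossover_force <- function(spec, mode = 1L) {
  m <- spec$modes[mode, ]
  kbt <- kBT_pN_nm(spec$wlc$temperature)
  lr <- log(m$k_bind0 / m$k_unbind0)
  denom <- (m$dx_bind_nm + m$dx_unbind_nm) / kbt
  if (abs(denom) < 1e-12) {
    if (abs(lr) < 1e-12) return(0)
    stop("rates never cross: zero Bell distances with unequal prefactors")
  }
  lr / denom
}

#' Generator-truth record of a condition
#'
#' @param spec a [condition_spec()]
#' @return data frame per mode: analytic crossover `fc_star_pN` and
#'   null-force free energy `dg0_star_kbt = -ddG(fc_star)`
#' @export
condition_truth <- function(spec) {
  fc <- vapply(seq_len(nrow(spec$modes)), function(m) crossover_force(spec, m),
               numeric(1))
  dg0 <- binding_free_energy(pmax(fc, 0), spec$n_released_nt, spec$wlc)
  data.frame(mode = seq_along(fc), fc_star_pN = fc, dg0_star_kbt = dg0,
             weight = spec$modes$weight)
}

#' Generate one constant-force telegraph trace
#'
#' Continuous-time two-state Markov chain with Bell rates at the given
#' force, sampled on a uniform grid with Gaussian measurement noise. The
#' unbound level sits above the bound level by the WLC extension of the
#' released nucleotides at this force. Reproducible for a fixed seed.
#'
#' @param spec a [condition_spec()]
#' @param force force in pN
#' @param duration trace duration in s
#' @param seed RNG seed
#' @param mode which interaction mode generates this trace
#' @return a [force_extension_trace()]; attribute `truth` carries the
#'   per-sample generator states, the rates used, and the mode index.
#'   Attribute `no_transition` flags traces without a single event.
#' @export
make_telegraph_trace <- function(spec, force, duration = 200, seed = 1L,
                                 mode = 1L) {
  stopifnot(inherits(spec, "condition_spec"), force > 0, duration > 0)
  rates <- bell_rates(spec, force, mode)
  kb <- rates[["k_bind"]]; ku <- rates[["k_unbind"]]
  fs <- spec$sampling_rate
  n <- round(duration * fs)
  dz <- wlc_extension(force, spec$wlc)
  jump <- spec$n_released_nt * spec$wlc$contour_length_per_nt * dz

  withr::with_seed(seed, {
    p_bound <- kb / (kb + ku)
    s0 <- stats::rbinom(1L, 1L, p_bound)
    # alternating dwell sequence; extend until the duration is covered
    states_seq <- integer(0)
    dwells <- numeric(0)
    total <- 0
    s <- s0
    while (total < duration) {
      chunk <- 64L
      st <- (s + seq_len(chunk) - 1L) %% 2L
      rt <- ifelse(st == 1L, ku, kb)  # bound leaves at k_unbind
      dw <- stats::rexp(chunk, rt)
      states_seq <- c(states_seq, st)
      dwells <- c(dwells, dw)
      total <- total + sum(dw)
      s <- (s + chunk) %% 2L
    }
    tgrid <- (seq_len(n) - 1L) / fs
    idx <- findInterval(tgrid, cumsum(c(0, dwells)), rightmost.closed = FALSE)
    state <- states_seq[pmin(idx, length(states_seq))]
    ext <- spec$baseline_nm + (1L - state) * jump +
      stats::rnorm(n, 0, spec$noise_sd)
    tr <- force_extension_trace(tgrid, ext, force, fs, spec$label)
    attr(tr, "truth") <- list(states = state, k_bind = kb, k_unbind = ku,
                              mode = mode, jump_nm = jump, seed = seed)
    attr(tr, "no_transition") <- length(unique(state)) == 1L
    if (attr(tr, "no_transition")) {
      warning("no transition within trace duration (force = ", force, " pN)")
    }
    tr
  })
}

#' Generate a full per-condition trace bundle with its truth record
#'
#' For each force, `n_traces` telegraph traces are generated; in a two-mode
#' condition each trace's mode is drawn from the mode weights. Per-trace
#' seeds are drawn once from the bundle seed, so the bundle is a pure
#' function of `(spec, forces, n_traces, duration, seed)`.
#'
#' @param spec a [condition_spec()]
#' @param forces forces in pN; defaults to `spec$forces`
#' @param n_traces traces per force
#' @param duration per-trace duration in s
#' @param seed bundle seed
#' @return list with `traces`, per-trace `modes`/`forces`, the `spec` and
#'   the analytic `truth` from [condition_truth()]
#' @export
make_condition_dataset <- function(spec, forces = spec$forces, n_traces = 20,
                                   duration = 200, seed = 1L) {
  stopifnot(inherits(spec, "condition_spec"), length(forces) >= 1L)
  truth <- condition_truth(spec)
  if (min(forces) > min(truth$fc_star_pN) || max(forces) < max(truth$fc_star_pN)) {
    warning("forces do not bracket the generator crossover(s)")
  }
  grid <- expand.grid(rep = seq_len(n_traces), force = forces)
  nm <- nrow(spec$modes)
  draws <- withr::with_seed(seed, {
    list(
      modes = if (nm > 1L) {
        sample.int(nm, nrow(grid), replace = TRUE, prob = spec$modes$weight)
      } else rep(1L, nrow(grid)),
      seeds = sample.int(.Machine$integer.max - 1L, nrow(grid))
    )
  })
  traces <- lapply(seq_len(nrow(grid)), function(i) {
    suppressWarnings(make_telegraph_trace(
      spec, grid$force[i], duration, seed = draws$seeds[i], mode = draws$modes[i]
    ))
  })
  list(traces = traces, forces = grid$force, modes = draws$modes,
       spec = spec, truth = truth, seed = seed)
}

#' Load a shipped salt-condition fixture
#'
#' Three conditions ship with the package, mirroring the measured regimes:
#' `"20mM"` (single mode, crossover 15 pN), `"42mM"` (two modes, crossovers
#' 10 and 15 pN), `"75mM"` (single mode, crossover 7 pN).
#'
#' @param name one of "20mM", "42mM", "75mM", or a path to a condition YAML
#' @param wlc a [wlc_params()] object
#' @return a [condition_spec()]
#' @export
fixture_condition <- function(name, wlc = wlc_params()) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "conditions", paste0("fixture_", name, ".yaml"),
                package = "ssbwrap")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown condition fixture: ", name)
  }
  y <- yaml::read_yaml(path)
  modes <- do.call(rbind, lapply(y$modes, as.data.frame))
  condition_spec(
    label = y$label, salt_mM = y$salt_mM, ligand_nM = y$ligand_nM,
    modes = modes, forces = as.numeric(y$forces_pN),
    noise_sd = y$noise_sd_nm, sampling_rate = y$sampling_rate_hz,
    n_released_nt = y$n_released_nt, wlc = wlc
  )
}
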