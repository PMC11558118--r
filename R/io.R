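# File formats and pipeline entry points: trace CSVs with YAML sidecars,
# charge-overlay CSVs, JSON reports stamped with schema/package/config/seed
# metadata, and validated run configurations.

.SCHEMA_VERSION <- "1"

#' Write a trace as CSV with a YAML metadata sidecar
#'
#' @param trace a [force_extension_trace()]
#' @param path CSV path; the sidecar goes to `<path>.yaml`
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "force_extension_trace"))
  df <- as.data.frame(trace)[, c("time_s", "extension_nm", "force_pN")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    sampling_rate_hz = attr(trace, "sampling_rate"),
    condition = attr(trace, "condition_label"),
    force_pN = trace$force_pN[1L]
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a trace CSV (with optional YAML sidecar)
#'
#' @param path CSV path with header `time_s,extension_nm,force_pN`
#' @return a [force_extension_trace()]
#' @export
read_trace_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed trace CSV ", path, ": ",
                                          conditionMessage(e)))
  need <- c("time_s", "extension_nm", "force_pN")
  if (!all(need %in% names(df))) {
    stop("trace CSV ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  force_extension_trace(
    df$time_s, df$extension_nm, df$force_pN[1L],
    sampling_rate = meta$sampling_rate_hz,
    condition_label = if (is.null(meta$condition)) "" else meta$condition
  )
}

#' Write / read charge overlays as CSV
#'
#' Columns: `subunit`, `residue_index`, `state`, `charge_e`.
#'
#' @param overlays overlay data frame
#' @param path CSV path
#' @return `path` / the overlay data frame
#' @export
write_overlays_csv <- function(overlays, path) {
  stopifnot(all(c("subunit", "residue_index", "state", "charge_e") %in%
                  names(overlays)))
  utils::write.csv(overlays, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_overlays_csv
#' @export
read_overlays_csv <- function(path) {
  ov <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subunit", "residue_index", "state", "charge_e")
  if (!all(need %in% names(ov))) {
    stop("overlay CSV lacks column(s): ",
         paste(setdiff(need, names(ov)), collapse = ", "))
  }
  ov
}

#' Deterministic hash of a configuration object
#'
#' Canonical-JSON serialisation hashed with MD5; used to stamp outputs.
#'
#' @param x any jsonlite-serialisable object
#' @return hex string
#' @export
config_hash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

#' Read and validate a run configuration YAML
#'
#' Recognised keys: `pipeline`, `inputs`, `params`, `seed`, `output_dir`,
#' `log_level`. Unknown keys are rejected.
#'
#' @param path YAML path
#' @return a `run_config` list (with defaults filled in and `hash` added)
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("pipeline", "inputs", "params", "seed", "output_dir", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$log_level)) cfg$log_level <- "info"
  cfg$hash <- config_hash(cfg[known[known %in% names(cfg)]])
  structure(cfg, class = "run_config")
}

#' Write a JSON report stamped with schema, package, config hash and seed
#'
#' @param report named list of results
#' @param path output JSON path
#' @param seed RNG seed used for the run
#' @param config optional configuration object (hashed into the stamp)
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path, seed = NA_integer_, config = NULL) {
  stamped <- c(list(
    schema_version = .SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("ssbwrap")),
    config_hash = if (is.null(config)) NA_character_ else config_hash(config),
    seed = seed
  ), report)
  jsonlite::write_json(stamped, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Materialise all synthetic fixtures under a directory
#'
#' Writes, per salt condition, the telegraph traces as CSV + YAML sidecars
#' and a bundle metadata YAML; plus the toy tetramer complex as PDB and its
#' charge overlays as CSV. Idempotent for a fixed seed.
#'
#' @param dir target directory
#' @param seed master seed
#' @param n_traces traces per force per condition
#' @param duration per-trace duration, s
#' @param force overwrite a non-empty directory
#' @return `dir`, invisibly
#' @export
generate_fixtures <- function(dir, seed = 1L, n_traces = 5, duration = 120,
                              force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in c("20mM", "42mM", "75mM")) {
    spec <- fixture_condition(cond)
    bundle <- make_condition_dataset(spec, n_traces = n_traces,
                                     duration = duration, seed = seed)
    cdir <- file.path(dir, paste0("fixture_", cond))
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_along(bundle$traces)) {
      write_trace_csv(bundle$traces[[i]],
                      file.path(cdir, sprintf("trace_%03d.csv", i)))
    }
    yaml::write_yaml(list(
      condition = cond, salt_mM = spec$salt_mM, seed = seed,
      n_traces_per_force = n_traces, duration_s = duration,
      forces_pN = unique(bundle$forces),
      truth = lapply(seq_len(nrow(bundle$truth)), function(m) {
        as.list(bundle$truth[m, ])
      })
    ), file.path(cdir, "bundle.yaml"))
  }
  cx <- make_toy_tetramer(seed = seed)
  write_complex_pdb(cx, file.path(dir, "toy_tetramer_synthetic.pdb"))
  write_overlays_csv(cx$overlays, file.path(dir, "charge_overlays.csv"))
  invisible(dir)
}

#' Read a condition bundle written by [generate_fixtures()]
#'
#' @param cdir condition directory containing `trace_*.csv` and `bundle.yaml`
#' @return list with `traces` and `meta`
#' @export
read_condition_bundle <- function(cdir) {
  files <- sort(list.files(cdir, pattern = "^trace_.*\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no traces found in ", cdir)
  meta <- yaml::read_yaml(file.path(cdir, "bundle.yaml"))
  list(traces = lapply(files, read_trace_csv), meta = meta)
}

#' Full trace-analysis pipeline over one or more condition bundles
#'
#' Traces -> segmentation -> dwells -> rates -> critical force -> mode
#' classification -> null-force binding free energies, mirroring the
#' tweezers analysis; returns the per-condition results plus the salt
#' profile with the inter-mode free-energy jump.
#'
#' @param bundles named list: each element has `traces` (list) and metadata
#'   fields `condition`/`salt_mM`, or is a [make_condition_dataset()] result
#' @param n_released_nt nucleotides entering the free-energy conversion
#' @param wlc a [wlc_params()]
#' @param seed analysis (bootstrap) seed
#' @return list with `results` (per condition), `profile`, `jump_kbt`
#' @export
analyze_traces <- function(bundles, n_released_nt = 20, wlc = wlc_params(),
                           seed = 1L) {
  stopifnot(is.list(bundles), length(bundles) >= 1L)
  results <- lapply(bundles, function(b) {
    label <- if (!is.null(b$spec)) b$spec$label else b$meta$condition
    salt <- if (!is.null(b$spec)) b$spec$salt_mM else b$meta$salt_mM
    suppressWarnings(analyze_condition(
      b$traces, condition_label = label, salt_mM = salt,
      n_released_nt = n_released_nt, wlc = wlc, seed = seed
    ))
  })
  prof <- energy_salt_profile(results)
  list(results = results, profile = prof$profile, jump_kbt = prof$jump_kbt)
}

#' Wrapping simulation pipeline on a toy complex
#'
#' Builds the charged, anchored topology for the requested surface state,
#' runs one Langevin trajectory per seed, and summarises subunit occupancy
#' (and optionally the 2D PMF of the 5' base location).
#'
#' @param complex a [make_toy_tetramer()] result
#' @param state `"unbridged"` or `"bridged"`
#' @param params a [sim_params()] (salt etc.)
#' @param n_steps,stride integration length and storage stride
#' @param seeds integer vector of trajectory seeds
#' @param burn_in fraction of frames discarded before statistics
#' @param pmf compute the pooled 5'-base PMF
#' @return list with `occupancy` (per seed), `mean_occupancy`, `pmf`
#'   (optional), `trajectories` (last trajectory only unless `keep_all`),
#'   `topology`
#' @param keep_all keep every trajectory object (memory!)
#' @export
simulate_wrapping <- function(complex, state, params = sim_params(),
                              n_steps = 5e5, stride = 500L, seeds = 1:4,
                              burn_in = 1 / 7, pmf = FALSE, keep_all = FALSE) {
  topo <- build_complex_topology(complex, state, params)
  frame <- local_frame(
    topo$xyz[topo$molecule == 1L, , drop = FALSE],
    toward = colMeans(topo$xyz[topo$molecule == 1L &
                                 topo$subunit == complex$anchor_subunit, ,
                               drop = FALSE])
  )
  occ <- numeric(length(seeds))
  samples <- list()
  trajs <- list()
  for (si in seq_along(seeds)) {
    tr <- run_langevin(topo, params, n_steps = n_steps, stride = stride,
                       seed = seeds[si])
    if (tr$diverged) warning("trajectory ", seeds[si], " diverged")
    op <- occupancy_profile(tr, topo, burn_in = burn_in)
    occ[si] <- op$mean
    if (pmf) {
      nf <- dim(tr$frames)[3]
      first <- min(nf, floor(nf * burn_in) + 1L)
      sub <- tr$frames[, , first:nf, drop = FALSE]
      tr_sub <- tr
      tr_sub$frames <- sub
      samples[[si]] <- project_dna(tr_sub, frame, topo)
    }
    if (keep_all || si == length(seeds)) trajs[[si]] <- tr
  }
  out <- list(
    state = state, seeds = seeds,
    occupancy = occ, mean_occupancy = mean(occ),
    topology = topo, frame = frame,
    trajectories = trajs[!vapply(trajs, is.null, logical(1))]
  )
  if (pmf) out$pmf <- pmf2d(do.call(rbind, samples))
  out
}
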