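#' Run the full simulation and analysis pipeline
#'
#' Executes, from a single configuration and seed: Wigner sampling ->
#' surface-hopping ensemble -> population series in all three pictures ->
#' hop-count matrix -> nine-rate kinetic-model fit -> single-exponential
#' singlet-manifold fit -> mean first-hop times -> hop-geometry statistics
#' -> coherence series -> bond-length statistics.  When `outdir` is given,
#' all tables are written as TSV with a provenance header (config hash and
#' seed) and per-stage failures are recorded without discarding completed
#' stages.
#'
#' @param config an `sh_run_config` (see [default_run_config()] and
#'   [read_run_config()]).
#' @param outdir optional output directory for the report bundle.
#' @param ensemble optional pre-computed ensemble (e.g. scripted
#'   fixtures); when supplied, the simulation stage is skipped and the
#'   analysis stages run on it.
#' @param model optional model overriding the config's preset.
#' @return an object of class `sh_report`: a list with elements `model`,
#'   `ensemble`, `populations` (list per basis), `hop_matrix`,
#'   `kinetic_fit`, `exp_fit`, `first_hop_times`, `hop_stats`,
#'   `coherence`, `bonds`, `failed_stages`, `seed`, `config`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL,
                         ensemble = NULL, model = NULL) {
  if (is.null(config$model))
    stop("run_pipeline: config is missing the model section")
  failed <- character()
  note <- function(stage, err) {
    failed <<- c(failed, paste0(stage, ": ", conditionMessage(err)))
    NULL
  }
  if (is.null(model)) {
    if (!identical(config$model$preset, "2tp_lvc"))
      stop("run_pipeline: unknown model preset ", config$model$preset)
    model <- default_2tp_model()
  }
  seed <- config$sampling$seed
  if (is.null(ensemble)) {
    params <- propagation_params(
      dt = config$propagation$dt, t_max = config$propagation$t_max,
      substeps = config$propagation$substeps,
      decoherence_C = config$propagation$decoherence_C,
      frustrated_policy = config$propagation$frustrated_policy)
    ensemble <- run_ensemble(model, n_traj = config$sampling$n_traj,
                             initial_state = config$sampling$initial_state,
                             params = params, seed = seed)
  }
  grid <- ensemble[[1]]$times

  pops <- list()
  for (b in c("mch_active", "diagonal_active", "quantum_amplitude")) {
    pops[[b]] <- tryCatch(compute_populations(ensemble, b, grid),
                          error = function(e) note(paste0("populations_", b), e))
  }
  hop_mat <- tryCatch(
    count_hops(ensemble,
               report_threshold = config$analysis$hop_report_threshold),
    error = function(e) note("hop_matrix", e))
  kin_fit <- tryCatch(
    fit_kinetic_model(pops$mch_active, options = list(seed = seed)),
    error = function(e) note("kinetic_fit", e))
  exp_fit <- tryCatch(
    fit_exponential_manifold(pops$mch_active,
                             manifold = config$analysis$manifolds$singlets,
                             ensemble = ensemble, n_boot = 100, seed = seed),
    error = function(e) note("exp_fit", e))
  fh <- tryCatch({
    trans <- list(c("S2", "S1"), c("S1", "T2"), c("T2", "T1"),
                  c("S2", "T2"), c("S1", "S0"))
    out <- lapply(trans, function(ft)
      c(list(from = ft[1], to = ft[2]),
        mean_first_hop_time(ensemble, ft[1], ft[2])))
    do.call(rbind, lapply(out, function(x)
      data.frame(from = x$from, to = x$to, mean_fs = x$mean_fs, n = x$n,
                 n_excluded = x$n_excluded)))
  }, error = function(e) note("first_hop_times", e))
  ref_mode <- config$analysis$reference_mode
  if (is.null(ref_mode) || identical(ref_mode, "auto")) ref_mode <- NULL
  hop_stats <- tryCatch({
    trans <- list(c("S2", "S1"), c("S1", "T2"), c("T2", "T1"))
    st <- lapply(trans, function(ft)
      hop_geometry_stats(ensemble, ft, model, reference_mode = ref_mode))
    names(st) <- vapply(trans, paste, "", collapse = "->")
    st
  }, error = function(e) note("hop_stats", e))
  coh <- tryCatch(coherence_series(ensemble, model, grid),
                  error = function(e) note("coherence", e))
  bonds <- tryCatch(
    lapply(config$analysis$bond_pairs, function(bp)
      bond_length_series(ensemble, bp, model)),
    error = function(e) note("bonds", e))

  report <- structure(list(
    model = model, ensemble = ensemble, populations = pops,
    hop_matrix = hop_mat, kinetic_fit = kin_fit, exp_fit = exp_fit,
    first_hop_times = fh, hop_stats = hop_stats, coherence = coh,
    bonds = bonds, failed_stages = failed, seed = seed, config = config
  ), class = "sh_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.sh_report <- function(x, ...) {
  cat("surfhop pipeline report (seed ", x$seed, ", ",
      length(x$ensemble), " trajectories)\n", sep = "")
  if (!is.null(x$exp_fit))
    cat(sprintf("  singlet-manifold lifetime: %.0f fs\n", x$exp_fit$tau_fs))
  if (!is.null(x$hop_matrix))
    cat("  accepted hops:", sum(x$hop_matrix$counts), "\n")
  if (length(x$failed_stages))
    cat("  FAILED stages:", paste(x$failed_stages, collapse = "; "), "\n")
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' TSV tables (populations per basis, hop matrix raw and rendered, kinetic
#' fit parameters, exponential fit, first-hop times, hop-geometry
#' statistics, bond summaries, coherence means) plus a `MANIFEST.yaml`
#' with seed, config and failure diagnostics.  Every table carries the
#' config hash and seed in its header.
#'
#' @param report an `sh_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  seed <- report$seed
  w <- function(df, name, extra = character())
    write_tsv_report(df, file.path(outdir, name), cfg, seed, extra)
  for (b in names(report$populations)) {
    ps <- report$populations[[b]]
    if (is.null(ps)) next
    w(data.frame(t_fs = ps$times, ps$populations, check.names = FALSE),
      paste0("populations_", b, ".tsv"))
  }
  if (!is.null(report$hop_matrix)) {
    hm <- report$hop_matrix
    w(data.frame(from = rownames(hm$counts), hm$counts, check.names = FALSE),
      "hop_matrix_full.tsv")
    rend <- format_hop_matrix(hm, main_pathway = cfg$analysis$main_pathway)
    w(data.frame(from = rownames(rend), rend, check.names = FALSE),
      "hop_matrix_report.tsv",
      extra = paste0("entries below ", hm$report_threshold,
                     " suppressed; main pathway in *..*"))
  }
  if (!is.null(report$kinetic_fit) && !is.null(report$kinetic_fit$parameters))
    w(report$kinetic_fit$parameters, "kinetic_fit.tsv",
      extra = paste0("SSE= ", report$kinetic_fit$residual,
                     " converged= ", report$kinetic_fit$converged))
  if (!is.null(report$exp_fit))
    w(data.frame(tau_fs = report$exp_fit$tau_fs,
                 se_tau_fs = report$exp_fit$se_tau_fs,
                 sse = report$exp_fit$residual,
                 converged = report$exp_fit$converged),
      "exponential_fit.tsv")
  if (!is.null(report$first_hop_times))
    w(report$first_hop_times, "first_hop_times.tsv")
  if (!is.null(report$hop_stats)) {
    for (nm in names(report$hop_stats)) {
      st <- report$hop_stats[[nm]]
      if (st$empty) next
      w(data.frame(mode = names(st$mu), mu = st$mu, sigma = st$sigma),
        paste0("hop_geometry_", gsub("->", "_to_", nm), ".tsv"),
        extra = c(paste0("n_hops= ", st$n_hops),
                  "projections in Angstrom, population-sd convention,",
                  "out-of-plane phases aligned to the reference mode"))
    }
  }
  if (!is.null(report$coherence)) {
    co <- report$coherence
    w(data.frame(t_fs = co$times, signed = co$signed_mean,
                 unsigned = co$unsigned_mean, check.names = FALSE),
      "coherence_means.tsv")
  }
  if (!is.null(report$bonds)) {
    bs <- do.call(rbind, lapply(report$bonds, function(b)
      data.frame(pair = paste(b$atom_pair, collapse = "-"),
                 t(b$summary))))
    w(bs, "bond_summary.tsv")
  }
  yaml::write_yaml(list(seed = seed,
                        config = unclass(cfg),
                        config_hash = config_hash(cfg),
                        failed_stages = report$failed_stages),
                   file.path(outdir, "MANIFEST.yaml"))
  invisible(outdir)
}
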