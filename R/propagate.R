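#' Propagation parameters
#'
#' Container for the surface-hopping integration settings.  Defaults follow
#' the standard protocol for this class of simulation: a 0.5 fs classical
#' time step, 100 electronic substeps per classical step, and an
#' energy-based decoherence correction with C = 0.1 Hartree.
#'
#' @param dt classical time step in fs (> 0).
#' @param t_max total propagation time in fs.
#' @param substeps electronic substeps per classical step (>= 1).
#' @param nuc_substeps internal velocity-Verlet subdivisions of each
#'   classical step (default 40, i.e. a 0.0125 fs nuclear integration step at
#'   the default `dt`).  Surface-hopping decisions, decoherence, amplitude
#'   propagation and stored frames remain at `dt`; the subdivision only
#'   integrates the nuclear equations of motion accurately through
#'   narrowly avoided crossings, where the active-surface force varies on
#'   scales shorter than `dt`.
#' @param decoherence_C decoherence parameter C in Hartree (>= 0; set to a
#'   negative value to disable the correction entirely).
#' @param rng_seed integer seed for the hopping random stream; when `NULL`
#'   the seed recorded on the initial condition is used.
#' @param frustrated_policy what to do with the nuclear momentum when a hop
#'   is refused for lack of kinetic energy: `"continue"` (keep it) or
#'   `"reflect"` (negate it).
#' @param hopping logical; `FALSE` propagates amplitudes without ever
#'   switching the active surface (useful for convergence checks).
#' @param freeze_nuclei logical; `TRUE` holds the nuclei fixed and
#'   propagates only the electronic amplitudes (pure quantum evolution).
#' @return an object of class `sh_params`.
#' @export
propagation_params <- function(dt = 0.5, t_max = 1000, substeps = 100,
                               decoherence_C = 0.1, rng_seed = NULL,
                               frustrated_policy = c("continue", "reflect"),
                               hopping = TRUE, freeze_nuclei = FALSE,
                               nuc_substeps = 40) {
  frustrated_policy <- match.arg(frustrated_policy)
  stopifnot(dt > 0, substeps >= 1, t_max > 0, nuc_substeps >= 1)
  structure(list(
    dt = dt, t_max = t_max, substeps = as.integer(substeps),
    decoherence_C = decoherence_C, rng_seed = rng_seed,
    frustrated_policy = frustrated_policy,
    hopping = isTRUE(hopping), freeze_nuclei = isTRUE(freeze_nuclei),
    nuc_substeps = as.integer(nuc_substeps)
  ), class = "sh_params")
}

#' Propagate one surface-hopping trajectory
#'
#' Velocity-Verlet nuclear dynamics on the active spin-mixed (diagonal)
#' surface, with electronic amplitudes advanced each classical step by the
#' local-diabatization (overlap) scheme: the step propagator is
#' `T^dagger %*% prod_m exp(-i Hbar_m dt/substeps)` where `T` is the
#' Loewdin-orthogonalized overlap of consecutive eigenvector sets and
#' `Hbar` is interpolated linearly between the step endpoints.  Hops are
#' drawn by the fewest-switches rule from the propagator flux (see
#' [hop_decision()]); momentum is rescaled along the full velocity vector
#' at accepted hops, and the energy-based decoherence correction is applied
#' once per classical step after the hop decision.
#'
#' @param model an `sh_lvc_model`.
#' @param init an `sh_phase_point` from [sample_wigner()] (or a list with
#'   fields `q`, `p`, `initial_state`, `seed`).
#' @param params an `sh_params` from [propagation_params()].
#' @return an object of class `sh_trajectory`: per-frame arrays `times`
#'   (fs), `q`, `p` (dimensionless), `e_diag`, `e_mch` (eV), complex
#'   `amplitudes` (diagonal basis), `pop_mch`, integer `active_diag`,
#'   character `active_mch`, energies `e_kin`/`e_pot`/`e_tot` (Hartree,
#'   for conservation bookkeeping), a `hops` data frame, and a `warnings`
#'   list (eigenvector-tracking failures, skipped decoherence, frustrated
#'   hops).
#' @export
propagate_trajectory <- function(model, init, params = propagation_params()) {
  stopifnot(inherits(model, "sh_lvc_model"))
  pk <- model_pack(model)
  nsteps <- as.integer(round(params$t_max / params$dt))
  init_state <- init$initial_state %||% model$states[length(model$states)]
  n0 <- match(init_state, pk$labels)
  if (is.na(n0)) stop("propagate_trajectory: initial state not in model")
  seed <- params$rng_seed %||% init$seed %||% 1L
  set.seed(as.integer(seed))
  dt_au <- fs_to_autime(params$dt)
  raw <- sh_propagate_cpp(
    pk$eps, pk$omega, pk$kappa, pk$lambda, pk$soc,
    as.numeric(init$q), as.numeric(init$p), n0,
    dt_au, nsteps, params$substeps, params$decoherence_C,
    as.integer(params$frustrated_policy == "reflect"),
    as.integer(params$hopping), as.integer(params$freeze_nuclei),
    as.integer(params$nuc_substeps %||% 40L)
  )
  times <- seq(0, by = params$dt, length.out = nsteps + 1)
  hops <- data.frame(
    t = raw$hop_step * params$dt,
    step = raw$hop_step,
    from_diag = raw$hop_from_diag,
    to_diag = raw$hop_to_diag,
    from_mch = pk$labels[raw$hop_from_mch],
    to_mch = pk$labels[raw$hop_to_mch],
    frustrated = as.logical(raw$hop_frustrated),
    gap_eV = hartree_to_ev(raw$hop_gap),
    stringsAsFactors = FALSE
  )
  colnames(raw$pop_mch) <- pk$labels
  structure(list(
    times = times,
    q = raw$q, p = raw$p,
    e_diag = hartree_to_ev(raw$e_diag),
    e_mch = hartree_to_ev(raw$e_mch),
    amplitudes = raw$amplitudes,
    pop_mch = raw$pop_mch,
    active_diag = as.integer(raw$active_diag),
    active_mch = pk$labels[raw$active_mch],
    e_kin = raw$e_kin, e_pot = raw$e_pot, e_tot = raw$e_tot,
    hops = hops,
    params = params,
    init = init,
    state_labels = pk$labels,
    warnings = list(
      n_track_fail = raw$n_track_fail,
      n_decoherence_skipped = raw$n_decoherence_skipped,
      n_frustrated = raw$n_frustrated
    )
  ), class = "sh_trajectory")
}

#' @export
print.sh_trajectory <- function(x, ...) {
  cat("Surface-hopping trajectory:", length(x$times), "frames,",
      sprintf("%.1f fs, dt = %.3g fs\n", max(x$times), x$params$dt))
  cat("Hops:", sum(!x$hops$frustrated), "accepted,",
      sum(x$hops$frustrated), "frustrated\n")
  cat("Final active state:", x$active_mch[length(x$active_mch)],
      sprintf("(diag %d)\n", x$active_diag[length(x$active_diag)]))
  drift <- max(abs(x$e_tot - x$e_tot[1]))
  cat(sprintf("Max |E_tot - E_tot(0)|: %.2e Hartree\n", drift))
  invisible(x)
}

#' Run an ensemble of surface-hopping trajectories
#'
#' Samples `n_traj` Wigner initial conditions and propagates each.  One
#' master seed streams independent per-trajectory sub-seeds for both the
#' initial-condition sampling and the hopping randomness, so the whole
#' ensemble (and any single member) is exactly reproducible.
#'
#' @param model an `sh_lvc_model`.
#' @param n_traj ensemble size (the reference protocol uses 100).
#' @param initial_state MCH label populated at t = 0.
#' @param params an `sh_params`.
#' @param seed master integer seed.
#' @return an object of class `sh_ensemble`: a list of `sh_trajectory`
#'   objects with attributes `model`, `seed` and `params`.
#' @export
run_ensemble <- function(model, n_traj = 100, initial_state = "S2",
                         params = propagation_params(), seed = 1L) {
  inits <- sample_wigner(model$modes, n_traj, initial_state, seed)
  set.seed(as.integer(seed))
  invisible(sample.int(.Machine$integer.max, n_traj))  # skip the wigner block
  traj_seeds <- sample.int(.Machine$integer.max, n_traj)
  trajs <- lapply(seq_len(n_traj), function(i) {
    p <- params
    p$rng_seed <- traj_seeds[i]
    propagate_trajectory(model, inits[[i]], p)
  })
  structure(trajs, class = "sh_ensemble", model = model, seed = seed,
            params = params)
}

#' @export
print.sh_ensemble <- function(x, ...) {
  nh <- sum(vapply(x, function(tr) sum(!tr$hops$frustrated), 0L))
  cat("Surface-hopping ensemble:", length(x), "trajectories,",
      sprintf("%.1f fs each, %d accepted hops total\n",
              max(x[[1]]$times), nh))
  invisible(x)
}

#' Fewest-switches hop decision from the step propagator
#'
#' Computes per-target hop probabilities for one classical step in the
#' local-diabatization formulation: the fractional decrease of the active
#' population over the step is apportioned among target states by the
#' propagator cross terms `Re(c_after[b] * Conj(P[b,a]) * Conj(c_before[a]))`,
#' with negative contributions clamped to zero.  All probabilities are zero
#' whenever the active population did not decrease.  A single uniform
#' variate is compared against the cumulative probabilities.
#'
#' @param c_before,c_after complex amplitude vectors at the step endpoints.
#' @param step_propagator complex unitary matrix `P` with
#'   `c_after = P %*% c_before`.
#' @param active index (1-based) of the active state.
#' @param rand uniform variate in `[0, 1)`; drawn from the session RNG when
#'   `NULL`.
#' @return a list with `target` (integer index of the selected state, or
#'   `NA` for no hop) and `probabilities` (numeric vector, zero at the
#'   active index, sum <= 1).
#' @export
hop_decision <- function(c_before, c_after, step_propagator, active,
                         rand = NULL) {
  probs <- as.numeric(sh_hop_probs_cpp(as.complex(c_before),
                                       as.complex(c_after),
                                       step_propagator, as.integer(active)))
  if (is.null(rand)) rand <- stats::runif(1)
  cum <- cumsum(probs)
  hit <- which(rand < cum)
  list(target = if (length(hit)) hit[1] else NA_integer_,
       probabilities = probs)
}

#' Energy-based decoherence correction
#'
#' Damps each non-active amplitude by `exp(-dt / tau_k)` with
#' `tau_k = (hbar / |E_k - E_active|) * (1 + C / e_kin)` and rescales the
#' active amplitude so the total population is exactly one; all relative
#' phases are preserved.  All quantities in Hartree atomic units
#' (hbar = 1).  When `e_kin <= 0` the correction is skipped and the input
#' returned unchanged (the propagator logs such skips).
#'
#' @param amplitudes complex amplitude vector (diagonal basis).
#' @param diag_energies per-state energies (Hartree).
#' @param active 1-based active-state index.
#' @param e_kin nuclear kinetic energy (Hartree).
#' @param C decoherence parameter (Hartree); default 0.1.
#' @param dt time interval (atomic units).
#' @return corrected complex amplitude vector with unit total population.
#' @export
apply_decoherence <- function(amplitudes, diag_energies, active, e_kin,
                              C = 0.1, dt) {
  as.complex(sh_decoherence_cpp(as.complex(amplitudes),
                                as.numeric(diag_energies),
                                as.integer(active), e_kin, C, dt))
}

#' Momentum rescaling at a surface hop
#'
#' Rescales the full momentum vector uniformly so the kinetic energy change
#' exactly balances the potential gap: `p' = p * sqrt(1 - e_gap / e_kin)`
#' when `e_kin >= e_gap`.  Otherwise the hop is frustrated and the momentum
#' is left unchanged (`policy = "continue"`) or negated
#' (`policy = "reflect"`).  Kinetic energy is
#' `sum(omega * p^2) / 2` in the dimensionless mode coordinates.
#'
#' @param p momentum vector (dimensionless).
#' @param e_gap potential-energy gap `E_new - E_old` (Hartree).
#' @param omega mode frequencies (Hartree); defaults to 1 for every mode.
#' @param policy `"continue"` or `"reflect"` for frustrated hops.
#' @return list with `p` (new momentum) and `frustrated` (logical).
#' @export
rescale_momentum <- function(p, e_gap, omega = rep(1, length(p)),
                             policy = c("continue", "reflect")) {
  policy <- match.arg(policy)
  e_kin <- 0.5 * sum(omega * p^2)
  if (e_kin >= e_gap && (e_kin > 0 || e_gap == 0)) {
    fac <- if (e_kin > 0) sqrt(1 - e_gap / e_kin) else 1
    list(p = p * fac, frustrated = FALSE)
  } else {
    list(p = if (policy == "reflect") -p else p, frustrated = TRUE)
  }
}
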