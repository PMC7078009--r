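#' Electronic population time series of an ensemble
#'
#' Fractions of the ensemble in each electronic state on a common time
#' grid, in one of three pictures: the active spin-mixed surface
#' (`"diagonal_active"`, labels `D1..Dn` in ascending energy order), the
#' MCH parent of the active surface (`"mch_active"`), or the ensemble mean
#' of the MCH-projected quantum amplitude populations
#' (`"quantum_amplitude"`).
#'
#' @param ensemble an `sh_ensemble` or plain list of `sh_trajectory`.
#' @param basis population picture (see above).
#' @param grid time grid in fs; defaults to the frame times of the first
#'   trajectory.  Every grid point must coincide with a stored frame of
#'   every trajectory.
#' @return an object of class `sh_population_series`: `times`,
#'   `populations` (times x labels matrix, rows summing to one), `basis`,
#'   `n_traj`.
#' @export
compute_populations <- function(ensemble,
                                basis = c("mch_active", "diagonal_active",
                                          "quantum_amplitude"),
                                grid = NULL) {
  basis <- match.arg(basis)
  if (length(ensemble) == 0) stop("compute_populations: empty ensemble")
  if (is.null(grid)) grid <- ensemble[[1]]$times
  idx_list <- lapply(seq_along(ensemble), function(i) {
    ii <- match(round(grid, 9), round(ensemble[[i]]$times, 9))
    if (anyNA(ii)) return(NA_integer_)
    ii
  })
  bad <- which(vapply(idx_list, function(x) anyNA(x), TRUE))
  if (length(bad))
    stop("compute_populations: trajectories not covering the grid: ",
         paste(bad, collapse = ", "))
  labels <- if (basis == "diagonal_active") {
    paste0("D", seq_along(ensemble[[1]]$state_labels))
  } else {
    unique(ensemble[[1]]$state_labels)
  }
  pop <- matrix(0, length(grid), length(labels),
                dimnames = list(NULL, labels))
  for (i in seq_along(ensemble)) {
    tr <- ensemble[[i]]
    ii <- idx_list[[i]]
    if (basis == "diagonal_active") {
      lab <- paste0("D", tr$active_diag[ii])
      for (k in seq_along(grid)) pop[k, lab[k]] <- pop[k, lab[k]] + 1
    } else if (basis == "mch_active") {
      lab <- tr$active_mch[ii]
      for (k in seq_along(grid)) pop[k, lab[k]] <- pop[k, lab[k]] + 1
    } else {
      # collapse expanded components onto their parent labels
      for (l in labels) {
        cols <- which(tr$state_labels == l)
        pop[, l] <- pop[, l] + rowSums(tr$pop_mch[ii, cols, drop = FALSE])
      }
    }
  }
  pop <- pop / length(ensemble)
  # clamp floating-point noise from the amplitude transformation
  pop[pop < 0 & pop > -1e-9] <- 0
  pop[pop > 1 & pop < 1 + 1e-9] <- 1
  structure(list(times = grid, populations = pop, basis = basis,
                 n_traj = length(ensemble)),
            class = "sh_population_series")
}

#' Build a population series directly from matrices
#'
#' Convenience constructor used for external or synthetic population data
#' (e.g. kinetic-model output or hand-built fixtures).
#'
#' @param times time grid (fs).
#' @param populations times x labels matrix with named columns.
#' @param basis free-form tag describing the picture.
#' @param n_traj ensemble size behind the fractions (NA when not
#'   applicable).
#' @return an `sh_population_series`.
#' @export
population_series <- function(times, populations, basis = "external",
                              n_traj = NA_integer_) {
  populations <- as.matrix(populations)
  stopifnot(length(times) == nrow(populations),
            !is.null(colnames(populations)))
  structure(list(times = times, populations = populations, basis = basis,
                 n_traj = n_traj), class = "sh_population_series")
}

#' @export
print.sh_population_series <- function(x, ...) {
  cat("Population series (", x$basis, "): ", length(x$times),
      " times, states ", paste(colnames(x$populations), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Count surface hops of an ensemble
#'
#' Tallies all accepted (non-frustrated) surface hops across the ensemble
#' into a from-state x to-state matrix.  The full matrix is always stored;
#' the rendered report (see [format_hop_matrix()] and the print method)
#' suppresses entries below `report_threshold` and can emphasize a main
#' pathway.
#'
#' @param ensemble an `sh_ensemble` or list of `sh_trajectory`.
#' @param label_basis `"mch"` (hops labeled by the MCH parent of the
#'   diagonal states, the convention of the reference analysis) or
#'   `"diagonal"`.
#' @param report_threshold minimum count shown in rendered reports
#'   (default 10).
#' @return an object of class `sh_hop_matrix` with integer `counts` and
#'   `report_threshold`.
#' @export
count_hops <- function(ensemble, label_basis = c("mch", "diagonal"),
                       report_threshold = 10L) {
  label_basis <- match.arg(label_basis)
  if (label_basis == "mch") {
    labels <- unique(ensemble[[1]]$state_labels)
  } else {
    labels <- paste0("D", seq_along(ensemble[[1]]$state_labels))
  }
  counts <- matrix(0L, length(labels), length(labels),
                   dimnames = list(from = labels, to = labels))
  for (tr in ensemble) {
    h <- tr$hops[!tr$hops$frustrated, , drop = FALSE]
    if (nrow(h) == 0) next
    if (label_basis == "mch") {
      from <- h$from_mch; to <- h$to_mch
    } else {
      from <- paste0("D", h$from_diag); to <- paste0("D", h$to_diag)
    }
    keep <- from != to  # diagonal entries stay zero by construction
    for (j in which(keep)) counts[from[j], to[j]] <- counts[from[j], to[j]] + 1L
  }
  structure(list(counts = counts, report_threshold = as.integer(report_threshold),
                 label_basis = label_basis),
            class = "sh_hop_matrix")
}

#' Render a hop-count matrix for reporting
#'
#' Returns a character matrix in which counts below the report threshold
#' are blanked and transitions in `main_pathway` (a character vector of
#' `"A->B"` strings) are wrapped in asterisks.  The stored numeric matrix
#' is never modified.
#'
#' @param x an `sh_hop_matrix`.
#' @param threshold suppression threshold; defaults to the stored one.
#' @param main_pathway character vector of emphasized transitions, e.g.
#'   `c("S2->S1", "S1->T2", "T2->T1")`.
#' @return character matrix with the same dimnames as `x$counts`.
#' @export
format_hop_matrix <- function(x, threshold = NULL,
                              main_pathway = c("S2->S1", "S1->T2", "T2->T1")) {
  threshold <- threshold %||% x$report_threshold
  cc <- x$counts
  out <- matrix("", nrow(cc), ncol(cc), dimnames = dimnames(cc))
  for (i in seq_len(nrow(cc))) for (j in seq_len(ncol(cc))) {
    if (i == j || cc[i, j] < threshold) next
    key <- paste0(rownames(cc)[i], "->", colnames(cc)[j])
    out[i, j] <- if (key %in% main_pathway) paste0("*", cc[i, j], "*")
                 else as.character(cc[i, j])
  }
  out
}

#' @export
print.sh_hop_matrix <- function(x, ...) {
  cat("Surface-hop counts (", x$label_basis,
      " labels; entries < ", x$report_threshold, " suppressed, ",
      "main pathway in *..*):\n", sep = "")
  print(format_hop_matrix(x), quote = FALSE)
  invisible(x)
}

#' Default nine-rate reaction network
#'
#' The kinetic network used for the reference system: main forward chain
#' S2 -> S1 -> T2 -> T1, the corresponding backward transitions, and three
#' minority forward channels S2 -> S1', S1' -> S0 and S2 -> T2.  The S1'
#' species separates trajectories that leave S1 by internal conversion to
#' S0 from those that undergo intersystem crossing; for fitting purposes
#' the split is implemented in the decay from S2, and S1' is unobservable
#' (reported inside S1).
#'
#' @return data frame with columns `from`, `to`.
#' @export
default_reaction_network <- function() {
  data.frame(
    from = c("S2", "S1", "T2", "S1", "T2", "T1", "S2", "S1p", "S2"),
    to   = c("S1", "T2", "T1", "S2", "S1", "T2", "S1p", "S0", "T2"),
    stringsAsFactors = FALSE
  )
}

#' Define a first-order kinetic model
#'
#' A reaction network of unimolecular transitions with mass-action rate
#' constants, solved as the linear ODE system `dP/dt = K P`.
#'
#' @param rates named numeric vector of rate constants in fs^-1; names are
#'   `"from->to"` strings matching `reactions`, or unnamed in the row order
#'   of `reactions`.
#' @param reactions data frame with columns `from`, `to`; defaults to
#'   [default_reaction_network()].
#' @param initial named vector of initial populations (unnamed species are
#'   0); must sum to one.  Default: all population in S2.
#' @return an object of class `sh_kinetic_model`.
#' @export
kinetic_model <- function(rates, reactions = default_reaction_network(),
                          initial = c(S2 = 1)) {
  species <- unique(c(reactions$from, reactions$to, names(initial)))
  keys <- paste0(reactions$from, "->", reactions$to)
  if (is.null(names(rates))) {
    if (length(rates) != nrow(reactions))
      stop("kinetic_model: unnamed rates must match the reaction list")
    names(rates) <- keys
  }
  if (!all(names(rates) %in% keys))
    stop("kinetic_model: unknown reaction in rates: ",
         paste(setdiff(names(rates), keys), collapse = ", "))
  rates <- rates[keys]
  names(rates) <- keys
  rates[is.na(rates)] <- 0
  if (any(rates < 0)) stop("kinetic_model: negative rates are not allowed")
  p0 <- stats::setNames(numeric(length(species)), species)
  p0[names(initial)] <- initial
  if (abs(sum(p0) - 1) > 1e-9)
    stop("kinetic_model: initial populations must sum to 1")
  structure(list(species = species, reactions = reactions,
                 rates = rates, initial = p0),
            class = "sh_kinetic_model")
}

# Rate matrix K (fs^-1) with columns as source species: dP/dt = K %*% P
rate_matrix <- function(model) {
  sp <- model$species
  K <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (r in seq_len(nrow(model$reactions))) {
    from <- model$reactions$from[r]
    to <- model$reactions$to[r]
    k <- model$rates[r]
    K[to, from] <- K[to, from] + k
    K[from, from] <- K[from, from] - k
  }
  K
}

#' Integrate a kinetic model on a time grid
#'
#' Solves `dP/dt = K P` exactly by eigendecomposition of the rate matrix
#' (with a stiff `deSolve::lsoda` fallback when the eigenbasis is
#' ill-conditioned).  Total population is conserved by construction.
#'
#' @param model an `sh_kinetic_model`.
#' @param grid time grid in fs.
#' @param observable when `TRUE` (default) the unobservable S1' species is
#'   reported inside S1; set `FALSE` to obtain the latent species.
#' @return an `sh_population_series` on `grid`.
#' @export
simulate_kinetics <- function(model, grid, observable = TRUE) {
  stopifnot(inherits(model, "sh_kinetic_model"))
  K <- rate_matrix(model)
  p0 <- model$initial
  eg <- eigen(K)
  P <- NULL
  sv <- svd(eg$vectors, nu = 0, nv = 0)$d
  if (min(sv) / max(sv) > 1e-10) {
    coef <- solve(eg$vectors, p0)
    E <- exp(outer(grid, eg$values))        # times x eigenmodes
    P <- Re(E %*% (coef * t(eg$vectors)))   # times x species
  }
  if (is.null(P) || anyNA(P)) {
    rhs <- function(t, y, parms) list(as.numeric(K %*% y))
    sol <- deSolve::lsoda(p0, grid, rhs, NULL, rtol = 1e-12, atol = 1e-12)
    P <- sol[, -1, drop = FALSE]
  }
  colnames(P) <- model$species
  P[P < 0 & P > -1e-12] <- 0
  if (observable && "S1p" %in% colnames(P)) {
    P[, "S1"] <- P[, "S1"] + P[, "S1p"]
    P <- P[, setdiff(colnames(P), "S1p"), drop = FALSE]
  }
  population_series(grid, P, basis = "kinetic_model")
}

# Sum-of-squares residual vector between a kinetic model (given rates) and
# an observed population series, over the species shared by both.
kin_residual <- function(rates, template, data) {
  m <- template
  m$rates[] <- rates
  sim <- simulate_kinetics(m, data$times, observable = TRUE)
  sp <- intersect(colnames(sim$populations), colnames(data$populations))
  # tiny ridge term: pulls rates that the data cannot identify (sources
  # never populated) to zero without biasing identified rates measurably
  c(as.numeric(sim$populations[, sp] - data$populations[, sp]),
    1e-4 * rates)
}

#' Fit a kinetic model to population data
#'
#' Nonnegative bounded least squares of all observable species
#' simultaneously (equal weights) using Levenberg--Marquardt
#' (`minpack.lm::nls.lm`) with multi-start over log-uniform initial
#' guesses.  The best start by residual sum of squares is returned.
#'
#' @param data an `sh_population_series` whose column labels cover at least
#'   two of the model species.
#' @param network an `sh_kinetic_model` template supplying the reaction
#'   topology and initial populations (its rates are ignored).
#' @param options list: `n_starts` (default 8), `seed` (default 1),
#'   `lower`/`upper` rate bounds in fs^-1 (defaults 0 and 1),
#'   `guess_range` for the log-uniform starts (default `c(1e-5, 1e-1)`),
#'   `extra_starts` optional list of explicit start vectors.
#' @return an object of class `sh_kinetic_fit`: `parameters` (data frame
#'   with estimate, asymptotic standard error and 95% CI per rate),
#'   `residual` (SSE), `model_populations` (fitted series),
#'   `converged`, `model` (the fitted `sh_kinetic_model`), and `starts`
#'   (log of all starts with their SSE).
#' @export
fit_kinetic_model <- function(data, network = NULL, options = list()) {
  if (is.null(network)) network <- kinetic_model(rep(0.01, 9))
  opts <- utils::modifyList(list(n_starts = 8, seed = 1, lower = 0, upper = 1,
                                 guess_range = c(1e-5, 1e-1),
                                 extra_starts = list()), options)
  sp_obs <- intersect(setdiff(network$species, "S1p"),
                      colnames(data$populations))
  if (length(sp_obs) < 2)
    stop("fit_kinetic_model: data must cover >= 2 model species")
  nk <- length(network$rates)
  set.seed(as.integer(opts$seed))
  lg <- log(opts$guess_range)
  starts <- lapply(seq_len(opts$n_starts), function(i)
    exp(stats::runif(nk, lg[1], lg[2])))
  starts <- c(starts, opts$extra_starts)
  runs <- lapply(starts, function(st) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = rep(opts$lower, nk), upper = rep(opts$upper, nk),
        fn = kin_residual, template = network, data = data,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    fit
  })
  ok <- !vapply(runs, is.null, TRUE)
  if (!any(ok)) {
    return(structure(list(parameters = NULL, residual = Inf,
                          model_populations = NULL, converged = FALSE,
                          model = network,
                          starts = starts,
                          diagnostics = "all starts failed"),
                     class = "sh_kinetic_fit"))
  }
  sse <- vapply(runs, function(f) if (is.null(f)) Inf else sum(f$fvec^2), 0)
  best <- runs[[which.min(sse)]]
  est <- stats::setNames(as.numeric(best$par), names(network$rates))
  # prune rates the data cannot identify (e.g. flow out of species that are
  # never populated): zeroing them must not change the data-only SSE
  data_sse <- function(k) {
    mloc <- network
    mloc$rates[] <- k
    sim <- simulate_kinetics(mloc, data$times, observable = TRUE)
    sp <- intersect(colnames(sim$populations), colnames(data$populations))
    sum((sim$populations[, sp] - data$populations[, sp])^2)
  }
  sse_best <- data_sse(est)
  for (j in order(est)) {
    if (est[j] == 0) next
    trial <- est
    trial[j] <- 0
    if (data_sse(trial) <= sse_best * (1 + 1e-9) + 1e-14) {
      est <- trial
      sse_best <- data_sse(est)
    }
  }
  se <- rep(NA_real_, nk)
  vc <- tryCatch(stats::vcov(best), error = function(e) NULL)
  if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  fitted_model <- network
  fitted_model$rates[] <- est
  sim <- simulate_kinetics(fitted_model, data$times, observable = TRUE)
  resid_out <- sse_best
  structure(list(
    parameters = data.frame(
      rate = names(network$rates), estimate = est, se = se,
      ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
      row.names = NULL),
    residual = resid_out,
    model_populations = sim,
    converged = isTRUE(best$info %in% 1:4),
    model = fitted_model,
    starts = data.frame(start = seq_along(starts), sse = sse)
  ), class = "sh_kinetic_fit")
}

#' @export
print.sh_kinetic_fit <- function(x, ...) {
  cat("Kinetic model fit: SSE =", format(x$residual, digits = 6),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  if (!is.null(x$parameters)) {
    df <- x$parameters
    df$estimate <- signif(df$estimate, 5)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Single-exponential lifetime fit of a manifold population
#'
#' Sums the populations of a manifold (e.g. the three singlet states),
#' fits `P(t) = exp(-t / tau)` by least squares with `tau > 0`, and, when
#' the per-trajectory ensemble is supplied, attaches a bootstrap standard
#' error obtained by resampling trajectories.
#'
#' @param data an `sh_population_series` containing the manifold labels.
#' @param manifold character vector of state labels; default the singlet
#'   manifold `c("S0", "S1", "S2")`.
#' @param ensemble optional `sh_ensemble` (or list of trajectories) behind
#'   `data`, used for the bootstrap.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed seed for the bootstrap resampling.
#' @return an object of class `sh_exp_fit`: `tau_fs`, `se_tau_fs`,
#'   `residual` (SSE), `model_populations`, `converged`.
#' @export
fit_exponential_manifold <- function(data, manifold = c("S0", "S1", "S2"),
                                     ensemble = NULL, n_boot = 200,
                                     seed = 1L) {
  present <- intersect(manifold, colnames(data$populations))
  if (length(present) == 0)
    stop("fit_exponential_manifold: no manifold label present in data")
  s <- rowSums(data$populations[, present, drop = FALSE])
  fit1 <- fit_exp_tau(data$times, s)
  se <- NA_real_
  if (!is.null(ensemble) && fit1$converged) {
    set.seed(as.integer(seed))
    basis <- if (inherits(data, "sh_population_series") &&
                 data$basis %in% c("mch_active", "diagonal_active",
                                   "quantum_amplitude")) data$basis
             else "mch_active"
    taus <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(seq_along(ensemble), replace = TRUE)
      ps <- compute_populations(ensemble[pick], basis = basis,
                                grid = data$times)
      pres <- intersect(manifold, colnames(ps$populations))
      sb <- rowSums(ps$populations[, pres, drop = FALSE])
      fb <- fit_exp_tau(data$times, sb)
      if (fb$converged) fb$tau else NA_real_
    }, 0)
    se <- stats::sd(taus, na.rm = TRUE)
  }
  structure(list(
    tau_fs = fit1$tau, se_tau_fs = se, residual = fit1$sse,
    model_populations = population_series(
      data$times,
      matrix(exp(-data$times / fit1$tau), ncol = 1,
             dimnames = list(NULL, "manifold")),
      basis = "exponential_fit"),
    converged = fit1$converged
  ), class = "sh_exp_fit")
}

# 1-D least-squares fit of s(t) ~ exp(-t/tau) over log10(tau)
fit_exp_tau <- function(times, s) {
  sse <- function(lt) sum((exp(-times / 10^lt) - s)^2)
  opt <- stats::optimize(sse, interval = c(-2, 9), tol = 1e-12)
  tau <- 10^opt$minimum
  # non-decaying input: the optimizer runs to the upper bound
  converged <- opt$minimum < 8.5 && s[length(s)] < 0.999 * s[1]
  list(tau = tau, sse = opt$objective, converged = converged)
}

#' @export
print.sh_exp_fit <- function(x, ...) {
  cat(sprintf("Exponential manifold fit: tau = %.1f fs (SE %.1f), SSE = %.4g%s\n",
              x$tau_fs, x$se_tau_fs, x$residual,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Mean time of the first occurrence of a specific hop
#'
#' Averages, over trajectories, the time of the first accepted hop from
#' `from_label` to `to_label` (MCH labels).  Trajectories without such a
#' hop are excluded and counted.
#'
#' @param ensemble an `sh_ensemble` or list of `sh_trajectory`.
#' @param from_label,to_label MCH state labels.
#' @return list with `mean_fs` (NA when no trajectory qualifies), `n`
#'   (qualifying trajectories), `n_excluded`, and `defined` (logical).
#' @export
mean_first_hop_time <- function(ensemble, from_label, to_label) {
  tt <- vapply(ensemble, function(tr) {
    h <- tr$hops
    sel <- !h$frustrated & h$from_mch == from_label & h$to_mch == to_label
    if (any(sel)) min(h$t[sel]) else NA_real_
  }, 0)
  n <- sum(!is.na(tt))
  list(mean_fs = if (n > 0) mean(tt, na.rm = TRUE) else NA_real_,
       n = n, n_excluded = length(tt) - n, defined = n > 0)
}

#' Build a scripted trajectory fixture
#'
#' Constructs a minimal `sh_trajectory` whose active-state history and hop
#' list are specified by hand.  Used for hand-checkable fixtures in the
#' analysis pipeline (populations, hop matrices, first-hop times) and for
#' reading externally produced ensembles.
#'
#' @param times frame times (fs), strictly increasing.
#' @param active character vector of MCH labels per frame.
#' @param hops data frame with columns `t`, `from_mch`, `to_mch` and
#'   optionally `frustrated` (default all `FALSE`); hop times must lie on
#'   frame boundaries.
#' @param state_labels full state-label set (default the five-state set).
#' @param q optional frames x modes coordinate matrix.
#' @param n_modes number of (zero) mode coordinates when `q` is omitted.
#' @return an `sh_trajectory` (with amplitude populations concentrated on
#'   the active state).
#' @export
scripted_trajectory <- function(times, active,
                                hops = data.frame(t = numeric(),
                                                  from_mch = character(),
                                                  to_mch = character()),
                                state_labels = c("S0", "S1", "S2", "T1", "T2"),
                                q = NULL, n_modes = 1L) {
  stopifnot(length(times) == length(active), all(diff(times) > 0))
  if (is.null(hops$frustrated)) hops$frustrated <- rep(FALSE, nrow(hops))
  if (nrow(hops) && !all(round(hops$t, 9) %in% round(times, 9)))
    stop("scripted_trajectory: hop times must coincide with frame times")
  hops$step <- match(round(hops$t, 9), round(times, 9)) - 1L
  hops$from_diag <- match(hops$from_mch, state_labels)
  hops$to_diag <- match(hops$to_mch, state_labels)
  hops$gap_eV <- rep(0, nrow(hops))
  nS <- length(state_labels)
  ai <- match(active, state_labels)
  pop <- matrix(0, length(times), nS, dimnames = list(NULL, state_labels))
  pop[cbind(seq_along(times), ai)] <- 1
  if (is.null(q)) q <- matrix(0, length(times), n_modes)
  structure(list(
    times = times, q = q, p = q * 0,
    e_diag = matrix(0, length(times), nS),
    e_mch = matrix(0, length(times), nS),
    amplitudes = pop * (1 + 0i),
    pop_mch = pop,
    active_diag = ai,
    active_mch = active,
    e_kin = rep(0, length(times)), e_pot = rep(0, length(times)),
    e_tot = rep(0, length(times)),
    hops = hops,
    params = propagation_params(dt = min(diff(times)),
                                t_max = max(times)),
    init = list(initial_state = active[1], seed = NA_integer_),
    state_labels = state_labels,
    warnings = list(n_track_fail = 0L, n_decoherence_skipped = 0L,
                    n_frustrated = sum(hops$frustrated))
  ), class = "sh_trajectory")
}
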