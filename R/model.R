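#' Construct a normal mode
#'
#' A harmonic normal mode of the electronic ground state.  The displacement
#' vector (one 3-vector per atom, dimensionless) is renormalized to unit
#' Euclidean norm; it is only required when Cartesian reconstruction
#' (bond lengths, mode projections of external geometries) is wanted.
#'
#' @param frequency_cm1 harmonic frequency in cm^-1 (must be > 0).
#' @param character `"in_plane"` or `"out_of_plane"`.
#' @param index integer mode label (as in frequency-analysis output).
#' @param reduced_mass_amu reduced mass in unified atomic mass units.
#' @param displacement optional natoms x 3 numeric matrix of Cartesian
#'   displacements (any overall scale; renormalized internally).
#' @return an object of class `sh_mode` with the frequency stored both in
#'   cm^-1 and Hartree (`omega`).
#' @export
normal_mode <- function(frequency_cm1, character = c("in_plane", "out_of_plane"),
                        index = NA_integer_, reduced_mass_amu = 1,
                        displacement = NULL) {
  character <- match.arg(character)
  if (!is.finite(frequency_cm1) || frequency_cm1 <= 0)
    stop("normal_mode: frequency must be finite and > 0")
  if (!is.null(displacement)) {
    displacement <- as.matrix(displacement)
    if (ncol(displacement) != 3)
      stop("normal_mode: displacement must be an natoms x 3 matrix")
    nrm <- sqrt(sum(displacement^2))
    if (nrm == 0) stop("normal_mode: zero-norm displacement vector")
    displacement <- displacement / nrm
  }
  structure(list(
    index = as.integer(index),
    frequency_cm1 = frequency_cm1,
    omega = cm1_to_hartree(frequency_cm1),
    character = character,
    reduced_mass_amu = reduced_mass_amu,
    displacement = displacement
  ), class = "sh_mode")
}

#' Build a linear vibronic coupling (LVC) model
#'
#' Assembles the analytic multi-state Hamiltonian used as electronic
#' structure throughout the package: harmonic diagonal potentials shifted
#' linearly by intrastate gradients `kappa`, linear interstate couplings
#' `lambda` within each spin multiplicity, and constant spin--orbit
#' couplings `soc` between singlet and triplet states.
#'
#' @param config a list with elements:
#' \describe{
#'   \item{states}{named integer vector of spin multiplicities, e.g.
#'     `c(S0 = 1, S1 = 1, S2 = 1, T1 = 3, T2 = 3)`.}
#'   \item{energies_eV}{named numeric vector of vertical energies at the
#'     Franck--Condon origin.}
#'   \item{modes}{list of `sh_mode` objects (or lists accepted by
#'     [normal_mode()]).}
#'   \item{kappa_eV}{optional states x modes matrix of intrastate gradients
#'     (eV per unit dimensionless coordinate); missing rows/entries are 0.}
#'   \item{lambda_eV}{optional list of entries
#'     `list(states = c("A","B"), mode = i, value = v)` (eV per unit q);
#'     states must share multiplicity.}
#'   \item{soc_eV}{optional list of entries
#'     `list(states = c("S","T"), value = v)` with constant coupling in eV
#'     (complex allowed); states must differ in multiplicity.}
#'   \item{triplet_components}{1 (default, scalar effective coupling) or 3
#'     (three degenerate sublevels per triplet, each sharing the SOC
#'     constant).}
#'   \item{geometry}{optional reference geometry,
#'     `list(atoms = <labels>, elements = <symbols>, coords = natoms x 3
#'     matrix in Angstrom)`.}
#'   \item{meta}{optional free-form metadata (e.g. orbital characters,
#'     perturbation-corrected energies), stored unmodified.}
#' }
#' @return an object of class `sh_lvc_model`.
#' @export
build_lvc_model <- function(config) {
  if (is.null(config$states) || length(config$states) < 2)
    stop("build_lvc_model: config must name at least 2 states")
  if (is.null(config$modes) || length(config$modes) < 1)
    stop("build_lvc_model: config must define at least 1 mode")
  states <- names(config$states)
  mult <- as.integer(config$states)
  if (any(is.na(states)) || is.null(states))
    stop("build_lvc_model: states must be a named multiplicity vector")
  nS <- length(states)

  e <- config$energies_eV
  if (!all(states %in% names(e)))
    stop("build_lvc_model: energies_eV must cover all states")
  e <- e[states]
  if (!all(is.finite(e))) stop("build_lvc_model: energies must be finite")

  modes <- lapply(config$modes, function(m) {
    if (inherits(m, "sh_mode")) m else do.call(normal_mode, m)
  })
  nM <- length(modes)

  kappa <- matrix(0, nS, nM, dimnames = list(states, NULL))
  if (!is.null(config$kappa_eV)) {
    km <- as.matrix(config$kappa_eV)
    if (is.null(rownames(km))) {
      if (nrow(km) != nS) stop("build_lvc_model: kappa_eV has wrong shape")
      rownames(km) <- states
    }
    if (ncol(km) != nM) stop("build_lvc_model: kappa_eV has wrong shape")
    kappa[rownames(km), ] <- km
  }

  lambda <- array(0, c(nS, nM, nS), dimnames = list(states, NULL, states))
  lambda <- aperm(lambda, c(1, 3, 2))  # nS x nS x nM
  for (entry in config$lambda_eV %||% list()) {
    ab <- match(entry$states, states)
    if (anyNA(ab)) stop("build_lvc_model: unknown state in lambda_eV")
    if (ab[1] == ab[2]) stop("build_lvc_model: lambda must couple two distinct states (use kappa for intrastate gradients)")
    if (mult[ab[1]] != mult[ab[2]])
      stop("build_lvc_model: lambda couples states of different multiplicity; use soc_eV")
    i <- entry$mode
    if (i < 1 || i > nM) stop("build_lvc_model: lambda mode index out of range")
    old <- lambda[ab[1], ab[2], i]
    if (old != 0 && old != entry$value)
      stop("build_lvc_model: conflicting (non-Hermitian) lambda specification")
    lambda[ab[1], ab[2], i] <- entry$value
    lambda[ab[2], ab[1], i] <- entry$value
  }

  soc <- matrix(0 + 0i, nS, nS, dimnames = list(states, states))
  for (entry in config$soc_eV %||% list()) {
    ab <- match(entry$states, states)
    if (anyNA(ab)) stop("build_lvc_model: unknown state in soc_eV")
    if (mult[ab[1]] == mult[ab[2]])
      stop("build_lvc_model: SOC between states of the same multiplicity is not allowed")
    v <- as.complex(entry$value)
    old <- soc[ab[1], ab[2]]
    if (old != 0 && old != v)
      stop("build_lvc_model: conflicting (non-Hermitian) SOC specification")
    soc[ab[1], ab[2]] <- v
    soc[ab[2], ab[1]] <- Conj(v)
  }

  tc <- config$triplet_components %||% 1L
  if (!tc %in% c(1L, 3L))
    stop("build_lvc_model: triplet_components must be 1 or 3")

  model <- structure(list(
    states = states,
    multiplicities = mult,
    energies_eV = as.numeric(e),
    energies = ev_to_hartree(as.numeric(e)),
    modes = modes,
    kappa = ev_to_hartree(kappa),
    lambda = ev_to_hartree(lambda),
    soc = ev_to_hartree(soc),
    triplet_components = as.integer(tc),
    geometry = config$geometry,
    meta = config$meta
  ), class = "sh_lvc_model")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sh_lvc_model <- function(x, ...) {
  cat("LVC model:", length(x$states), "states (",
      paste0(x$states, "[", x$multiplicities, "]", collapse = " "),
      "),", length(x$modes), "modes\n")
  cat("Vertical energies (eV):",
      paste(sprintf("%s=%.3f", x$states, x$energies_eV), collapse = " "), "\n")
  cat("Mode frequencies (cm^-1):",
      paste(sprintf("%.0f", vapply(x$modes, `[[`, 0, "frequency_cm1")),
            collapse = " "), "\n")
  cat("triplet_components:", x$triplet_components, "\n")
  invisible(x)
}

# Expanded numeric arrays for the C++ core, with triplet sublevels
# replicated when triplet_components == 3.  Returns atomic-unit arrays plus
# the map from expanded component index back to the parent state label.
model_pack <- function(model) {
  nS <- length(model$states)
  tc <- model$triplet_components
  ncomp <- ifelse(tc == 3L & model$multiplicities > 1, 3L, 1L)
  idx <- rep(seq_len(nS), ncomp)
  comp <- unlist(lapply(ncomp, seq_len))
  ne <- length(idx)
  lam <- array(0, c(ne, ne, length(model$modes)))
  soc <- matrix(0 + 0i, ne, ne)
  for (a in seq_len(ne)) for (b in seq_len(ne)) {
    pa <- idx[a]; pb <- idx[b]
    if (model$multiplicities[pa] == model$multiplicities[pb]) {
      # lambda acts within a spin sublevel (diagonal in the spin projection)
      if (comp[a] == comp[b]) lam[a, b, ] <- model$lambda[pa, pb, ]
    } else {
      soc[a, b] <- model$soc[pa, pb]
    }
  }
  list(
    eps = model$energies[idx],
    omega = vapply(model$modes, `[[`, 0, "omega"),
    kappa = model$kappa[idx, , drop = FALSE],
    lambda = lam,
    soc = soc,
    parent = idx,
    labels = model$states[idx]
  )
}

#' Evaluate the electronic structure at a geometry
#'
#' Assembles the MCH (spin-pure) potential matrix at the dimensionless mode
#' coordinates `q`, diagonalizes the full spin--orbit-including Hamiltonian
#' into the spin-mixed ("diagonal") basis, and returns energies, the
#' MCH-to-diagonal transformation and analytic (Hellmann--Feynman)
#' gradients.
#'
#' @param model an `sh_lvc_model`.
#' @param q numeric vector of dimensionless mode coordinates, one per mode.
#' @return an object of class `sh_elstruct` with elements `h_mch` (complex
#'   matrix, eV), `mch_energies`, `diag_energies` (eV, ascending),
#'   `transform` (unitary, columns = diagonal states in the MCH basis),
#'   `grad_diag` and `grad_mch` (eV per unit q), and `labels` (MCH parent
#'   label of each expanded component).
#' @export
evaluate_electronic <- function(model, q) {
  stopifnot(inherits(model, "sh_lvc_model"))
  q <- as.numeric(q)
  if (length(q) != length(model$modes))
    stop("evaluate_electronic: q must have one value per mode")
  if (!all(is.finite(q)))
    stop("evaluate_electronic: q contains NaN/Inf")
  pk <- model_pack(model)
  out <- sh_eval_cpp(pk$eps, pk$omega, pk$kappa, pk$lambda, pk$soc, q)
  structure(list(
    h_mch = hartree_to_ev(out$h_mch),
    mch_energies = hartree_to_ev(as.numeric(out$mch_energies)),
    diag_energies = hartree_to_ev(as.numeric(out$diag_energies)),
    transform = out$transform,
    grad_diag = hartree_to_ev(out$grad_diag),
    grad_mch = hartree_to_ev(out$grad_mch),
    labels = pk$labels,
    q = q
  ), class = "sh_elstruct")
}

#' @export
print.sh_elstruct <- function(x, ...) {
  cat("Electronic structure at q = (",
      paste(sprintf("%.3f", x$q), collapse = ", "), ")\n")
  cat("MCH energies (eV): ", paste(sprintf("%.4f", x$mch_energies),
                                   collapse = " "), "\n")
  cat("Diagonal energies (eV):", paste(sprintf("%.4f", x$diag_energies),
                                       collapse = " "), "\n")
  invisible(x)
}

#' MCH parent of each diagonal state
#'
#' For each spin-mixed eigenstate, the MCH state contributing the largest
#' weight `|U[n, k]|^2`, used for population bookkeeping in the MCH picture.
#'
#' @param elstruct an `sh_elstruct` from [evaluate_electronic()].
#' @return character vector of MCH labels, one per diagonal state.
#' @export
mch_parent_labels <- function(elstruct) {
  U <- elstruct$transform
  elstruct$labels[apply(Mod(U)^2, 2, which.max)]
}
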