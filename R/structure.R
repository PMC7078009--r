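#' Project a geometric distortion onto normal modes
#'
#' The mode projection of a geometry is the flattened scalar product
#' `p_i = sum((geometry - reference) * dhat_i)` between the Cartesian
#' distortion from the reference (Franck--Condon) geometry and the
#' normalized, mass-unweighted displacement vector of mode i.  With
#' geometries in Angstrom the projections are in Angstrom.
#'
#' @param geometry natoms x 3 matrix (Angstrom).
#' @param reference natoms x 3 matrix (Angstrom), same atoms and order.
#' @param modes list of `sh_mode` objects carrying displacement vectors.
#' @return named numeric vector of projections, one per mode (names are
#'   the mode indices).
#' @export
project_onto_modes <- function(geometry, reference, modes) {
  geometry <- as.matrix(geometry); reference <- as.matrix(reference)
  if (!all(dim(geometry) == dim(reference)))
    stop("project_onto_modes: geometry and reference differ in atom count")
  dr <- geometry - reference
  p <- vapply(modes, function(m) {
    if (is.null(m$displacement))
      stop("project_onto_modes: mode without displacement vector")
    if (!all(dim(m$displacement) == dim(dr)))
      stop("project_onto_modes: mode displacement has wrong atom count")
    sum(dr * m$displacement)
  }, 0)
  names(p) <- vapply(modes, function(m) as.character(m$index), "")
  p
}

#' Align out-of-plane projections to a reference phase
#'
#' For a planar molecule the sign of every out-of-plane mode is arbitrary
#' (the two half-spaces are mirror images).  To compare geometries, each
#' one whose projection on the reference out-of-plane mode is negative is
#' mirrored through the molecular plane, which flips the sign of all
#' out-of-plane projections and leaves in-plane projections untouched.
#' The operation is idempotent.
#'
#' @param projections numeric vector (one geometry) or geometries x modes
#'   matrix of projections, columns ordered as `modes`.
#' @param modes list of `sh_mode` (their `character` field is used).
#' @param reference_mode column index of the reference mode; must be
#'   labeled `out_of_plane`.
#' @return aligned projections, same shape as the input.
#' @export
align_out_of_plane_phase <- function(projections, modes, reference_mode) {
  oop <- vapply(modes, function(m) m$character == "out_of_plane", TRUE)
  if (!oop[reference_mode])
    stop("align_out_of_plane_phase: reference mode is labeled in_plane")
  vec_in <- is.null(dim(projections))
  pm <- if (vec_in) matrix(projections, nrow = 1) else as.matrix(projections)
  flip <- pm[, reference_mode] < 0
  pm[flip, oop] <- -pm[flip, oop, drop = FALSE]
  if (vec_in) pm[1, ] else pm
}

# Angstrom of Cartesian displacement per unit dimensionless coordinate of
# mode i: 1 / sqrt(mu_i * omega_i) Bohr in atomic units.
mode_displacement_scale <- function(modes) {
  vapply(modes, function(m) {
    bohr_to_angstrom(1 / sqrt(m$reduced_mass_amu * sh_units$me_per_amu *
                                m$omega))
  }, 0)
}

# Per-frame mode projections (Angstrom) of a trajectory, directly from its
# dimensionless mode coordinates (equivalent to Cartesian reconstruction
# followed by project_onto_modes, for orthonormal mode vectors).
trajectory_projections <- function(traj, model) {
  sc <- mode_displacement_scale(model$modes)
  if (ncol(traj$q) != length(sc))
    stop("trajectory has ", ncol(traj$q), " mode coordinates but the model has ",
         length(sc), " modes")
  sweep(traj$q, 2, sc, `*`)
}

#' Statistics of hop-inducing geometries
#'
#' Collects, for every accepted hop of a given transition, the geometry at
#' the beginning of the classical step in which the hop fired, projects it
#' onto the normal modes, optionally aligns the out-of-plane phases, and
#' returns the per-mode mean and standard deviation (population
#' convention, denominator n).
#'
#' @param ensemble an `sh_ensemble` or list of `sh_trajectory`.
#' @param transition length-2 character vector `c(from, to)` of MCH labels.
#' @param model the `sh_lvc_model` behind the ensemble (for mode metadata).
#' @param align apply [align_out_of_plane_phase()] (default `TRUE`).
#' @param reference_mode index of the reference out-of-plane mode within
#'   the model's mode list; defaults to the first out-of-plane mode.
#' @return an object of class `sh_hop_geometry_stats`: `transition`, `mu`,
#'   `sigma` (named per mode), `n_hops`, `projections` (hops x modes
#'   matrix), `empty` flag.
#' @export
hop_geometry_stats <- function(ensemble, transition, model, align = TRUE,
                               reference_mode = NULL) {
  if (is.null(reference_mode))
    reference_mode <- which(vapply(model$modes, function(m)
      m$character == "out_of_plane", TRUE))[1]
  sc <- mode_displacement_scale(model$modes)
  rows <- list()
  for (tr in ensemble) {
    h <- tr$hops
    sel <- !h$frustrated & h$from_mch == transition[1] &
      h$to_mch == transition[2]
    for (s in h$step[sel]) {
      # frame `s` (1-based row s) is the beginning of classical step s
      rows[[length(rows) + 1]] <- tr$q[s, ] * sc
    }
  }
  mode_names <- vapply(model$modes, function(m) as.character(m$index), "")
  if (length(rows) == 0) {
    return(structure(list(transition = transition,
                          mu = NULL, sigma = NULL, n_hops = 0L,
                          projections = NULL, empty = TRUE),
                     class = "sh_hop_geometry_stats"))
  }
  pm <- do.call(rbind, rows)
  colnames(pm) <- mode_names
  if (align && !is.na(reference_mode))
    pm <- align_out_of_plane_phase(pm, model$modes, reference_mode)
  n <- nrow(pm)
  mu <- colMeans(pm)
  sigma <- sqrt(colMeans(sweep(pm, 2, mu)^2))  # population (n) convention
  structure(list(transition = transition, mu = mu, sigma = sigma,
                 n_hops = n, projections = pm, empty = FALSE),
            class = "sh_hop_geometry_stats")
}

#' @export
print.sh_hop_geometry_stats <- function(x, ...) {
  cat("Hop-inducing geometries for", x$transition[1], "->", x$transition[2],
      ":", x$n_hops, "hops\n")
  if (!x$empty)
    print(round(rbind(mu = x$mu, sigma = x$sigma), 4))
  invisible(x)
}

#' Time-resolved coherence analysis of mode projections
#'
#' For each mode and time, the ensemble average of the signed projections
#' `<p_i>` and of their absolute values `<|p_i|>`, plus a binned density
#' of the per-trajectory projections.  Equal signed and unsigned
#' amplitudes signal fully coherent motion; a vanishing signed average
#' with a finite unsigned one signals complete dephasing.
#'
#' @param ensemble an `sh_ensemble` or list of `sh_trajectory`.
#' @param model the underlying `sh_lvc_model`.
#' @param grid time grid (fs); defaults to the first trajectory's frames.
#' @param n_bins number of histogram bins for the density (default 40).
#' @return an object of class `sh_coherence_series`: `times`,
#'   `signed_mean` and `unsigned_mean` (times x modes matrices), `density`
#'   (list per mode of bins x times matrices with bin-edge attribute).
#' @export
coherence_series <- function(ensemble, model, grid = NULL, n_bins = 40) {
  if (length(ensemble) == 0) stop("coherence_series: empty ensemble")
  if (is.null(grid)) grid <- ensemble[[1]]$times
  nM <- length(model$modes)
  proj <- lapply(ensemble, function(tr) {
    ii <- match(round(grid, 9), round(tr$times, 9))
    if (anyNA(ii)) stop("coherence_series: trajectory not covering the grid")
    trajectory_projections(tr, model)[ii, , drop = FALSE]
  })
  mode_names <- vapply(model$modes, function(m) as.character(m$index), "")
  signed <- matrix(0, length(grid), nM, dimnames = list(NULL, mode_names))
  unsigned <- signed
  for (pmat in proj) {
    signed <- signed + pmat
    unsigned <- unsigned + abs(pmat)
  }
  signed <- signed / length(proj)
  unsigned <- unsigned / length(proj)
  density <- lapply(seq_len(nM), function(i) {
    vals <- vapply(proj, function(pmat) pmat[, i], numeric(length(grid)))
    rng <- range(vals)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    dm <- apply(vals, 1, function(v)
      graphics::hist(v, breaks = edges, plot = FALSE)$counts)
    attr(dm, "edges") <- edges
    dm  # bins x times
  })
  names(density) <- mode_names
  structure(list(times = grid, signed_mean = signed,
                 unsigned_mean = unsigned, density = density,
                 n_traj = length(ensemble)),
            class = "sh_coherence_series")
}

#' Reconstruct Cartesian frames of a trajectory
#'
#' Rebuilds Cartesian geometries (Angstrom) from the dimensionless mode
#' coordinates, the model's reference geometry and the mode displacement
#' vectors: `r(t) = r_ref + sum_i q_i(t) * s_i * dhat_i` with
#' `s_i = 1 / sqrt(mu_i * omega_i)` (converted to Angstrom).
#'
#' @param traj an `sh_trajectory`.
#' @param model an `sh_lvc_model` with `geometry` and mode displacements.
#' @param frames integer indices of frames to reconstruct (default all).
#' @return list of natoms x 3 matrices, one per requested frame.
#' @export
cartesian_frames <- function(traj, model, frames = seq_along(traj$times)) {
  if (is.null(model$geometry))
    stop("cartesian_frames: model has no reference geometry")
  ref <- as.matrix(model$geometry$coords)
  sc <- mode_displacement_scale(model$modes)
  disp <- lapply(model$modes, function(m) {
    if (is.null(m$displacement))
      stop("cartesian_frames: mode without displacement vector")
    m$displacement
  })
  lapply(frames, function(f) {
    g <- ref
    for (i in seq_along(disp)) g <- g + traj$q[f, i] * sc[i] * disp[[i]]
    g
  })
}

#' Bond-length time series over an ensemble
#'
#' Euclidean distance between two named atoms in every frame of every
#' trajectory, with ensemble summary statistics.  The Cartesian positions
#' are reconstructed from the mode coordinates (see [cartesian_frames()]);
#' distances are translation-invariant by construction.
#'
#' @param ensemble an `sh_ensemble` or list of `sh_trajectory`.
#' @param atom_pair length-2 character vector of atom labels as given in
#'   the model geometry (e.g. `c("N1", "H8")`).
#' @param model an `sh_lvc_model` with reference geometry and mode
#'   displacement vectors.
#' @return an object of class `sh_bond_series`: `atom_pair`, `series`
#'   (list of per-trajectory distance vectors, Angstrom), `summary`
#'   (min, max, mean, sd over all frames of all trajectories).
#' @export
bond_length_series <- function(ensemble, atom_pair, model) {
  if (is.null(model$geometry))
    stop("bond_length_series: model has no reference geometry")
  labels <- model$geometry$atoms
  ia <- match(atom_pair[1], labels)
  ib <- match(atom_pair[2], labels)
  if (is.na(ia) || is.na(ib))
    stop("bond_length_series: unknown atom label: ",
         paste(atom_pair[is.na(c(ia, ib))], collapse = ", "))
  ref <- as.matrix(model$geometry$coords)
  sc <- mode_displacement_scale(model$modes)
  # per-mode 3-vector of relative displacement (atom a minus atom b)
  S <- t(vapply(seq_along(model$modes), function(i) {
    d <- model$modes[[i]]$displacement
    sc[i] * (d[ia, ] - d[ib, ])
  }, numeric(3)))                     # modes x 3
  r0 <- ref[ia, ] - ref[ib, ]
  series <- lapply(ensemble, function(tr) {
    rel <- tr$q %*% S                 # frames x 3
    rel <- sweep(rel, 2, r0, `+`)
    sqrt(rowSums(rel^2))
  })
  all_d <- unlist(series)
  structure(list(
    atom_pair = atom_pair,
    series = series,
    summary = c(min = min(all_d), max = max(all_d),
                mean = mean(all_d), sd = stats::sd(all_d))
  ), class = "sh_bond_series")
}

#' @export
print.sh_bond_series <- function(x, ...) {
  cat(sprintf("Bond %s-%s over %d trajectories: mean %.3f (sd %.3f), range [%.3f, %.3f] Angstrom\n",
              x$atom_pair[1], x$atom_pair[2], length(x$series),
              x$summary["mean"], x$summary["sd"],
              x$summary["min"], x$summary["max"]))
  invisible(x)
}

#' Compare hop-geometry statistics with an MECP geometry
#'
#' Projects a minimum-energy crossing point geometry onto the normal
#' modes, aligns its out-of-plane phase to the reference mode, and
#' compares per mode with the hop statistics: in-plane modes by the
#' absolute difference `|mu - p_mecp|`; out-of-plane modes (whose sign is
#' arbitrary for a planar molecule) by whether `|p_mecp| <= |mu| + 2 sigma`,
#' i.e. whether the MECP distortion lies within the band of total
#' distortion covered by the hops.
#'
#' @param stats an `sh_hop_geometry_stats`.
#' @param mecp_geometry natoms x 3 matrix (Angstrom).
#' @param reference natoms x 3 reference (Franck--Condon) geometry.
#' @param modes list of `sh_mode` with displacement vectors.
#' @param reference_mode index of the reference out-of-plane mode.
#' @return data frame with one row per mode: `mode`, `character`,
#'   `mu_hop`, `sigma_hop`, `p_mecp`, `delta` (in-plane only),
#'   `within_band` (out-of-plane only).
#' @export
compare_to_mecp <- function(stats, mecp_geometry, reference, modes,
                            reference_mode = NULL) {
  if (stats$empty) stop("compare_to_mecp: empty hop statistics")
  if (is.null(reference_mode))
    reference_mode <- which(vapply(modes, function(m)
      m$character == "out_of_plane", TRUE))[1]
  p <- project_onto_modes(mecp_geometry, reference, modes)
  if (!is.na(reference_mode))
    p <- align_out_of_plane_phase(p, modes, reference_mode)
  ch <- vapply(modes, function(m) m$character, "")
  oop <- ch == "out_of_plane"
  data.frame(
    mode = vapply(modes, function(m) m$index, 0L),
    character = ch,
    mu_hop = as.numeric(stats$mu),
    sigma_hop = as.numeric(stats$sigma),
    p_mecp = as.numeric(p),
    delta = ifelse(oop, NA_real_, abs(stats$mu - p)),
    within_band = ifelse(oop, abs(p) <= abs(stats$mu) + 2 * stats$sigma, NA),
    row.names = NULL
  )
}
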