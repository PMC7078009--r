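#' Read normal modes from a Molden-style frequency file
#'
#' Parses the `[FR-COORD]` (reference geometry, Bohr), `[FREQ]`
#' (frequencies, cm^-1) and `[FR-NORM-COORD]` (per-mode Cartesian
#' displacement) blocks.  Displacement vectors are renormalized to unit
#' Euclidean norm (the applied factors are returned as an attribute) and
#' frequencies converted to Hartree internally.  Mode character is
#' assigned geometrically when the reference geometry is planar in z:
#' modes with more than half their norm along z are labeled
#' `out_of_plane`, the rest `in_plane`.
#'
#' @param path file path.
#' @return list with `geometry` (`atoms`, `elements`, `coords` in
#'   Angstrom) and `modes` (list of `sh_mode`); attribute
#'   `renormalization` logs the per-mode norm factors.
#' @export
read_normal_modes <- function(path) {
  lines <- trimws(readLines(path))
  find_block <- function(tag) {
    i <- grep(paste0("^\\[", tag, "\\]$"), lines, ignore.case = TRUE)
    if (length(i) != 1)
      stop("read_normal_modes: missing or duplicated block [", tag, "]")
    i
  }
  block_body <- function(start) {
    ends <- grep("^\\[", lines)
    stop_at <- ends[ends > start]
    end <- if (length(stop_at)) min(stop_at) - 1 else length(lines)
    lines[seq(start + 1, end)]
  }
  coord_lines <- block_body(find_block("FR-COORD"))
  coord_lines <- coord_lines[nzchar(coord_lines)]
  toks <- strsplit(coord_lines, "\\s+")
  elements <- vapply(toks, `[[`, "", 1)
  coords_bohr <- t(vapply(toks, function(x) as.numeric(x[2:4]), numeric(3)))
  natoms <- length(elements)
  freq_lines <- block_body(find_block("FREQ"))
  freqs <- as.numeric(freq_lines[nzchar(freq_lines)])
  nm_lines <- block_body(find_block("FR-NORM-COORD"))
  vib_idx <- grep("^[Vv]ibration", nm_lines)
  if (length(vib_idx) != length(freqs))
    stop("read_normal_modes: [FREQ] lists ", length(freqs),
         " modes but [FR-NORM-COORD] has ", length(vib_idx))
  planar_z <- all(abs(coords_bohr[, 3]) < 1e-6)
  renorm <- numeric(length(freqs))
  modes <- vector("list", length(freqs))
  for (k in seq_along(vib_idx)) {
    start <- vib_idx[k] + 1
    end <- if (k < length(vib_idx)) vib_idx[k + 1] - 1 else length(nm_lines)
    body <- nm_lines[start:end]
    body <- body[nzchar(body)]
    vals <- as.numeric(unlist(strsplit(body, "\\s+")))
    if (length(vals) != 3 * natoms)
      stop("read_normal_modes: mode ", k, " has ", length(vals) / 3,
           " atoms but [FR-COORD] has ", natoms)
    disp <- matrix(vals, ncol = 3, byrow = TRUE)
    nrm <- sqrt(sum(disp^2))
    if (nrm == 0) stop("read_normal_modes: zero-norm vector in mode ", k)
    renorm[k] <- nrm
    zfrac <- sum(disp[, 3]^2) / nrm^2
    ch <- if (planar_z && zfrac > 0.5) "out_of_plane" else "in_plane"
    modes[[k]] <- normal_mode(freqs[k], character = ch, index = k,
                              displacement = disp)
  }
  out <- list(
    geometry = list(
      atoms = paste0(elements, seq_along(elements)),
      elements = elements,
      coords = bohr_to_angstrom(coords_bohr)
    ),
    modes = modes
  )
  attr(out, "renormalization") <- renorm
  out
}

#' Write normal modes to a Molden-style frequency file
#'
#' Inverse of [read_normal_modes()] (geometry written in Bohr).
#'
#' @param path output file path.
#' @param geometry list with `elements` and `coords` (Angstrom).
#' @param modes list of `sh_mode` with displacement vectors.
#' @return `path`, invisibly.
#' @export
write_normal_modes <- function(path, geometry, modes) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[Molden Format]", con)
  writeLines("[FREQ]", con)
  writeLines(sprintf("%.6f", vapply(modes, `[[`, 0, "frequency_cm1")), con)
  writeLines("[FR-COORD]", con)
  cb <- angstrom_to_bohr(as.matrix(geometry$coords))
  writeLines(sprintf("%-3s %18.12f %18.12f %18.12f",
                     geometry$elements, cb[, 1], cb[, 2], cb[, 3]), con)
  writeLines("[FR-NORM-COORD]", con)
  for (k in seq_along(modes)) {
    writeLines(sprintf("vibration %d", k), con)
    d <- modes[[k]]$displacement
    writeLines(sprintf("%18.12f %18.12f %18.12f", d[, 1], d[, 2], d[, 3]),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path file path (coordinates in Angstrom).
#' @return list of frames, each `list(elements, coords, comment)`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n) || i + 1 + n > length(lines))
      stop("read_xyz: malformed frame header at line ", i)
    comment <- lines[i + 1]
    toks <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    frames[[length(frames) + 1]] <- list(
      elements = vapply(toks, `[[`, "", 1),
      coords = t(vapply(toks, function(x) as.numeric(x[2:4]), numeric(3))),
      comment = comment
    )
    i <- i + 2 + n
  }
  frames
}

#' Write a multi-frame XYZ file
#'
#' Coordinates in Angstrom; the comment line carries the frame time (fs)
#' and active state when available.
#'
#' @param path output file path.
#' @param frames list of `list(elements, coords)` frames, or an
#'   `sh_trajectory` together with `model` for Cartesian reconstruction.
#' @param model required when `frames` is an `sh_trajectory`.
#' @param comments optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(path, frames, model = NULL, comments = NULL) {
  if (inherits(frames, "sh_trajectory")) {
    traj <- frames
    if (is.null(model)) stop("write_xyz: model needed for a trajectory")
    comments <- sprintf("t= %.3f fs state= %s", traj$times, traj$active_mch)
    frames <- lapply(cartesian_frames(traj, model),
                     function(g) list(elements = model$geometry$elements,
                                      coords = g))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(if (!is.null(comments)) comments[k]
               else fr$comment %||% "", con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", fr$elements,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Write a trajectory as a plain-text directory bundle
#'
#' One directory per trajectory: `frames.tsv` (time, coordinates, momenta,
#' energies, amplitude populations, active states), `hops.tsv`, and, when
#' a model with a reference geometry is given, `trajectory.xyz`.
#'
#' @param traj an `sh_trajectory`.
#' @param dir output directory (created if needed).
#' @param model optional `sh_lvc_model` for the XYZ export.
#' @return `dir`, invisibly.
#' @export
write_trajectory_bundle <- function(traj, dir, model = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nM <- ncol(traj$q)
  df <- data.frame(t_fs = traj$times)
  for (i in seq_len(nM)) df[[paste0("q", i)]] <- traj$q[, i]
  for (i in seq_len(nM)) df[[paste0("p", i)]] <- traj$p[, i]
  for (k in seq_len(ncol(traj$e_diag)))
    df[[paste0("e_diag", k, "_eV")]] <- traj$e_diag[, k]
  for (k in seq_len(ncol(traj$amplitudes)))
    df[[paste0("pop_diag", k)]] <- Mod(traj$amplitudes[, k])^2
  for (k in seq_len(ncol(traj$pop_mch)))
    df[[paste0("pop_mch_", colnames(traj$pop_mch)[k])]] <- traj$pop_mch[, k]
  df$active_diag <- traj$active_diag
  df$active_mch <- traj$active_mch
  df$e_kin_Ha <- traj$e_kin
  df$e_pot_Ha <- traj$e_pot
  df$e_tot_Ha <- traj$e_tot
  utils::write.table(df, file.path(dir, "frames.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(traj$hops, file.path(dir, "hops.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(model) && !is.null(model$geometry))
    write_xyz(file.path(dir, "trajectory.xyz"), traj, model)
  invisible(dir)
}

#' Read a trajectory bundle written by [write_trajectory_bundle()]
#'
#' Restores the fields needed by the analysis layer (frames, hops, active
#' states, amplitude populations); propagation metadata is not recovered.
#'
#' @param dir bundle directory.
#' @param state_labels state labels of the originating model.
#' @return an `sh_trajectory`.
#' @export
read_trajectory_bundle <- function(dir,
                                   state_labels = c("S0", "S1", "S2",
                                                    "T1", "T2")) {
  df <- utils::read.table(file.path(dir, "frames.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  hops <- utils::read.table(file.path(dir, "hops.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  qc <- grep("^q[0-9]+$", names(df))
  pc <- grep("^p[0-9]+$", names(df))
  ec <- grep("^e_diag", names(df))
  pdc <- grep("^pop_diag", names(df))
  pmc <- grep("^pop_mch_", names(df))
  labels <- sub("^pop_mch_", "", names(df)[pmc])
  tr <- scripted_trajectory(df$t_fs, df$active_mch,
                            hops = hops[, c("t", "from_mch", "to_mch",
                                            "frustrated")],
                            state_labels = labels)
  tr$q <- as.matrix(df[, qc, drop = FALSE])
  tr$p <- as.matrix(df[, pc, drop = FALSE])
  tr$e_diag <- as.matrix(df[, ec, drop = FALSE])
  tr$pop_mch <- as.matrix(df[, pmc, drop = FALSE])
  colnames(tr$pop_mch) <- labels
  tr$amplitudes <- sqrt(as.matrix(df[, pdc, drop = FALSE])) * (1 + 0i)
  tr$active_diag <- df$active_diag
  tr$e_kin <- df$e_kin_Ha; tr$e_pot <- df$e_pot_Ha; tr$e_tot <- df$e_tot_Ha
  tr
}

#' Default run configuration
#'
#' The study conditions of the reference protocol: 100 trajectories of
#' 1 ps at dt = 0.5 fs with 100 substeps, decoherence C = 0.1 Hartree,
#' all trajectories started in S2 from a ground-state Wigner sample;
#' analysis uses the singlet/triplet manifold split, the N-H and S-H
#' bonds, and the first out-of-plane mode as phase reference.
#'
#' @return a named list of class `sh_run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    model = list(preset = "2tp_lvc"),
    sampling = list(n_traj = 100L, seed = 1L, initial_state = "S2"),
    propagation = list(dt = 0.5, t_max = 1000, substeps = 100L,
                       decoherence_C = 0.1,
                       frustrated_policy = "continue"),
    analysis = list(
      manifolds = list(singlets = c("S0", "S1", "S2"),
                       triplets = c("T1", "T2")),
      bond_pairs = list(c("N1", "H8"), c("S7", "H8")),
      reference_mode = "auto",  # first out-of-plane mode
      hop_report_threshold = 10L,
      main_pathway = c("S2->S1", "S1->T2", "T2->T1")
    )
  ), class = "sh_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown top-level sections or unknown keys within a section are
#' rejected; omitted keys fall back to [default_run_config()].
#'
#' @param path YAML file path.
#' @return an `sh_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- default_run_config()
  bad <- setdiff(names(raw), names(def))
  if (length(bad))
    stop("read_run_config: unknown section(s): ", paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    bad_keys <- setdiff(names(raw[[sec]]), names(def[[sec]]))
    if (length(bad_keys))
      stop("read_run_config: unknown key(s) in ", sec, ": ",
           paste(bad_keys, collapse = ", "))
    def[[sec]] <- utils::modifyList(def[[sec]], raw[[sec]])
  }
  def
}

#' Write a run configuration to YAML
#'
#' @param config an `sh_run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable fingerprint of a configuration, stamped into output headers.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

# TSV writer with provenance header lines.
write_tsv_report <- function(df, path, config = NULL, seed = NULL,
                             extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste0("# config_hash= ", config_hash(config),
                      " seed= ", seed %||% "NA"), con)
  for (line in extra) writeLines(paste0("# ", line), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
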