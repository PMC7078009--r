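#' Default 2-thiopyridone-like LVC model
#'
#' The package's built-in synthetic stand-in for the electronic structure
#' of photo-excited 2-thiopyridone (2-TP): five states (S0, S1, S2, T1,
#' T2) with the Franck--Condon vertical excitation energies 3.16, 3.82,
#' 2.64 and 2.90 eV, over six harmonic normal modes of an idealized planar
#' 12-atom 2-TP geometry -- three in-plane (S/ring rocking at 225 cm^-1,
#' N-H rocking at 1120 cm^-1, ring stretching at 1590 cm^-1) and three
#' out-of-plane (ring torsion at 310 cm^-1, two N-H-centred wags at 460
#' and 570 cm^-1).
#'
#' The coupling constants are illustrative: no published values exist for
#' this system, so they were chosen once from physical scales
#' (intrastate gradients giving reorganization energies of 0.01--0.2 eV on
#' the in-plane tuning modes, zero on out-of-plane modes by planar
#' symmetry; interstate couplings of 0.02--0.08 eV within each spin
#' multiplicity; constant spin--orbit couplings of 0.0025--0.010 eV (20--80 cm^-1), the
#' scale of a sulfur heavy-atom effect) so that the model reproduces the
#' qualitative relaxation pattern of the reference system -- ultrafast
#' S2 -> S1 internal conversion driven by in-plane motion, followed by
#' slower intersystem crossing into the triplet manifold.  They are not
#' fitted to any published observable.
#'
#' @param triplet_components 1 (default) or 3 spin sublevels per triplet.
#' @return an `sh_lvc_model`.
#' @export
default_2tp_model <- function(triplet_components = 1L) {
  geom <- default_2tp_geometry()
  modes <- default_2tp_modes(geom)
  # mode order: 2 (ip), 5 (oop), 7 (oop), 8 (oop), 17 (ip), 22 (ip)
  kappa <- rbind(
    S0 = c(0.00, 0, 0, 0,  0.00,  0.00),
    S1 = c(0.03, 0, 0, 0, -0.22, -0.08),
    S2 = c(0.06, 0, 0, 0,  0.10, -0.28),
    T1 = c(0.05, 0, 0, 0, -0.04, -0.24),
    T2 = c(0.03, 0, 0, 0, -0.34, -0.02)
  )
  lam <- list(
    list(states = c("S1", "S2"), mode = 5L, value = 0.08),
    list(states = c("S1", "S2"), mode = 6L, value = 0.06),
    list(states = c("S0", "S1"), mode = 5L, value = 0.03),
    list(states = c("S0", "S1"), mode = 6L, value = 0.02),
    list(states = c("T1", "T2"), mode = 2L, value = 0.04),
    list(states = c("T1", "T2"), mode = 3L, value = 0.04),
    list(states = c("T1", "T2"), mode = 4L, value = 0.04)
  )
  soc <- list(
    list(states = c("S1", "T2"), value = 0.010),
    list(states = c("S2", "T2"), value = 0.008),
    list(states = c("S1", "T1"), value = 0.005),
    list(states = c("S2", "T1"), value = 0.005),
    list(states = c("S0", "T1"), value = 0.0025),
    list(states = c("S0", "T2"), value = 0.0025)
  )
  build_lvc_model(list(
    states = c(S0 = 1L, S1 = 1L, S2 = 1L, T1 = 3L, T2 = 3L),
    energies_eV = c(S0 = 0, S1 = 3.16, S2 = 3.82, T1 = 2.64, T2 = 2.90),
    modes = modes,
    kappa_eV = kappa,
    lambda_eV = lam,
    soc_eV = soc,
    triplet_components = triplet_components,
    geometry = geom,
    meta = list(
      characters = c(S0 = "closed-shell", S1 = "(n,pi*)", S2 = "(pi,pi*)",
                     T1 = "(pi,pi*)", T2 = "(n,pi*)"),
      energies_pt2_eV = c(S1 = 3.34, S2 = 3.64, T1 = 2.92, T2 = 3.31),
      note = paste("Synthetic LVC stand-in; couplings illustrative,",
                   "not fitted to published data")
    )
  ))
}

# Idealized planar 2-TP geometry (Angstrom, z = 0): pyridine-like ring
# with the thione sulfur on C2 and the amine hydrogen on N1.
default_2tp_geometry <- function() {
  r <- 1.39                       # ring circumradius = ring bond length
  ang <- pi / 180 * c(90, 150, 210, 270, 330, 30)
  ring <- cbind(r * cos(ang), r * sin(ang), 0)
  outward <- ring[, 1:2] / sqrt(rowSums(ring[, 1:2]^2))
  coords <- rbind(
    ring[1, ],                                  # N1
    ring[2, ], ring[3, ], ring[4, ], ring[5, ], ring[6, ],  # C2..C6
    c(ring[2, 1:2] + 1.68 * outward[2, ], 0),   # S7 (C=S)
    c(ring[1, 1:2] + 1.01 * outward[1, ], 0),   # H8 (N-H)
    c(ring[3, 1:2] + 1.08 * outward[3, ], 0),   # H9  (C3-H)
    c(ring[4, 1:2] + 1.08 * outward[4, ], 0),   # H10 (C4-H)
    c(ring[5, 1:2] + 1.08 * outward[5, ], 0),   # H11 (C5-H)
    c(ring[6, 1:2] + 1.08 * outward[6, ], 0)    # H12 (C6-H)
  )
  elements <- c("N", "C", "C", "C", "C", "C", "S", "H", "H", "H", "H", "H")
  list(atoms = paste0(elements, seq_along(elements)),
       elements = elements,
       coords = unname(coords))
}

# Six synthetic normal modes: hand-drawn displacement patterns,
# Gram-Schmidt orthonormalized within each symmetry class (in-plane
# patterns live in xy, out-of-plane in z, so the classes are orthogonal
# by construction).
default_2tp_modes <- function(geom = default_2tp_geometry()) {
  n <- nrow(geom$coords)
  at <- function(...) {
    m <- matrix(0, n, 3)
    spec <- list(...)
    for (s in spec) m[s[[1]], ] <- m[s[[1]], ] + unlist(s[[2]])
    m
  }
  raw <- list(
    # index 2: in-plane S/ring rocking (slow, sulfur-heavy)
    list(2L, 225, "in_plane", 3.5,
         at(list(7, c(0.80, 0.30, 0)), list(1, c(-0.20, -0.20, 0)),
            list(8, c(-0.30, -0.20, 0)), list(2, c(0.20, 0.10, 0)))),
    # index 5: out-of-plane ring torsion
    list(5L, 310, "out_of_plane", 3.0,
         at(list(1, c(0, 0, 0.40)), list(2, c(0, 0, -0.40)),
            list(3, c(0, 0, 0.40)), list(4, c(0, 0, -0.40)),
            list(5, c(0, 0, 0.40)), list(6, c(0, 0, -0.40)),
            list(7, c(0, 0, -0.30)), list(8, c(0, 0, 0.50)))),
    # index 7: N-H out-of-plane wag with ring counter-motion
    list(7L, 460, "out_of_plane", 1.4,
         at(list(8, c(0, 0, 0.80)), list(1, c(0, 0, -0.20)),
            list(4, c(0, 0, 0.30)), list(7, c(0, 0, -0.20)))),
    # index 8: nearly pure N-H out-of-plane wag
    list(8L, 570, "out_of_plane", 1.2,
         at(list(8, c(0, 0, 0.95)), list(1, c(0, 0, -0.15)),
            list(2, c(0, 0, 0.10)), list(6, c(0, 0, 0.10)))),
    # index 17: in-plane N-H rocking
    list(17L, 1120, "in_plane", 1.3,
         at(list(8, c(0.90, 0, 0)), list(1, c(-0.15, 0, 0)),
            list(2, c(0.10, -0.05, 0)), list(6, c(-0.10, 0.05, 0)))),
    # index 22: in-plane ring stretch with N-H rock
    list(22L, 1590, "in_plane", 2.0,
         at(list(1, c(0, 0.40, 0)), list(4, c(0, -0.40, 0)),
            list(2, c(0.20, 0.20, 0)), list(5, c(-0.20, -0.20, 0)),
            list(8, c(0.50, 0, 0)), list(10, c(0, -0.40, 0))))
  )
  # orthonormalize within each class, in listed order
  vecs <- lapply(raw, `[[`, 5)
  chars <- vapply(raw, `[[`, "", 3)
  for (k in seq_along(vecs)) {
    v <- vecs[[k]]
    for (j in seq_len(k - 1)) {
      if (chars[j] != chars[k]) next
      v <- v - sum(v * vecs[[j]]) * vecs[[j]]
    }
    vecs[[k]] <- v / sqrt(sum(v^2))
  }
  lapply(seq_along(raw), function(k) {
    normal_mode(frequency_cm1 = raw[[k]][[2]], character = chars[k],
                index = raw[[k]][[1]], reduced_mass_amu = raw[[k]][[4]],
                displacement = vecs[[k]])
  })
}
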