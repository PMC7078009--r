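# Small model builders and scripted fixtures shared across the test files.

# Two states of the same multiplicity, one mode: vertical gap `gap` (eV),
# interstate coupling lambda (eV per unit q), optional kappas.
two_state_model <- function(gap = 1, lambda = 0.1, kappa = c(0, 0),
                            freq_cm1 = 1000) {
  build_lvc_model(list(
    states = c(A = 1L, B = 1L),
    energies_eV = c(A = 0, B = gap),
    modes = list(list(frequency_cm1 = freq_cm1, character = "in_plane")),
    kappa_eV = rbind(A = kappa[1], B = kappa[2]),
    lambda_eV = list(list(states = c("A", "B"), mode = 1L, value = lambda))
  ))
}

# One singlet and one triplet with constant SOC V (eV); energies equal by
# default so the diagonal splitting is exactly 2|V|.
soc_pair_model <- function(V = 0.02, gap = 0, freq_cm1 = 1000) {
  build_lvc_model(list(
    states = c(S = 1L, T = 3L),
    energies_eV = c(S = 1, T = 1 + gap),
    modes = list(list(frequency_cm1 = freq_cm1, character = "in_plane")),
    soc_eV = list(list(states = c("S", "T"), value = V))
  ))
}

# Uncoupled copy of the five-state default: same states/modes, all kappa,
# lambda and SOC zero.
uncoupled_5state_model <- function() {
  build_lvc_model(list(
    states = c(S0 = 1L, S1 = 1L, S2 = 1L, T1 = 3L, T2 = 3L),
    energies_eV = c(S0 = 0, S1 = 3.16, S2 = 3.82, T1 = 2.64, T2 = 2.90),
    modes = lapply(c(300, 700, 1200), function(f)
      list(frequency_cm1 = f, character = "in_plane"))
  ))
}

# The hand-checkable 3-trajectory scripted ensemble: frames every 5 fs to
# 100 fs; trajectory 1 hops S2->S1 at 10 fs, trajectory 3 hops S2->S1 at
# 50 fs and S1->T2 at 150... (kept inside the grid: at 80 fs).
scripted_ensemble <- function() {
  tms <- seq(0, 100, by = 5)
  lab <- function(breaks, labels) {
    # step function over the grid: labels[k] applies from breaks[k] (incl.)
    out <- character(length(tms))
    for (k in seq_along(breaks))
      out[tms >= breaks[k]] <- labels[k]
    out
  }
  t1 <- scripted_trajectory(
    tms, lab(c(0, 10), c("S2", "S1")),
    hops = data.frame(t = 10, from_mch = "S2", to_mch = "S1"),
    n_modes = 6L)
  t2 <- scripted_trajectory(tms, lab(0, "S2"), n_modes = 6L)
  t3 <- scripted_trajectory(
    tms, lab(c(0, 50, 80), c("S2", "S1", "T2")),
    hops = data.frame(t = c(50, 80), from_mch = c("S2", "S1"),
                      to_mch = c("S1", "T2")), n_modes = 6L)
  list(t1, t2, t3)
}

# Random orthonormal in-plane/out-of-plane mode set over `natoms` atoms
# (planar z = 0 reference): `n_ip` modes in xy, `n_oop` in z, built by QR.
random_mode_set <- function(natoms = 4, n_ip = 3, n_oop = 3, seed = 1) {
  set.seed(seed)
  ip_basis <- qr.Q(qr(matrix(rnorm(2 * natoms * n_ip), 2 * natoms)))[, 1:n_ip]
  oop_basis <- qr.Q(qr(matrix(rnorm(natoms * n_oop), natoms)))[, 1:n_oop]
  modes <- list()
  for (k in seq_len(n_ip)) {
    d <- matrix(0, natoms, 3)
    d[, 1:2] <- matrix(ip_basis[, k], natoms, 2)
    modes[[length(modes) + 1]] <-
      normal_mode(800 + 10 * k, "in_plane", index = k, displacement = d)
  }
  for (k in seq_len(n_oop)) {
    d <- matrix(0, natoms, 3)
    d[, 3] <- oop_basis[, k]
    modes[[length(modes) + 1]] <-
      normal_mode(400 + 10 * k, "out_of_plane", index = n_ip + k,
                  displacement = d)
  }
  modes
}
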