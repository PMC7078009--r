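test_that("uncoupled limit keeps the active state and full coherence", {
  m <- uncoupled_5state_model()
  init <- list(q = c(0.5, -0.3, 0.8), p = c(0.2, 0.4, -0.1),
               initial_state = "S2", seed = 3)
  tr <- propagate_trajectory(m, init, propagation_params(t_max = 200))
  expect_true(all(tr$active_mch == "S2"))
  expect_equal(nrow(tr$hops), 0)
  i_s2 <- which(tr$state_labels == "S2")
  # |c_S2|^2 = 1 throughout (diagonal state of S2 character)
  expect_true(all(abs(tr$pop_mch[, "S2"] - 1) < 1e-10))
  expect_true(all(abs(rowSums(Mod(tr$amplitudes)^2) - 1) < 1e-8))
})

test_that("single-surface motion matches the closed-form harmonic solution", {
  m <- build_lvc_model(list(
    states = c(A = 1L, B = 1L), energies_eV = c(A = 0, B = 5),
    modes = list(list(frequency_cm1 = 1000, character = "in_plane"))
  ))
  q0 <- 0.8; p0 <- -0.4
  omega <- m$modes[[1]]$omega
  run_err <- function(dt) {
    tr <- propagate_trajectory(
      m, list(q = q0, p = p0, initial_state = "A", seed = 1),
      propagation_params(dt = dt, t_max = 100, hopping = FALSE,
                         nuc_substeps = 1))
    tau <- fs_to_autime(tr$times) * omega
    max(abs(tr$q[, 1] - (q0 * cos(tau) + p0 * sin(tau))))
  }
  e1 <- run_err(0.5)
  e2 <- run_err(0.25)
  expect_lt(e1, 2e-2)
  # O(dt^2) global error: halving dt reduces the error ~4x
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})

test_that("frozen-nuclei two-level SOC dynamics is an exact Rabi cycle", {
  V_ev <- 0.02
  m <- soc_pair_model(V = V_ev, gap = 0)
  tr <- propagate_trajectory(
    m, list(q = 0, p = 0, initial_state = "S", seed = 1),
    propagation_params(dt = 0.5, t_max = 100, substeps = 100,
                       freeze_nuclei = TRUE, hopping = FALSE,
                       decoherence_C = -1))
  V <- ev_to_hartree(V_ev)
  t_au <- fs_to_autime(tr$times)
  # degenerate two-level system: P_S(t) = cos^2(V t), period pi / |V| (a.u.)
  expect_lt(max(abs(tr$pop_mch[, "S"] - cos(V * t_au)^2)), 1e-6)
  t_half <- tr$times[which.min(tr$pop_mch[, "S"])]
  expect_lt(abs(t_half - autime_to_fs(pi / (2 * V))), tr$params$dt)
  # independent dense-substep integration oracle
  nsub <- 20000
  dt_fine <- max(t_au) / nsub
  c2 <- c(1 + 0i, 0i)
  H <- matrix(c(0, V, V, 0), 2)
  ev <- eigen(H, symmetric = TRUE)
  stepU <- ev$vectors %*% diag(exp(-1i * ev$values * dt_fine)) %*% t(ev$vectors)
  pops <- numeric(nsub + 1); pops[1] <- 1
  for (k in seq_len(nsub)) {
    c2 <- stepU %*% c2
    pops[k + 1] <- Mod(c2[1])^2
  }
  oracle <- approx(seq(0, max(t_au), length.out = nsub + 1), pops,
                   xout = t_au)$y
  expect_lt(max(abs(tr$pop_mch[, "S"] - oracle)), 1e-6)
})

test_that("hop probabilities obey the no-flux and clamping rules", {
  # active population unchanged: all probabilities zero
  P <- diag(2) * (1 + 0i)
  c0 <- c(sqrt(0.7), sqrt(0.3)) * (1 + 0i)
  d <- hop_decision(c0, c0, P, active = 1, rand = 0.0)
  expect_true(all(d$probabilities == 0))
  expect_true(is.na(d$target))
  # active population decreased: probability mass on the target
  th <- 0.3
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2) * (1 + 0i)
  c1 <- as.complex(R %*% c(1, 0))
  d2 <- hop_decision(c(1 + 0i, 0i), c1, R, active = 1, rand = 0.999)
  expect_gte(min(d2$probabilities), 0)
  expect_lte(sum(d2$probabilities), 1)
  expect_equal(sum(d2$probabilities), sin(th)^2, tolerance = 1e-12)
  # drawn variate below the cumulative probability selects the hop
  d3 <- hop_decision(c(1 + 0i, 0i), c1, R, active = 1, rand = 0.01)
  expect_identical(d3$target, 2L)
})

test_that("hop probability agrees with per-substep flux accumulation", {
  # small-transfer two-state step: compare the one-shot propagator
  # probability against brute-force accumulation over many substeps
  V <- ev_to_hartree(0.004)
  dt <- fs_to_autime(0.5)
  H <- matrix(c(0, V, V, 0), 2)
  ev <- eigen(H, symmetric = TRUE)
  c0 <- c(1 + 0i, 0i)
  nsub <- 2000
  U1 <- ev$vectors %*% diag(exp(-1i * ev$values * dt / nsub)) %*%
    t(ev$vectors)
  acc <- 0
  cc <- c0
  for (k in seq_len(nsub)) {
    cn <- U1 %*% cc
    dp <- Mod(cc[1])^2 - Mod(cn[1])^2
    if (dp > 0) acc <- acc + dp / Mod(cc[1])^2
    cc <- cn
  }
  Ufull <- ev$vectors %*% diag(exp(-1i * ev$values * dt)) %*% t(ev$vectors)
  c1 <- as.complex(Ufull %*% c0)
  d <- hop_decision(c0, c1, Ufull, active = 1, rand = 0.999)
  expect_equal(d$probabilities[2], acc, tolerance = 1e-4)
})

test_that("decoherence damps by the energy-gap time constant and renormalizes", {
  # |dE| = 0.1 Ha, e_kin = 0.1 Ha, C = 0.1 Ha -> tau = (1/0.1)(1+1) = 20 au
  c0 <- sqrt(c(0.6, 0.4)) * (1 + 0i)
  dt <- 2.0
  out <- apply_decoherence(c0, c(0, 0.1), active = 1, e_kin = 0.1,
                           C = 0.1, dt = dt)
  expect_equal(Mod(out[2]), sqrt(0.4) * exp(-dt / 20), tolerance = 1e-12)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # only the active state populated: nothing changes
  pure <- c(1 + 0i, 0i)
  expect_equal(apply_decoherence(pure, c(0, 0.5), 1, 0.05, 0.1, 1), pure)
  # phases preserved
  cph <- c(sqrt(0.5) * exp(0.3i), sqrt(0.5) * exp(-1.1i))
  outp <- apply_decoherence(cph, c(0, 0.2), 1, 0.1, 0.1, 1)
  expect_equal(Arg(outp), Arg(cph), tolerance = 1e-12)
})

test_that("momentum rescaling conserves energy or flags frustration", {
  r0 <- rescale_momentum(c(0.3, -0.2), e_gap = 0)
  expect_identical(r0$p, c(0.3, -0.2))
  expect_false(r0$frustrated)
  # e_kin = 0.2, e_gap = 0.15 -> |p'|/|p| = 0.5
  p <- c(0.5, sqrt(0.4 - 0.25))
  expect_equal(0.5 * sum(p^2), 0.2)
  r1 <- rescale_momentum(p, e_gap = 0.15)
  expect_equal(sqrt(sum(r1$p^2)) / sqrt(sum(p^2)), 0.5, tolerance = 1e-12)
  r2 <- rescale_momentum(c(0.1, 0.1), e_gap = 99)
  expect_true(r2$frustrated)
  expect_identical(r2$p, c(0.1, 0.1))
  r3 <- rescale_momentum(c(0.1, 0.1), e_gap = 99, policy = "reflect")
  expect_identical(r3$p, c(-0.1, -0.1))
})

test_that("energy is conserved across hops and bookkeeping is consistent", {
  m <- default_2tp_model()
  ics <- sample_wigner(m$modes, 3, "S2", seed = 21)
  for (ic in ics) {
    tr <- propagate_trajectory(m, ic,
                               propagation_params(t_max = 300,
                                                  rng_seed = ic$seed))
    # total energy jump at accepted hop steps is pure integration error,
    # i.e. comparable to neighbouring steps, never the potential gap
    accepted <- tr$hops[!tr$hops$frustrated, ]
    if (nrow(accepted) > 0) {
      jumps <- abs(tr$e_tot[accepted$step + 1] - tr$e_tot[accepted$step])
      expect_lt(max(jumps), 1e-5)
    }
    # final active state equals the initial state pushed through the hop list
    state <- tr$active_diag[1]
    for (j in seq_len(nrow(tr$hops))) {
      if (!tr$hops$frustrated[j]) state <- tr$hops$to_diag[j]
    }
    expect_identical(state, tr$active_diag[length(tr$active_diag)])
    expect_equal(tr$e_tot, tr$e_kin + tr$e_pot, tolerance = 1e-12)
  }
})

test_that("electronic propagation converges when dt is halved", {
  m <- default_2tp_model()
  ic <- sample_wigner(m$modes, 1, "S2", seed = 31)[[1]]
  base <- propagate_trajectory(
    m, ic, propagation_params(dt = 0.5, t_max = 25, substeps = 100,
                              hopping = FALSE, nuc_substeps = 40))
  fine <- propagate_trajectory(
    m, ic, propagation_params(dt = 0.25, t_max = 25, substeps = 200,
                              hopping = FALSE, nuc_substeps = 40))
  pb <- Mod(base$amplitudes[nrow(base$amplitudes), ])^2
  pf <- Mod(fine$amplitudes[nrow(fine$amplitudes), ])^2
  expect_lt(max(abs(pb - pf)), 1e-3)
})
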