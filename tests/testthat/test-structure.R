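test_that("mode projections satisfy basis-vector and Parseval identities", {
  modes <- random_mode_set(natoms = 4, n_ip = 3, n_oop = 3, seed = 11)
  ref <- matrix(rnorm(12), 4, 3)
  # displacing along one mode projects onto it alone
  g8 <- ref + 1.0 * modes[[4]]$displacement
  p <- project_onto_modes(g8, ref, modes)
  expect_equal(unname(p[4]), 1.0, tolerance = 1e-12)
  expect_lt(max(abs(p[-4])), 1e-12)
  # zero distortion projects to zero
  expect_true(all(project_onto_modes(ref, ref, modes) == 0))
  # linearity
  p2 <- project_onto_modes(ref + 2.5 * (g8 - ref), ref, modes)
  expect_equal(unname(p2[4]), 2.5, tolerance = 1e-12)
  expect_error(project_onto_modes(ref[1:3, ], ref, modes), "atom count")
})

test_that("Parseval holds for complete orthonormal mode sets", {
  natoms <- 3
  set.seed(13)
  # complete orthonormal basis of all 9 Cartesian directions
  B <- qr.Q(qr(matrix(rnorm(81), 9)))
  modes <- lapply(1:9, function(k)
    normal_mode(500 + k, "in_plane", index = k,
                displacement = matrix(B[, k], natoms, 3)))
  ref <- matrix(rnorm(9), natoms, 3)
  for (r in 1:100) {
    dr <- matrix(rnorm(9, 0, 0.3), natoms, 3)
    p <- project_onto_modes(ref + dr, ref, modes)
    expect_equal(sum(p^2), sum(dr^2), tolerance = 1e-10)
  }
})

test_that("out-of-plane phase alignment flips signs by the stated rule", {
  modes <- list(normal_mode(400, "out_of_plane", 7,
                            displacement = cbind(0, 0, c(1, 0, 0))),
                normal_mode(500, "out_of_plane", 8,
                            displacement = cbind(0, 0, c(0, 1, 0))),
                normal_mode(1100, "in_plane", 17,
                            displacement = cbind(c(1, 0, 0), 0, 0)))
  # reference mode = column 2 (mode 8)
  p <- c(0.2, -0.3, 0.5)   # p7, p8, p17
  out <- align_out_of_plane_phase(p, modes, reference_mode = 2)
  expect_equal(unname(out), c(-0.2, 0.3, 0.5))
  # already positive: unchanged
  p_pos <- c(0.2, 0.3, 0.5)
  expect_equal(align_out_of_plane_phase(p_pos, modes, 2), p_pos)
  # idempotence on random matrices
  set.seed(3)
  pm <- matrix(rnorm(60), 20, 3)
  once <- align_out_of_plane_phase(pm, modes, 2)
  expect_equal(align_out_of_plane_phase(once, modes, 2), once)
  expect_true(all(once[, 2] >= 0))
  # in-plane columns untouched
  expect_equal(once[, 3], pm[, 3])
  expect_error(align_out_of_plane_phase(p, modes, 3), "in_plane")
})

test_that("hop-geometry statistics match hand-computed values", {
  tms <- seq(0, 20, 5)
  mk <- function(q_at_hop, hop_t) {
    q <- matrix(0, 5, 2)
    q[which(tms == hop_t) - 1, ] <- q_at_hop   # frame preceding the hop
    scripted_trajectory(tms, c("S1", "S1", rep("T2", 3)),
                        hops = data.frame(t = hop_t, from_mch = "S1",
                                          to_mch = "T2"),
                        q = q)
  }
  m <- default_2tp_model()
  sc <- surfhop:::mode_displacement_scale(m$modes)[1:2]
  # two hops with in-plane projections 0.1 and 0.3 on mode "2"
  ens <- list(mk(c(0.1, 0) / sc, 10), mk(c(0.3, 0) / sc, 10))
  # build a 2-mode model view for the fixture
  m2 <- m; m2$modes <- m$modes[1:2]
  st <- hop_geometry_stats(ens, c("S1", "T2"), m2, align = FALSE)
  expect_equal(st$n_hops, 2L)
  expect_equal(unname(st$mu[1]), 0.2, tolerance = 1e-12)
  expect_equal(unname(st$sigma[1]), 0.1, tolerance = 1e-12)  # population sd
  # single hop: sigma = 0
  st1 <- hop_geometry_stats(ens[1], c("S1", "T2"), m2, align = FALSE)
  expect_equal(unname(st1$sigma), c(0, 0))
  # opposite out-of-plane phases align to equal sign: mu = 0.2, sigma = 0
  ens2 <- list(mk(c(0, 0.2) / sc, 10), mk(c(0, -0.2) / sc, 10))
  st2 <- hop_geometry_stats(ens2, c("S1", "T2"), m2, align = TRUE,
                            reference_mode = 2)
  expect_equal(unname(st2$mu[2]), 0.2, tolerance = 1e-12)
  expect_equal(unname(st2$sigma[2]), 0, tolerance = 1e-12)
  # no matching hops: flagged empty
  st0 <- hop_geometry_stats(ens, c("S2", "S1"), m2)
  expect_true(st0$empty)
  expect_identical(st0$n_hops, 0L)
})

test_that("coherence series bounds and dephasing behave as expected", {
  m <- default_2tp_model()
  m2 <- m; m2$modes <- m$modes[1:2]
  sc <- surfhop:::mode_displacement_scale(m2$modes)
  tms <- seq(0, 100, 1)
  omega <- 2 * pi / 50
  coherent <- lapply(1:20, function(i) {
    q <- cbind(sin(omega * tms) / sc[1], 0)
    scripted_trajectory(tms, rep("S2", length(tms)), q = q)
  })
  cs <- coherence_series(coherent, m2, tms)
  expect_equal(unname(cs$signed_mean[, 1]), sin(omega * tms),
               tolerance = 1e-10)
  expect_equal(unname(cs$unsigned_mean[, 1]), abs(sin(omega * tms)),
               tolerance = 1e-10)
  # random phases dephase the signed mean but not the unsigned mean
  set.seed(8)
  dephased <- lapply(1:400, function(i) {
    ph <- runif(1, 0, 2 * pi)
    q <- cbind(sin(omega * tms + ph) / sc[1], 0)
    scripted_trajectory(tms, rep("S2", length(tms)), q = q)
  })
  cd <- coherence_series(dephased, m2, tms)
  mid <- tms > 5  # away from t = 0 the phases are uniform
  expect_lt(stats::median(abs(cd$signed_mean[mid, 1]) /
                            cd$unsigned_mean[mid, 1]), 0.1)
  # triangle inequality everywhere, any ensemble
  expect_true(all(cd$unsigned_mean >= abs(cd$signed_mean) - 1e-12))
  expect_true(all(cs$unsigned_mean >= abs(cs$signed_mean) - 1e-12))
})

test_that("bond lengths are exact on static fixtures and translation-invariant", {
  m <- default_2tp_model()
  # static trajectory at the reference geometry: N1-H8 distance = 1.01
  tms <- seq(0, 10, 5)
  still <- scripted_trajectory(tms, rep("S2", 3),
                               q = matrix(0, 3, length(m$modes)))
  bs <- bond_length_series(list(still), c("N1", "H8"), m)
  expect_equal(unname(bs$summary["mean"]), 1.01, tolerance = 1e-9)
  expect_equal(unname(bs$summary["sd"]), 0)
  # two frames differing along the N-H stretch direction
  sc <- surfhop:::mode_displacement_scale(m$modes)
  q2 <- matrix(0, 2, length(m$modes))
  # displace along mode 17 (in-plane N-H rock, index 5 in the list)
  q2[2, 5] <- 0.5 / sc[5]
  two <- scripted_trajectory(c(0, 5), c("S2", "S2"), q = q2)
  bs2 <- bond_length_series(list(two), c("N1", "H8"), m)
  d <- bs2$series[[1]]
  expect_equal(unname(bs2$summary["max"]), max(d))
  expect_equal(unname(bs2$summary["mean"]), mean(d), tolerance = 1e-12)
  # translating the whole molecule leaves distances unchanged
  m_shift <- m
  m_shift$geometry$coords <- m$geometry$coords +
    matrix(rep(c(1.3, -0.7, 2.1), each = 12), 12, 3)
  bs3 <- bond_length_series(list(two), c("N1", "H8"), m_shift)
  expect_equal(bs3$series[[1]], bs2$series[[1]], tolerance = 1e-12)
  expect_error(bond_length_series(list(two), c("N1", "XX"), m), "XX")
})

test_that("MECP comparison applies the in-plane/out-of-plane rules", {
  modes <- random_mode_set(natoms = 4, n_ip = 2, n_oop = 2, seed = 21)
  ref <- matrix(rnorm(12), 4, 3)
  # synthetic hop stats: known mu/sigma
  st <- structure(list(
    transition = c("S1", "T2"),
    mu = c(`1` = 0.3, `2` = -0.1, `3` = 0.1, `4` = 0.05),
    sigma = c(`1` = 0.05, `2` = 0.05, `3` = 0.1, `4` = 0.02),
    n_hops = 5L, projections = NULL, empty = FALSE),
    class = "sh_hop_geometry_stats")
  # MECP equal to the "mean hop geometry" along in-plane modes
  g_mean <- ref + 0.3 * modes[[1]]$displacement -
    0.1 * modes[[2]]$displacement
  cmp <- compare_to_mecp(st, g_mean, ref, modes, reference_mode = 3)
  expect_equal(cmp$delta[1:2], c(0, 0), tolerance = 1e-10)
  expect_true(all(is.na(cmp$delta[3:4])))
  # out-of-plane: p_mecp = 0.5 against mu = 0.1, sigma = 0.1 -> outside band
  g_oop <- ref + 0.5 * modes[[3]]$displacement
  cmp2 <- compare_to_mecp(st, g_oop, ref, modes, reference_mode = 3)
  expect_false(cmp2$within_band[3])
  expect_true(is.na(cmp2$within_band[1]))
  # MECP = reference: all projections zero
  cmp3 <- compare_to_mecp(st, ref, ref, modes, reference_mode = 3)
  expect_true(all(abs(cmp3$p_mecp) < 1e-12))
})
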