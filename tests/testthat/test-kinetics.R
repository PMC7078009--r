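test_that("populations of the scripted ensemble match hand counts", {
  ens <- scripted_ensemble()
  pops <- compute_populations(ens, "mch_active")
  expect_equal(unname(pops$populations[1, "S2"]), 1)  # all start in S2
  # after the 10 fs hop of trajectory 1: S1 = 1/3, S2 = 2/3
  at <- function(t) which(pops$times == t)
  expect_equal(unname(pops$populations[at(25), c("S1", "S2")]),
               c(1, 2) / 3)
  # after 50 fs (trajectory 3 hops): S1 = 2/3, S2 = 1/3
  expect_equal(unname(pops$populations[at(60), c("S1", "S2")]),
               c(2, 1) / 3)
  # after 80 fs: S1 = 1/3, S2 = 1/3, T2 = 1/3
  expect_equal(unname(pops$populations[at(90), c("S1", "S2", "T2")]),
               c(1, 1, 1) / 3)
  expect_equal(rowSums(pops$populations), rep(1, length(pops$times)),
               tolerance = 1e-12)
})

test_that("population rows sum to one in every basis", {
  m <- default_2tp_model()
  ens <- lapply(sample_wigner(m$modes, 3, "S2", seed = 17), function(ic)
    propagate_trajectory(m, ic, propagation_params(t_max = 50,
                                                   rng_seed = ic$seed)))
  for (b in c("mch_active", "diagonal_active", "quantum_amplitude")) {
    pops <- compute_populations(ens, b)
    expect_equal(rowSums(pops$populations), rep(1, length(pops$times)),
                 tolerance = 1e-9)
    expect_true(all(pops$populations >= 0 & pops$populations <= 1))
  }
  # trajectory shorter than the grid is reported with its index
  short <- scripted_trajectory(seq(0, 20, 5), rep("S2", 5))
  expect_error(compute_populations(c(ens, list(short)), "mch_active",
                                   grid = ens[[1]]$times),
               "4")
})

test_that("hop counting is exact on fixtures and respects the threshold", {
  ens <- scripted_ensemble()
  hm <- count_hops(ens)
  expect_equal(unname(hm$counts["S2", "S1"]), 2)
  expect_equal(unname(hm$counts["S1", "T2"]), 1)
  expect_equal(sum(hm$counts), 3)
  expect_true(all(diag(hm$counts) == 0))
  # zero-hop ensemble
  none <- count_hops(list(scripted_trajectory(c(0, 5), c("S2", "S2"))))
  expect_true(all(none$counts == 0))
  # entries below the report threshold stay in the matrix, vanish in the
  # rendered table
  rendered <- format_hop_matrix(hm, threshold = 10)
  expect_identical(unname(rendered["S2", "S1"]), "")
  rendered2 <- format_hop_matrix(hm, threshold = 1)
  expect_identical(unname(rendered2["S2", "S1"]), "*2*")
})

test_that("kinetic simulation matches closed-form solutions", {
  grid <- seq(0, 500, 2)
  # all rates zero: populations constant
  m0 <- kinetic_model(rep(0, 9))
  s0 <- simulate_kinetics(m0, grid)
  expect_true(all(s0$populations[, "S2"] == 1))
  # single reaction: exponential decay
  m1 <- kinetic_model(c(0.004), reactions = data.frame(from = "S2", to = "S1"))
  s1 <- simulate_kinetics(m1, grid)
  expect_equal(unname(s1$populations[, "S2"]), exp(-0.004 * grid),
               tolerance = 1e-8)
  # irreversible chain A -> B -> C: Bateman closed form
  k1 <- 0.01; k2 <- 0.003
  mc <- kinetic_model(c(k1, k2),
                      reactions = data.frame(from = c("A", "B"),
                                             to = c("B", "C")),
                      initial = c(A = 1))
  sc <- simulate_kinetics(mc, grid)
  bateman_B <- k1 / (k2 - k1) * (exp(-k1 * grid) - exp(-k2 * grid))
  expect_equal(unname(sc$populations[, "B"]), bateman_B, tolerance = 1e-6)
  expect_equal(rowSums(sc$populations), rep(1, length(grid)),
               tolerance = 1e-10)
  expect_error(kinetic_model(c(-0.1), reactions = data.frame(from = "A",
                                                             to = "B"),
                             initial = c(A = 1)),
               "negative")
})

test_that("the nine-rate fit recovers known rates from noiseless data", {
  truth <- c(0.02, 0.004, 0.003, 0.003, 0.002, 0.002, 0.004, 0.009, 0.002)
  mt <- kinetic_model(truth)
  grid <- seq(0, 1000, 5)
  data <- simulate_kinetics(mt, grid)
  fit <- fit_kinetic_model(data, options = list(seed = 4))
  expect_true(fit$converged)
  expect_lt(fit$residual, 1e-10)
  expect_equal(unname(fit$parameters$estimate), truth, tolerance = 0.01)
})

test_that("degenerate and nested kinetic fits behave sanely", {
  grid <- seq(0, 1000, 10)
  flat <- population_series(
    grid, cbind(S0 = 0, S1 = 0, S2 = rep(1, length(grid)), T1 = 0, T2 = 0))
  fit <- fit_kinetic_model(flat, options = list(seed = 2, n_starts = 4))
  expect_lt(max(fit$parameters$estimate), 1e-6)
  # data from a 2-reaction truth: the 9-rate network nests it
  m2 <- kinetic_model(c(`S2->S1` = 0.01, `S1->T2` = 0.002))
  data2 <- simulate_kinetics(m2, grid)
  fit9 <- fit_kinetic_model(data2, options = list(
    seed = 3, extra_starts = list(rep(1e-4, 9))))
  fit2 <- fit_kinetic_model(
    data2, network = kinetic_model(c(0.005, 0.005),
                                   reactions = default_reaction_network()[1:2, ]),
    options = list(seed = 3))
  expect_lte(fit9$residual, fit2$residual + 1e-10)
})

test_that("exponential manifold fit recovers the input lifetime exactly", {
  grid <- seq(0, 1000, 0.5)
  s <- exp(-grid / 1058)
  data <- population_series(grid, cbind(S0 = 0, S1 = s, S2 = 0,
                                        T1 = 1 - s, T2 = 0))
  fit <- fit_exponential_manifold(data, c("S0", "S1", "S2"))
  expect_true(fit$converged)
  expect_equal(fit$tau_fs, 1058, tolerance = 1e-6)
  # non-decaying data does not converge
  flat <- population_series(grid, cbind(S1 = rep(1, length(grid))))
  expect_false(fit_exponential_manifold(flat, "S1")$converged)
})

test_that("stochastic ensemble lifetime is recovered within 3 standard errors", {
  set.seed(99)
  tau_true <- 1000
  tms <- seq(0, 1000, 5)
  ens <- lapply(1:100, function(i) {
    t_dec <- stats::rexp(1, 1 / tau_true)
    lab <- ifelse(tms < t_dec, "S1", "T1")
    hop_t <- tms[which(tms >= t_dec)[1]]
    hops <- if (!is.na(hop_t) && hop_t > 0)
      data.frame(t = hop_t, from_mch = "S1", to_mch = "T1")
    else data.frame(t = numeric(), from_mch = character(),
                    to_mch = character())
    if (!is.na(hop_t) && hop_t == 0) lab[] <- "T1"
    scripted_trajectory(tms, lab, hops = hops)
  })
  pops <- compute_populations(ens, "mch_active")
  fit <- fit_exponential_manifold(pops, c("S0", "S1", "S2"),
                                  ensemble = ens, n_boot = 100, seed = 7)
  se_analytic <- tau_true / sqrt(100)
  expect_lt(abs(fit$tau_fs - tau_true), 3 * se_analytic)
  expect_gt(fit$se_tau_fs, 0)
})

test_that("mean first-hop times follow the fixture hop lists", {
  one <- scripted_trajectory(seq(0, 200, 5),
                             c(rep("S1", 20), rep("S0", 21)),
                             hops = data.frame(t = 100, from_mch = "S1",
                                               to_mch = "S0"))
  r1 <- mean_first_hop_time(list(one), "S1", "S0")
  expect_equal(r1$mean_fs, 100)
  expect_equal(r1$n, 1)
  early <- scripted_trajectory(seq(0, 200, 5),
                               c(rep("S1", 10), rep("S0", 31)),
                               hops = data.frame(t = 50, from_mch = "S1",
                                                 to_mch = "S0"))
  late <- scripted_trajectory(seq(0, 200, 5),
                              c(rep("S1", 30), rep("S0", 11)),
                              hops = data.frame(t = 150, from_mch = "S1",
                                                to_mch = "S0"))
  r2 <- mean_first_hop_time(list(early, late, scripted_trajectory(
    seq(0, 200, 5), rep("S1", 41))), "S1", "S0")
  expect_equal(r2$mean_fs, 100)  # mean of hops at 50 and 150 fs
  expect_equal(r2$n, 2)
  expect_equal(r2$n_excluded, 1)
  r3 <- mean_first_hop_time(list(one), "S2", "T2")
  expect_false(r3$defined)
  expect_identical(r3$n, 0L)
})

test_that("hop bookkeeping is consistent with net population change", {
  # net change of each label between t = 0 and t_max equals
  # inflow - outflow from the hop lists (fixture check)
  ens <- scripted_ensemble()
  pops <- compute_populations(ens, "mch_active")
  first <- pops$populations[1, ]
  last <- pops$populations[nrow(pops$populations), ]
  hm <- count_hops(ens)$counts
  for (lab in colnames(hm)) {
    net <- (sum(hm[, lab]) - sum(hm[lab, ])) / length(ens)
    expect_equal(unname(last[lab] - first[lab]), net, tolerance = 1e-12)
  }
})
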