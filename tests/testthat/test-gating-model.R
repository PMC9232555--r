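# Tetrameric gating scheme: generator structure, equilibria, dynamics and
# the stochastic oracle.

test_that("generator matrix has the binding-chain structure and zero row sums", {
  p <- gating_params(kd_pip2 = 2, k_off = 12, beta_max = 40, alpha = 5)
  Q <- build_rate_matrix(p, pip2 = 3, dag = 50)
  expect_equal(rowSums(Q), rep(0, 6), ignore_attr = TRUE, tolerance = 1e-12)
  kon <- 12 / 2
  expect_equal(Q["C0", "C1"], 4 * kon * 3)
  expect_equal(Q["C2", "C3"], 2 * kon * 3)
  expect_equal(Q["C3", "C2"], 3 * 12)
  expect_equal(Q["C4", "O"], beta_of_dag(p, 50))
  expect_equal(Q["O", "C4"], p$alpha)
  expect_equal(Q["C0", "O"], 0)  # supportive: no C0 gate

  Qi <- build_rate_matrix(gating_params(polarity = "inhibitory"), 3, 50)
  expect_gt(Qi["C0", "O"], 0)
  expect_equal(Qi["C4", "O"], 0)

  # no ligand, supportive: only unbinding and the gate entries off-diagonal
  Q0 <- build_rate_matrix(p, pip2 = 0, dag = 50)
  expect_equal(Q0["C0", "C1"], 0)
  expect_equal(Q0["C1", "C0"], 12)
  expect_error(build_rate_matrix(p, pip2 = -1, dag = 0),
               class = "pipgate_error_precondition")
})

test_that("equilibrium occupancy is binomial when the gate is shut", {
  p <- gating_params(kd_pip2 = 2, k_off = 12, beta_max = 0, alpha = 5)
  for (ratio in c(0.1, 1, 10)) {
    ss <- steady_state(p, pip2 = ratio * p$kd_pip2, dag = 50)
    expect_false(ss$degenerate)
    expect_equal(unlist(ss[1, 1:5]), dbinom(0:4, 4, ratio / (1 + ratio)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(ss$Po, 0, tolerance = 1e-10)
  }
})

test_that("steady-state Po matches the detailed-balance closed form on a grid", {
  for (x in c(0.2, 0.5, 1, 5, 12.5)) {
    for (theta in c(0.1, 0.5, 1, 4, 20)) {
      for (pol in c("supportive", "inhibitory")) {
        alpha <- 6
        dag <- 50
        p <- gating_params(kd_pip2 = 2, k_off = 9, alpha = alpha,
                           polarity = pol,
                           beta_max = theta * alpha /
                             (50^0.8 / (46^0.8 + 50^0.8)))
        ss <- steady_state(p, pip2 = x * p$kd_pip2, dag = dag)
        expect_equal(ss$Po, oracle_steady_po(x, theta, pol),
                     tolerance = 1e-8)
        expect_equal(unlist(ss[1, 1:6]),
                     oracle_steady_occupancy(x, theta, pol),
                     tolerance = 1e-8, ignore_attr = TRUE)
      }
    }
  }
})

test_that("steady Po is monotone in PIP2, opposite signs by polarity", {
  ladder <- c(0.1, 0.5, 1, 2, 5, 10, 30)
  po_sup <- vapply(ladder, function(z)
    steady_state(gating_params(), z, 50)$Po, numeric(1))
  po_inh <- vapply(ladder, function(z)
    steady_state(gating_params(polarity = "inhibitory"), z, 50)$Po,
    numeric(1))
  expect_true(all(diff(po_sup) > 0))
  expect_true(all(diff(po_inh) < 0))
  # saturating PIP2 shuts the inhibitory-mode channel
  expect_lt(steady_state(gating_params(polarity = "inhibitory"),
                         1e5, 50)$Po, 1e-10)
})

test_that("disconnected chain is flagged degenerate, not an error", {
  p <- gating_params(beta_max = 0, alpha = 0, k_off = 10)
  ss <- steady_state(p, pip2 = 0, dag = 0)
  expect_true(ss$degenerate)
})

test_that("master-equation integration conserves occupancy and relaxes to equilibrium", {
  p <- gating_params(kd_pip2 = 2, k_off = 10, beta_max = 60, alpha = 10)
  lip <- tibble::tibble(time_s = seq(0, 5, 0.005), pip2_uM = 4, dag_uM = 50)
  # start far from equilibrium: everything in C0
  sim <- simulate_gating(p, lip, init = c(1, 0, 0, 0, 0, 0))
  expect_lt(attr(sim, "mass_defect"), 1e-9)
  expect_true(all(as.matrix(sim[, c("C0", "C1", "C2", "C3", "C4", "O")]) >
                    -1e-12))
  ss <- steady_state(p, 4, 50)
  expect_equal(dplyr::last(sim$Po), ss$Po, tolerance = 1e-6)
})

test_that("step depletion of PIP2 gives monotone Po loss in supportive mode", {
  p <- gating_params()
  tt <- seq(0, 2, 0.002)
  lip <- tibble::tibble(time_s = tt, pip2_uM = ifelse(tt < 0.2, 10, 0),
                        dag_uM = 50)
  sim <- simulate_gating(p, lip)
  po_after <- sim$Po[sim$time_s >= 0.21]
  expect_true(all(diff(po_after) < 1e-10))
  expect_error(
    simulate_gating(p, lip, times = c(0, 0.5, 0.5, 1)),
    class = "pipgate_error_nonmonotone_time")
})

test_that("Gillespie oracle agrees with the ODE solution and is reproducible", {
  p <- gating_params(kd_pip2 = 2, k_off = 2, beta_max = 12, alpha = 5)
  lip <- tibble::tibble(time_s = c(0, 2), pip2_uM = 2, dag_uM = 50)
  checkpoints <- seq(0.1, 2, length.out = 20)
  n_ch <- 10000L
  # start all channels in C2 so the transient is informative
  init <- c(0, 0, 1, 0, 0, 0)
  g1 <- gillespie_gating(p, lip, n_channels = n_ch, seed = 7,
                         record_times = checkpoints, init = init)
  g2 <- gillespie_gating(p, lip, n_channels = n_ch, seed = 7,
                         record_times = checkpoints, init = init)
  expect_identical(g1, g2)  # same seed, same trajectory
  ode <- simulate_gating(p, lip, times = c(0, checkpoints), init = init)
  po_ode <- ode$Po[-1]
  se <- sqrt(pmax(po_ode * (1 - po_ode), 1e-12) / n_ch)
  expect_true(all(abs(g1$Po - po_ode) <= 3 * se + 1e-9))
})

test_that("single channel with no ligand and shut gate stays in C0", {
  p <- gating_params(beta_max = 0, alpha = 0, k_off = 10)
  lip <- tibble::tibble(time_s = c(0, 1), pip2_uM = 0, dag_uM = 0)
  g <- gillespie_gating(p, lip, n_channels = 1L, seed = 3,
                        record_times = seq(0.1, 1, 0.1),
                        init = c(1, 0, 0, 0, 0, 0))
  expect_true(all(g$C0 == 1))
  expect_true(all(g$Po == 0))
})
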