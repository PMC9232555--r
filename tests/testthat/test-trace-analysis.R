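# Fitting pipeline: exactness on noiseless input, honesty on degenerate
# input, oracle agreement under noise, scaling invariance.

test_that("logistic decay fit recovers generating parameters exactly", {
  cases <- list(c(t_half = 0.229, f_s = 0.040),
                c(t_half = 0.092, f_s = 0.020),
                c(t_half = 0.054, f_s = 0.012))
  for (cs in cases) {
    df <- make_logistic_decay(cs[["t_half"]], cs[["f_s"]])
    fit <- fit_decay(df)
    expect_true(fit$converged)
    est <- tidy(fit)
    expect_equal(est$estimate[est$term == "t_half_ms"],
                 1000 * cs[["t_half"]], tolerance = 1e-3)
    expect_equal(est$estimate[est$term == "f_s_ms"],
                 1000 * cs[["f_s"]], tolerance = 1e-3)
  }
})

test_that("flat or too-short decay segments are reported, not fabricated", {
  flat <- tibble::tibble(time_s = seq(0, 0.7, 0.001), value = 1.5)
  fit <- fit_decay(flat)
  expect_false(fit$converged)
  expect_match(fit$reason, "no decay")
  short <- make_logistic_decay(0.2, 0.04)[1:10, ]
  expect_false(fit_decay(short)$converged)
  expect_error(fit_decay(flat, value_col = "nope"),
               class = "pipgate_error_missing_column")
})

test_that("noisy decay fits are unbiased and agree with a grid-search oracle", {
  truth <- c(t_half = 0.229, f_s = 0.040)
  base <- make_logistic_decay(truth[["t_half"]], truth[["f_s"]])
  rel_err <- vapply(1:200, function(s) {
    set.seed(s)
    noisy <- base
    noisy$value <- noisy$value + rnorm(nrow(base), sd = 0.05 * 1.8)
    fit <- fit_decay(noisy)
    if (!fit$converged) return(NA_real_)
    abs(tidy(fit)$estimate[1] - 229) / 229
  }, numeric(1))
  expect_lt(median(rel_err, na.rm = TRUE), 0.05)

  # one representative noisy fit agrees with brute-force grid search to a cell
  set.seed(11)
  noisy <- base
  noisy$value <- noisy$value + rnorm(nrow(base), sd = 0.05 * 1.8)
  fit <- fit_decay(noisy)
  grid <- oracle_grid_decay(noisy$time_s, noisy$value,
                            t_half_grid = seq(0.15, 0.31, by = 0.004),
                            f_s_grid = seq(0.02, 0.08, by = 0.002))
  expect_lt(abs(tidy(fit)$estimate[1] / 1000 - grid$t_half), 0.004)
  expect_lt(abs(tidy(fit)$estimate[2] / 1000 - grid$f_s), 0.002)
})

test_that("exponential recovery fit is exact and matches the log-linear oracle", {
  for (tau in c(2.01, 4.78)) {
    df <- make_exp_recovery(tau, t_end = max(10, 3 * tau))
    fit <- fit_recovery(df)
    expect_true(fit$converged)
    expect_equal(tidy(fit)$estimate[1], tau, tolerance = 1e-3)
    # log-linear regression on |I - I_0| recovers -1/tau as the slope
    resid <- df$value - (-1)
    sl <- unname(coef(lm(log(abs(resid)) ~ df$time_s))[2])
    expect_equal(sl, -1 / tau, tolerance = 1e-8)
  }
  flat <- tibble::tibble(time_s = seq(0, 10, 0.01), value = -1)
  expect_false(fit_recovery(flat)$converged)
})

test_that("kinetic fits are invariant to linear rescaling of the observable", {
  df <- make_logistic_decay(0.229, 0.04)
  f1 <- tidy(fit_decay(df))
  df2 <- df; df2$value <- 3.7 * df2$value + 0.9
  f2 <- tidy(fit_decay(df2))
  expect_equal(f1$estimate[1:2], f2$estimate[1:2], tolerance = 1e-6)

  dr <- make_exp_recovery(2.01)
  r1 <- tidy(fit_recovery(dr))
  dr2 <- dr; dr2$value <- -2 * dr2$value + 0.25
  r2 <- tidy(fit_recovery(dr2))
  expect_equal(r1$estimate[1], r2$estimate[1], tolerance = 1e-6)
})

test_that("Hill fit recovers truth exactly, checks preconditions, flags non-saturation", {
  dr <- generate_dose_response(ec50 = 46, hill_n = 0.8, r_max = 1,
                               sd = 0, n_per_conc = 1, seed = 1)
  fit <- hill_fit(dr)
  expect_true(fit$converged)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "ec50_uM"], 46, tolerance = 1e-6)
  expect_equal(est$estimate[est$term == "hill_n"], 0.8, tolerance = 1e-6)
  # response at C = EC50 is r_max / 2 by definition
  cf <- setNames(est$estimate, est$term)
  expect_equal(cf[["r_max"]] * 46^cf[["hill_n"]] /
                 (cf[["ec50_uM"]]^cf[["hill_n"]] + 46^cf[["hill_n"]]),
               cf[["r_max"]] / 2, tolerance = 1e-9)

  expect_error(hill_fit(dr[dr$conc_uM < 1, ]),
               class = "pipgate_error_precondition")

  # concentrations far below EC50: no saturation information
  ns <- generate_dose_response(ec50 = 5000, hill_n = 1, r_max = 1,
                               concentrations = c(0.01, 0.1, 1, 3),
                               sd = 0, n_per_conc = 1, seed = 2)
  expect_false(hill_fit(ns)$converged)
})

test_that("noisy Hill fits agree with a grid-search oracle within one cell", {
  set.seed(5)
  dr <- generate_dose_response(seed = 5)
  fit <- hill_fit(dr)
  grid <- oracle_grid_hill(dr$conc_uM, dr$response,
                           ec50_grid = seq(20, 90, by = 2),
                           n_grid = seq(0.4, 1.6, by = 0.05))
  expect_lt(abs(tidy(fit)$estimate[1] - grid$ec50), 2)
  expect_lt(abs(tidy(fit)$estimate[2] - grid$hill_n), 0.05)
})

test_that("fit accessors expose broom-style tidy and glance", {
  fit <- fit_decay(make_logistic_decay(0.2, 0.04))
  expect_named(tidy(fit), c("term", "estimate"))
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$model, "logistic_decay")
  expect_gt(g$n, 20)
})
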