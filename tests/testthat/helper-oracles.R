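# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: closed forms from detailed balance, grid search
# for the nonlinear fits, and direct textbook formulas.

# Detailed-balance steady state of the tetrameric scheme: closed-state
# weights are binomial in x = pip2/Kd; the open-state weight is x^4 * theta
# (supportive) or theta (inhibitory), theta = beta/alpha.
oracle_steady_po <- function(x, theta, polarity = "supportive") {
  w_closed <- choose(4, 0:4) * x^(0:4)
  w_open <- if (polarity == "supportive") x^4 * theta else theta
  w_open / (sum(w_closed) + w_open)
}

oracle_steady_occupancy <- function(x, theta, polarity = "supportive") {
  w <- c(choose(4, 0:4) * x^(0:4),
         if (polarity == "supportive") x^4 * theta else theta)
  w / sum(w)
}

# brute-force grid search for the logistic decay (t_half, f_s at fixed
# conditional linear parameters via least squares)
oracle_grid_decay <- function(t, v, t_half_grid, f_s_grid) {
  best <- NULL
  for (th in t_half_grid) for (fs in f_s_grid) {
    basis <- 1 / (1 + exp((t - th) / fs))
    fit <- stats::lm(v ~ basis)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(t_half = th, f_s = fs, rss = rss)
    }
  }
  best
}

# grid-search oracle for the Hill fit (EC50, n at conditional r_max)
oracle_grid_hill <- function(conc, resp, ec50_grid, n_grid) {
  best <- NULL
  for (ec in ec50_grid) for (h in n_grid) {
    basis <- conc^h / (ec^h + conc^h)
    fit <- stats::lm(resp ~ 0 + basis)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(ec50 = ec, hill_n = h, rss = rss)
    }
  }
  best
}

# noiseless generators for the two fit equations (field convention)
make_logistic_decay <- function(t_half_s, f_s_s, i_min = 0.2, i_d = 1.8,
                                dt = 0.001, t_end = 0.7) {
  tt <- seq(0, t_end, by = dt)
  tibble::tibble(time_s = tt,
                 value = i_min + i_d / (1 + exp((tt - t_half_s) / f_s_s)))
}

make_exp_recovery <- function(tau_s, i_0 = -1, a = 0.5, dt = 0.01,
                              t_end = 10) {
  tt <- seq(0, t_end, by = dt)
  tibble::tibble(time_s = tt, value = i_0 + a * exp(-tt / tau_s))
}

# standard single-pulse episode used by simulation tests
episode_protocol <- function(first_pulse_s = 2) {
  voltage_protocol(n_pulses = 1L, first_pulse_s = first_pulse_s)
}

# noiseless single-pulse WT-style current trace from explicit parameters
simulate_episode_trace <- function(gating, vsp = vsp_params(),
                                   protocol = episode_protocol(),
                                   t_end = 16, oag_uM = 50) {
  tt <- sample_times(protocol, t_end)
  pip2 <- simulate_vsp_episode(vsp, protocol, times = tt)
  lipids <- tibble::tibble(time_s = tt, pip2_uM = pip2$pip2_uM,
                           dag_uM = oag_uM)
  sim <- simulate_gating(gating, lipids, protocol, times = tt)
  tibble::tibble(time_s = tt, current_nA = sim$current_nA,
                 voltage_mV = sim$voltage_mV)
}
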