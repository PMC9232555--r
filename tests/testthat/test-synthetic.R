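# Synthetic data generator: determinism, embedded truth, noiseless
# self-consistency, and the study-shaped phenotypes.

test_that("trace generation is deterministic given seed and cell index", {
  prot <- voltage_protocol(n_pulses = 2, first_pulse_s = 1, period_s = 6)
  spec <- construct_spec("WT", n_cells = 1)
  t1 <- generate_cell_trace(spec, 3, prot, noise_model(0.02, 0, 99),
                            duration_s = 14)
  t2 <- generate_cell_trace(spec, 3, prot, noise_model(0.02, 0, 99),
                            duration_s = 14)
  expect_identical(t1$current_nA, t2$current_nA)
  # different cell index: different truth and residuals
  t3 <- generate_cell_trace(spec, 4, prot, noise_model(0.02, 0, 99),
                            duration_s = 14)
  expect_false(identical(t1$current_nA, t3$current_nA))
  expect_false(trace_meta(t1)$truth$onset_half_s ==
                 trace_meta(t3)$truth$onset_half_s)
  # changing only the noise seed preserves the generating truth
  t4 <- generate_cell_trace(construct_spec("WT", n_cells = 1,
                                           cell_variability_cv = 0),
                            3, prot, noise_model(0.02, 0, 99),
                            duration_s = 14)
  t5 <- generate_cell_trace(construct_spec("WT", n_cells = 1,
                                           cell_variability_cv = 0),
                            3, prot, noise_model(0.02, 0, 100),
                            duration_s = 14)
  expect_equal(trace_meta(t4)$truth$gating$k_off,
               trace_meta(t5)$truth$gating$k_off)
})

test_that("every generated artifact embeds its generating truth", {
  prot <- voltage_protocol(n_pulses = 1, first_pulse_s = 1)
  tr <- generate_cell_trace(construct_spec("R437Q", n_cells = 1), 1, prot,
                            noise_model(0, 0, 5), duration_s = 10)
  m <- trace_meta(tr)
  expect_equal(m$construct, "R437Q")
  expect_equal(m$truth$gating$kd_pip2, 10)
  expect_true(all(c("onset_half_s", "analysis_pulses", "po_ref") %in%
                    names(m$truth)))
  fr <- generate_fret_trace()
  expect_equal(trace_meta(fr)$truth$vsp$k_rec, 1 / 5.66)
  dr <- generate_dose_response(seed = 2)
  expect_equal(attr(dr, "pipgate_meta")$truth$ec50_uM, 46)
})

test_that("per-cell parameter draws have the specified lognormal structure", {
  spec <- construct_spec("WT", cell_variability_cv = 0.15, n_cells = 200)
  draws <- purrr::map(1:200, ~draw_cell_parameters(spec, .x, 31L))
  koff <- vapply(draws, function(d) d$gating$k_off, numeric(1))
  alpha <- vapply(draws, function(d) d$gating$alpha, numeric(1))
  kd <- vapply(draws, function(d) d$gating$kd_pip2, numeric(1))
  onset <- vapply(draws, function(d) d$onset_half_s, numeric(1))
  base <- trpc6_preset("WT")
  # mean multiplier 1 within 3 SE (SE = cv/sqrt(n)); Kd invariant by design
  se <- 0.15 / sqrt(200)
  expect_lt(abs(mean(koff) / base$k_off - 1), 3 * se)
  expect_lt(abs(mean(alpha) / base$alpha - 1), 3 * se)
  expect_equal(kd, rep(2, 200))
  expect_true(all(onset >= 30 & onset <= 120))
  # onset uniform mean 75, SE = 90/sqrt(12)/sqrt(200)
  expect_lt(abs(mean(onset) - 75), 3 * 90 / sqrt(12) / sqrt(200))
})

test_that("noiseless wild-type trace is self-consistent with its truth", {
  prot <- voltage_protocol(n_pulses = 2, first_pulse_s = 2, period_s = 14)
  spec <- construct_spec("WT", cell_variability_cv = 0, n_cells = 1)
  tr <- generate_cell_trace(spec, 1, prot, noise_model(0, 0, 1),
                            duration_s = 29, onset_half_s = 1e-3)
  pp <- analyze_pulses(tr, prot)
  expect_true(all(pp$decay_converged & pp$recovery_converged))
  # truth parameters equal the preset (cv = 0)
  m <- trace_meta(tr)
  wt <- trpc6_preset("WT")
  expect_equal(m$truth$gating$k_off, wt$k_off)
  # pre-pulse current near the -1 nA calibration on the plateau pulse
  expect_lt(abs(abs(pp$I_pre_nA[2]) - 1), 0.35)
})

test_that("polarity-switched construct is potentiated by the VSP pulse", {
  prot <- voltage_protocol(n_pulses = 2, first_pulse_s = 2, period_s = 14)
  spec <- construct_spec("K771Q", cell_variability_cv = 0, n_cells = 1)
  tr <- generate_cell_trace(spec, 1, prot, noise_model(0, 0, 1),
                            duration_s = 29, onset_half_s = 1e-3)
  rr <- inhibition_ratio(tr, prot)
  expect_true(all(rr$inhibition_ratio > 1))
})

test_that("panel generation enforces unique labels and returns truth rows", {
  prot <- voltage_protocol(n_pulses = 1, first_pulse_s = 1)
  s1 <- construct_spec("WT", n_cells = 2)
  expect_error(generate_panel(list(s1, s1), prot),
               class = "pipgate_error_precondition")
  expect_error(generate_panel(list(), prot),
               class = "pipgate_error_precondition")
  dead <- construct_spec("K75Q", n_cells = 2, no_current = TRUE)
  pan <- generate_panel(list(s1, dead), prot, noise_model(0, 0, 2),
                        duration_s = 8)
  expect_equal(nrow(pan$truth), 4)
  expect_equal(length(pan$traces), 2)  # dead construct contributes no traces
  expect_true(all(pan$truth$no_current[pan$truth$construct == "K75Q"]))
})

test_that("FRET trace scaling leaves fitted kinetics unchanged", {
  prot <- voltage_protocol(n_pulses = 1, first_pulse_s = 2)
  tt <- sample_times(prot, 20)
  f1 <- generate_fret_trace(vsp_params(), prot, scale = 1, times = tt)
  f2 <- generate_fret_trace(vsp_params(), prot, scale = 2, offset = 3,
                            times = tt)
  k1 <- fit_fret_episode(f1)
  k2 <- fit_fret_episode(f2)
  expect_equal(tidy(k1$depletion)$estimate[1],
               tidy(k2$depletion)$estimate[1], tolerance = 1e-6)
  expect_equal(tidy(k1$replenishment)$estimate[1],
               tidy(k2$replenishment)$estimate[1], tolerance = 1e-6)
})

test_that("noisy FRET replicates recover the replenishment constant", {
  prot <- voltage_protocol(n_pulses = 1, first_pulse_s = 2)
  tt <- sample_times(prot, 20)
  taus <- vapply(1:50, function(s) {
    fr <- generate_fret_trace(vsp_params(), prot,
                              noise_model(0.02, 0, s), times = tt)
    fit <- fit_fret_episode(fr)$replenishment
    if (fit$converged) tidy(fit)$estimate[1] else NA_real_
  }, numeric(1))
  expect_lt(abs(median(taus, na.rm = TRUE) - 5.66) / 5.66, 0.10)
})

test_that("dose-response generator matches the Hill equation exactly when noiseless", {
  dr <- generate_dose_response(ec50 = 46, hill_n = 0.8, r_max = 1, sd = 0,
                               n_per_conc = 1, seed = 9)
  mu <- 1 * dr$conc_uM^0.8 / (46^0.8 + dr$conc_uM^0.8)
  expect_equal(dr$response, mu, tolerance = 1e-12)
  # replicate counts fall in the stated 12-25 range when drawn
  dr2 <- generate_dose_response(seed = 10)
  counts <- dplyr::count(dr2, conc_uM)$n
  expect_true(all(counts >= 12 & counts <= 25))
  expect_error(generate_dose_response(concentrations = c(-1, 1, 10, 100)),
               class = "pipgate_error_precondition")
})

test_that("EC50 recovery bias is small at study replication over many seeds", {
  est <- vapply(1:100, function(s) {
    dr <- generate_dose_response(seed = s)
    fit <- hill_fit(dr)
    if (fit$converged) tidy(fit)$estimate[1] else NA_real_
  }, numeric(1))
  # EC50 sampling distributions are right-skewed; the median is the
  # appropriate center for a concentration-scale parameter
  expect_lt(abs(median(est, na.rm = TRUE) - 46) / 46, 0.10)
})
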