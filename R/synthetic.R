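# Study-shaped synthetic data: whole-cell current traces under the VSP pulse
# protocol, FRET-reported PIP2 traces, mutant panels and dose-response tables.
# Every artifact embeds its generating truth so parameter-recovery tests need
# no bookkeeping outside the object.

#' Construct specification for a synthetic mutant panel
#'
#' Describes one channel construct (wild type or mutant): its gating
#' parameters, the per-cell biological variability, and how many cells to
#' simulate.  Per-cell variability is lognormal (mean 1, coefficient of
#' variation `cell_variability_cv`) applied to `k_off` (with `k_on` tied so
#' `kd_pip2` is preserved) and to `alpha`.
#'
#' @param label Construct label (e.g. `"WT"`, `"R437Q"`); must be non-empty.
#' @param gating A [gating_params()]; defaults to [trpc6_preset()] when
#'   `label` is a known preset, otherwise the wild-type preset.
#' @param cell_variability_cv Lognormal coefficient of variation (>= 0).
#' @param n_cells Number of cells (>= 1).
#' @param no_current Mark the construct as carrying no OAG-evoked current
#'   (distal N-terminal phenotype); such cells are flagged, not simulated.
#' @return An object of class `construct_spec`.
#' @export
construct_spec <- function(label, gating = NULL, cell_variability_cv = 0.15,
                           n_cells = 6L, no_current = FALSE) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort("`label` must be a non-empty string.",
          class = "pipgate_error_precondition")
  }
  check_nonneg(cell_variability_cv, "cell_variability_cv")
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) abort("`n_cells` must be >= 1.",
                          class = "pipgate_error_precondition")
  if (is.null(gating)) {
    gating <- if (label %in% c("WT", "R437Q", "K442Q", "K771Q")) {
      trpc6_preset(label)
    } else trpc6_preset("WT")
  }
  stopifnot(inherits(gating, "gating_params"))
  structure(
    list(label = label, gating = gating,
         cell_variability_cv = cell_variability_cv,
         n_cells = n_cells, no_current = isTRUE(no_current)),
    class = "construct_spec"
  )
}

#' Recording noise model
#'
#' @param sigma_current_nA Gaussian white-noise SD added to the current (nA);
#'   for FRET traces the same field is interpreted in ratio units.
#' @param baseline_drift_nA_s Linear baseline drift (nA/s).
#' @param rng_seed Integer base seed; per-cell streams are derived from it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_current_nA = 0.02, baseline_drift_nA_s = 0,
                        rng_seed = 1L) {
  check_nonneg(sigma_current_nA, "sigma_current_nA")
  structure(
    list(sigma_current_nA = sigma_current_nA,
         baseline_drift_nA_s = baseline_drift_nA_s,
         rng_seed = as.integer(rng_seed)),
    class = "noise_model"
  )
}

#' Trace metadata
#'
#' Returns the metadata list attached to a generated or read trace
#' (schema version, kind, construct, protocol, generating truth, seed).
#'
#' @param trace A trace tibble.
#' @return A list (possibly empty).
#' @export
trace_meta <- function(trace) {
  m <- attr(trace, "pipgate_meta")
  if (is.null(m)) list() else m
}

new_trace <- function(df, meta, kind) {
  attr(df, "pipgate_meta") <- meta
  class(df) <- c(paste0(kind, "_trace"), class(df))
  df
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Draw per-cell generating parameters
#'
#' Deterministically derives one cell's gating parameters and OAG-onset
#' half-time from the construct spec and the `(rng_seed, cell_index)` pair:
#' lognormal (mean 1, CV `cell_variability_cv`) multipliers on `k_off` (with
#' `k_on` tied so `kd_pip2` is unchanged) and on `alpha`, and an onset
#' half-time uniform on 30-120 s.  This is the exact draw used by
#' [generate_cell_trace()], exposed so parameter-recovery tests can examine
#' the generating distribution without simulating traces.
#'
#' @param spec A [construct_spec()].
#' @param cell_index Positive integer.
#' @param rng_seed Base integer seed (the [noise_model()] seed).
#' @return A list with `gating` ([gating_params()]), `onset_half_s`,
#'   `cell_factors` and the derived `seed`.
#' @export
draw_cell_parameters <- function(spec, cell_index, rng_seed) {
  stopifnot(inherits(spec, "construct_spec"))
  cell_index <- as.integer(cell_index)
  if (cell_index < 1L) abort("`cell_index` must be >= 1.",
                             class = "pipgate_error_precondition")
  seed <- derive_seed(rng_seed, cell_index)
  set.seed(seed)
  onset_half_s <- runif(1L, 30, 120)
  fac <- rlnorm_cv(2L, spec$cell_variability_cv)
  g0 <- spec$gating
  gating <- gating_params(
    kd_pip2 = g0$kd_pip2, k_off = g0$k_off * fac[1L],
    beta_max = g0$beta_max, alpha = g0$alpha * fac[2L],
    dag_ec50 = g0$dag_ec50, dag_hill = g0$dag_hill, polarity = g0$polarity,
    pip2_independent_fraction = g0$pip2_independent_fraction,
    g_total = g0$g_total, e_rev = g0$e_rev)
  list(gating = gating, onset_half_s = onset_half_s,
       cell_factors = list(k_off = fac[1L], alpha = fac[2L]), seed = seed)
}

#' Generate one synthetic whole-cell current trace
#'
#' Simulates an OAG-activated recording: the current rises along a logistic
#' OAG-onset curve whose half-time is drawn per cell from 30-120 s, while
#' depolarizing pulses (the VSP episode) transiently deplete PIP2.  Per-cell
#' kinetic variability is applied per [construct_spec()], the lipid course
#' comes from [simulate_vsp_episode()], gating from [simulate_gating()], and
#' Gaussian noise plus optional baseline drift is added on the two-rate
#' sampling grid (1 ms inside pulse windows, 50 ms elsewhere).  The trace is
#' deterministic given `(noise$rng_seed, cell_index)`; the metadata records
#' the generating truth, including which pulses lie on the OAG plateau
#' (`analysis_pulses`).
#'
#' @param spec A [construct_spec()].
#' @param cell_index Positive integer identifying the cell within the
#'   construct; part of the RNG stream.
#' @param protocol A [voltage_protocol()].
#' @param noise A [noise_model()].
#' @param vsp A [vsp_params()]; use `k_vsp = 0` for the inactive-VSP control.
#' @param oag_uM Bath OAG concentration (uM).
#' @param duration_s Trace duration; defaults to cover the whole pulse train.
#' @param onset_half_s Override for the OAG-onset half-time (s); `NULL`
#'   draws it from 30-120 s as in a recorded cell.  Setting a small value
#'   puts every pulse on the OAG plateau, which is convenient when testing
#'   the analysis mechanics rather than emulating a recording.
#' @param fine_dt_s,coarse_dt_s Two-rate sampling intervals (s).
#' @return A `current_trace` tibble with `time_s`, `current_nA`,
#'   `voltage_mV`; metadata via [trace_meta()].
#' @export
generate_cell_trace <- function(spec, cell_index = 1L,
                                protocol = voltage_protocol(n_pulses = 9L),
                                noise = noise_model(),
                                vsp = vsp_params(), oag_uM = 50,
                                duration_s = NULL, onset_half_s = NULL,
                                fine_dt_s = 0.001, coarse_dt_s = 0.05) {
  stopifnot(inherits(spec, "construct_spec"), inherits(noise, "noise_model"),
            inherits(protocol, "voltage_protocol"), inherits(vsp, "vsp_params"))
  cell_index <- as.integer(cell_index)
  if (cell_index < 1L) abort("`cell_index` must be >= 1.",
                             class = "pipgate_error_precondition")
  if (is.null(duration_s)) {
    duration_s <- protocol$first_pulse_s +
      protocol$n_pulses * protocol$period_s + 2
  }
  pulses <- protocol_pulses(protocol)
  if (nrow(pulses) && max(pulses$end_s) > duration_s) {
    abort("protocol pulses extend past the trace duration.",
          class = "pipgate_error_precondition")
  }
  draw <- draw_cell_parameters(spec, cell_index, noise$rng_seed)
  seed <- draw$seed
  if (is.null(onset_half_s)) onset_half_s <- draw$onset_half_s
  fac <- c(draw$cell_factors$k_off, draw$cell_factors$alpha)
  cell_gating <- draw$gating
  set.seed(derive_seed(seed, 1L))  # noise stream, distinct from the draw

  tt <- sample_times(protocol, duration_s, fine_dt_s = fine_dt_s,
                     coarse_dt_s = coarse_dt_s)
  pip2 <- simulate_vsp_episode(vsp, protocol, times = tt)
  dag <- oag_uM / (1 + exp(-(tt - onset_half_s) / (onset_half_s / 8)))
  lipids <- tibble(time_s = tt, pip2_uM = pip2$pip2_uM, dag_uM = dag)

  po_ref <- steady_state(cell_gating, vsp$pip2_rest, oag_uM)$Po
  sim <- simulate_gating(cell_gating, lipids, protocol, times = tt,
                         po_ref = po_ref)
  cur <- sim$current_nA
  if (noise$sigma_current_nA > 0) {
    cur <- cur + rnorm(length(cur), sd = noise$sigma_current_nA)
  }
  cur <- cur + noise$baseline_drift_nA_s * tt

  # pulses on the OAG plateau (2-4 nearest the peak response)
  dag_at_pulse <- oag_uM /
    (1 + exp(-(pulses$start_s - onset_half_s) / (onset_half_s / 8)))
  plateau <- pulses$pulse[dag_at_pulse >= 0.90 * oag_uM]
  if (length(plateau) < 2L && nrow(pulses) >= 2L) {
    plateau <- tail(pulses$pulse, 2L)
  }
  plateau <- tail(plateau, 4L)

  meta <- list(
    schema_version = "1.0", kind = "current", construct = spec$label,
    seed = seed, cell_index = cell_index, protocol = protocol,
    sampling = list(fine_dt_s = fine_dt_s, coarse_dt_s = coarse_dt_s),
    truth = list(
      gating = unclass(cell_gating), vsp = unclass(vsp),
      oag_uM = oag_uM, onset_half_s = onset_half_s,
      cell_factors = list(k_off = fac[1L], alpha = fac[2L]),
      po_ref = po_ref, analysis_pulses = plateau,
      noise = unclass(noise))
  )
  new_trace(tibble(time_s = tt, current_nA = cur,
                   voltage_mV = sim$voltage_mV),
            meta, "current")
}

#' Generate a mutant panel of synthetic traces
#'
#' One trace per cell per construct, plus a truth table of the generating
#' parameters.  Constructs marked `no_current` contribute truth rows flagged
#' `no_current` but no traces.
#'
#' @param specs List of [construct_spec()] objects with unique labels.
#' @param protocol A [voltage_protocol()].
#' @param noise A [noise_model()]; each cell gets a derived seed.
#' @param ... Passed on to [generate_cell_trace()].
#' @return A list with `traces` (named list of `current_trace`s) and `truth`
#'   (tibble: construct, cell, generating parameters).
#' @export
generate_panel <- function(specs, protocol = voltage_protocol(n_pulses = 9L),
                           noise = noise_model(), ...) {
  if (inherits(specs, "construct_spec")) specs <- list(specs)
  if (!length(specs)) abort("at least one construct spec is required.",
                            class = "pipgate_error_precondition")
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    abort("construct labels must be unique within a panel.",
          class = "pipgate_error_precondition")
  }
  traces <- list()
  truth <- list()
  cell_counter <- 0L
  for (sp in specs) {
    for (ci in seq_len(sp$n_cells)) {
      cell_counter <- cell_counter + 1L
      id <- sprintf("%s_cell%02d", sp$label, ci)
      if (sp$no_current) {
        truth[[id]] <- tibble(construct = sp$label, cell = ci,
                              no_current = TRUE, kd_pip2_uM = NA_real_,
                              k_off_s = NA_real_, alpha_s = NA_real_,
                              onset_half_s = NA_real_, seed = NA_integer_)
        next
      }
      # distinct stream per (construct, cell): offset cells across constructs
      cell_noise <- noise_model(noise$sigma_current_nA,
                                noise$baseline_drift_nA_s,
                                derive_seed(noise$rng_seed,
                                            match(sp$label, labels) * 1000L))
      tr <- generate_cell_trace(sp, ci, protocol, cell_noise, ...)
      m <- trace_meta(tr)
      traces[[id]] <- tr
      truth[[id]] <- tibble(
        construct = sp$label, cell = ci, no_current = FALSE,
        kd_pip2_uM = m$truth$gating$kd_pip2,
        k_off_s = m$truth$gating$k_off,
        alpha_s = m$truth$gating$alpha,
        onset_half_s = m$truth$onset_half_s,
        seed = m$seed)
    }
  }
  list(traces = traces, truth = dplyr::bind_rows(truth))
}

#' Generate a synthetic FRET-reported PIP2 trace
#'
#' Emits the VSP-episode PIP2 time course as a FRET-like ratio
#' `ratio = offset + scale * pip2 / pip2_rest` (a monotone linear transform,
#' so fitted depletion/replenishment kinetics are unchanged), with optional
#' Gaussian noise.
#'
#' @param vsp A [vsp_params()].
#' @param protocol A [voltage_protocol()].
#' @param noise A [noise_model()]; `sigma_current_nA` is read in ratio units.
#' @param scale,offset Linear transform of normalized PIP2.
#' @param times Sample times; defaults to the [simulate_vsp_episode()] grid.
#' @return A `fret_trace` tibble with `time_s`, `ratio`, `voltage_mV`.
#' @export
generate_fret_trace <- function(vsp = vsp_params(),
                                protocol = voltage_protocol(n_pulses = 1L),
                                noise = noise_model(sigma_current_nA = 0),
                                scale = 1, offset = 0.5, times = NULL) {
  stopifnot(inherits(vsp, "vsp_params"), inherits(protocol, "voltage_protocol"))
  pip2 <- simulate_vsp_episode(vsp, protocol, times = times)
  ratio <- offset + scale * pip2$pip2_uM / vsp$pip2_rest
  seed <- derive_seed(noise$rng_seed, 424242L)
  if (noise$sigma_current_nA > 0) {
    set.seed(seed)
    ratio <- ratio + rnorm(length(ratio), sd = noise$sigma_current_nA)
  }
  meta <- list(
    schema_version = "1.0", kind = "fret", construct = "PIP2_sensor",
    seed = seed, protocol = protocol,
    truth = list(vsp = unclass(vsp), scale = scale, offset = offset,
                 noise = unclass(noise))
  )
  new_trace(tibble(time_s = pip2$time_s, ratio = ratio,
                   voltage_mV = protocol_voltage(protocol, pip2$time_s)),
            meta, "fret")
}

#' Generate a synthetic dose-response table
#'
#' Hill-equation responses (e.g. Fura-2 delta-ratio vs OAG concentration)
#' with Gaussian noise and per-concentration replicate counts drawn from
#' 12-25 unless given.
#'
#' @param ec50 Half-maximal concentration (uM).
#' @param hill_n Hill coefficient.
#' @param r_max Maximal response.
#' @param concentrations Tested concentrations (uM, > 0).
#' @param sd Gaussian per-replicate noise SD (response units); 0 for
#'   noiseless.
#' @param n_per_conc Replicates per concentration; single number, vector, or
#'   `NULL` to draw from 12-25.
#' @param seed Integer seed.
#' @return A tibble with `conc_uM`, `replicate`, `response`; generating truth
#'   in attribute `pipgate_meta`.
#' @export
generate_dose_response <- function(ec50 = 46, hill_n = 0.8, r_max = 1,
                                   concentrations = c(0.01, 0.1, 1, 10, 30, 100),
                                   sd = 0.05, n_per_conc = NULL, seed = 1L) {
  check_pos(ec50, "ec50")
  check_pos(hill_n, "hill_n")
  check_pos(r_max, "r_max")
  check_nonneg(sd, "sd")
  if (any(concentrations <= 0)) {
    abort("`concentrations` must be positive.",
          class = "pipgate_error_precondition")
  }
  set.seed(as.integer(seed))
  k <- length(concentrations)
  n_per_conc <- if (is.null(n_per_conc)) {
    sample(12:25, k, replace = TRUE)
  } else rep_len(n_per_conc, k)
  mu <- r_max * concentrations^hill_n / (ec50^hill_n + concentrations^hill_n)
  out <- purrr::map_dfr(seq_len(k), function(i) {
    tibble(conc_uM = concentrations[i],
           replicate = seq_len(n_per_conc[i]),
           response = mu[i] + if (sd > 0) rnorm(n_per_conc[i], sd = sd) else 0)
  })
  attr(out, "pipgate_meta") <- list(
    schema_version = "1.0", kind = "dose_response", seed = as.integer(seed),
    truth = list(ec50_uM = ec50, hill_n = hill_n, r_max = r_max, sd = sd))
  out
}
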