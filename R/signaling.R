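#' Voltage-sensitive phosphatase (VSP) episode parameters
#'
#' While the command potential is at or above `activation_threshold_mV` the
#' phosphatase dephosphorylates PIP2 at rate `k_vsp` toward a residual floor;
#' at rest, PIP2 is replenished toward `pip2_rest` at rate `k_rec`:
#' `d[PIP2]/dt = -k_vsp * a(V) * ([PIP2] - floor * rest) + k_rec * (rest - [PIP2])`,
#' with `a(V)` a 0/1 step of the command voltage.  The shipped defaults are a
#' packaged calibration reproducing the reference FRET-measured PIP2
#' kinetics: depletion half-time about 135 ms during the +100 mV / 700 ms
#' step and replenishment time constant 5.66 s after repolarization.
#'
#' @param k_vsp Dephosphorylation rate while VSP is active (1/s).
#' @param k_rec Replenishment rate toward the resting level (1/s).
#' @param pip2_rest Resting PIP2 concentration (uM).
#' @param activation_threshold_mV Command potential at or above which the
#'   phosphatase is active.
#' @param depletion_floor Minimum attainable fraction of `pip2_rest`, in
#'   `[0, 1)`.
#' @return An object of class `vsp_params`.
#' @export
vsp_params <- function(k_vsp = 4.5184, k_rec = 1 / 5.66, pip2_rest = 16,
                       activation_threshold_mV = 50, depletion_floor = 0.15) {
  check_nonneg(k_vsp, "k_vsp")
  check_nonneg(k_rec, "k_rec")
  check_pos(pip2_rest, "pip2_rest")
  check_nonneg(depletion_floor, "depletion_floor")
  if (depletion_floor >= 1) {
    abort("`depletion_floor` must be < 1.", class = "pipgate_error_precondition")
  }
  structure(
    list(k_vsp = k_vsp, k_rec = k_rec, pip2_rest = pip2_rest,
         activation_threshold_mV = activation_threshold_mV,
         depletion_floor = depletion_floor),
    class = "vsp_params"
  )
}

#' @export
print.vsp_params <- function(x, ...) {
  cat(sprintf(
    "<vsp_params> k_vsp %.3g /s, k_rec %.3g /s, rest %.3g uM, floor %.3g, threshold %g mV\n",
    x$k_vsp, x$k_rec, x$pip2_rest, x$depletion_floor,
    x$activation_threshold_mV))
  invisible(x)
}

#' Simulate a VSP depolarization episode
#'
#' Computes the PIP2 time course under a pulse protocol from the linear
#' depletion/replenishment ODE in [vsp_params()].  Within each constant-
#' voltage interval the ODE is linear with constant coefficients, so the
#' exact piecewise-exponential solution is evaluated on the sampling grid
#' (no numerical integration error).
#'
#' @param vsp A [vsp_params()].
#' @param protocol A [voltage_protocol()].
#' @param times Output sample times; defaults to a [sample_times()] grid over
#'   the protocol plus a post-pulse tail.
#' @return A tibble with `time_s`, `pip2_uM` and `vsp_active`.
#' @examples
#' prot <- voltage_protocol(n_pulses = 1, first_pulse_s = 1)
#' pip2 <- simulate_vsp_episode(vsp_params(), prot)
#' @export
simulate_vsp_episode <- function(vsp, protocol, times = NULL) {
  stopifnot(inherits(vsp, "vsp_params"), inherits(protocol, "voltage_protocol"))
  if (is.null(times)) {
    t_end <- protocol$first_pulse_s +
      protocol$n_pulses * protocol$period_s + 5
    times <- sample_times(protocol, t_end)
  }
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.",
          class = "pipgate_error_nonmonotone_time")
  }
  edges <- protocol_edges(protocol)
  if (protocol$n_pulses > 0L && protocol$pulse_dur_s < min(diff(times))) {
    abort("protocol contains a step shorter than one sampling interval.",
          class = "pipgate_error_precondition")
  }
  bounds <- c(min(times) - 1e-9, edges[edges > min(times) & edges < max(times)],
              max(times) + 1e-9)
  p_floor <- vsp$depletion_floor * vsp$pip2_rest
  p <- numeric(length(times))
  active <- logical(length(times))
  p0 <- vsp$pip2_rest
  for (k in seq_len(length(bounds) - 1L)) {
    idx <- times >= bounds[k] & times < bounds[k + 1L]
    t0 <- bounds[k]
    mid <- (bounds[k] + bounds[k + 1L]) / 2
    a <- as.numeric(protocol_voltage(protocol, mid) >=
                      vsp$activation_threshold_mV)
    rate <- vsp$k_vsp * a + vsp$k_rec
    p_inf <- if (rate > 0) {
      (vsp$k_vsp * a * p_floor + vsp$k_rec * vsp$pip2_rest) / rate
    } else p0
    if (any(idx)) {
      p[idx] <- p_inf + (p0 - p_inf) * exp(-rate * (times[idx] - t0))
      active[idx] <- a == 1
    }
    p0 <- p_inf + (p0 - p_inf) * exp(-rate * (bounds[k + 1L] - t0))
  }
  tibble(time_s = times, pip2_uM = p, vsp_active = active)
}

#' Receptor-PLC signaling cascade parameters
#'
#' Mass-action model of receptor-operated PIP2 hydrolysis: agonist applied
#' over `[agonist_on_time, agonist_on_time + agonist_duration)` activates PLC
#' (`k_plc_act`, first order toward full activation, deactivating at
#' `k_plc_deact` so the response is transient), which hydrolyzes PIP2 at rate
#' `k_hyd * PLC * [PIP2]`, producing one DAG and one IP3 per PIP2 consumed.
#' PIP2 is resynthesized toward `pip2_rest` at `k_pip2_synth` and DAG is
#' removed at `k_dag_deg`; IP3 is tracked for mass-balance bookkeeping only.
#'
#' @param agonist_on_time Time of agonist application (s).
#' @param agonist_duration Length of the agonist application (s).
#' @param k_plc_act,k_plc_deact PLC activation/deactivation rates (1/s).
#' @param k_hyd PIP2 hydrolysis rate per unit PLC activity (1/s).
#' @param k_dag_deg DAG removal rate (1/s).
#' @param k_pip2_synth PIP2 resynthesis rate (1/s).
#' @param pip2_rest Resting PIP2 concentration (uM).
#' @return An object of class `cascade_params`.
#' @export
cascade_params <- function(agonist_on_time = 20, agonist_duration = 40,
                           k_plc_act = 0.5,
                           k_plc_deact = 0.12, k_hyd = 0.19,
                           k_dag_deg = 0.0167, k_pip2_synth = 1 / 5.66,
                           pip2_rest = 19) {
  for (f in c("k_plc_act", "k_plc_deact", "k_hyd", "k_dag_deg",
              "k_pip2_synth")) {
    check_nonneg(get(f), f)
  }
  check_nonneg(agonist_on_time, "agonist_on_time")
  check_pos(agonist_duration, "agonist_duration")
  check_pos(pip2_rest, "pip2_rest")
  structure(
    list(agonist_on_time = agonist_on_time,
         agonist_duration = agonist_duration, k_plc_act = k_plc_act,
         k_plc_deact = k_plc_deact, k_hyd = k_hyd, k_dag_deg = k_dag_deg,
         k_pip2_synth = k_pip2_synth, pip2_rest = pip2_rest),
    class = "cascade_params"
  )
}

#' Simulate receptor-driven PIP2 hydrolysis
#'
#' Integrates the [cascade_params()] mass-action ODE.  Cumulative hydrolysis
#' flux and cumulative DAG degradation are integrated alongside the state so
#' the stoichiometric bookkeeping (PIP2 consumed = DAG produced = IP3
#' produced) can be checked to solver accuracy.
#'
#' @param cascade A [cascade_params()].
#' @param duration Total simulated time (s), must exceed `agonist_on_time`.
#' @param dt Output sampling interval (s).
#' @param oag_uM Constant exogenous OAG added to the reported `dag_uM`
#'   (membrane-permeant DAG analog; it is not hydrolysis-derived and does not
#'   enter the mass balance).
#' @return A tibble with `time_s`, `pip2_uM`, `dag_uM`, `ip3_uM`, `plc`,
#'   `cum_hydrolysis_uM` and `cum_dag_removed_uM`.
#' @export
simulate_receptor_activation <- function(cascade, duration, dt = 0.05,
                                         oag_uM = 0) {
  stopifnot(inherits(cascade, "cascade_params"))
  if (duration <= cascade$agonist_on_time) {
    abort("`duration` must exceed `agonist_on_time`.",
          class = "pipgate_error_precondition")
  }
  times <- sort(unique(c(seq(0, duration, by = dt), cascade$agonist_on_time,
                         min(cascade$agonist_on_time + cascade$agonist_duration,
                             duration))))
  y0 <- c(plc = 0, pip2 = cascade$pip2_rest, dag = 0, ip3 = 0,
          cum_hyd = 0, cum_deg = 0)
  deriv <- function(t, y, p) {
    ag <- as.numeric(t >= p$agonist_on_time &
                       t < p$agonist_on_time + p$agonist_duration)
    hyd <- p$k_hyd * y[["plc"]] * y[["pip2"]]
    list(c(
      p$k_plc_act * ag * (1 - y[["plc"]]) - p$k_plc_deact * y[["plc"]],
      -hyd + p$k_pip2_synth * (p$pip2_rest - y[["pip2"]]),
      hyd - p$k_dag_deg * y[["dag"]],
      hyd,
      hyd,
      p$k_dag_deg * y[["dag"]]
    ))
  }
  sol <- deSolve::lsoda(y0, times, deriv, cascade, rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol))) {
    abort(sprintf("cascade integration failed; last valid time %.6g s.",
                  max(sol[is.finite(rowSums(sol)), 1L])),
          class = "pipgate_error_integration")
  }
  tibble(
    time_s = sol[, "time"],
    pip2_uM = sol[, "pip2"],
    dag_uM = sol[, "dag"] + oag_uM,
    ip3_uM = sol[, "ip3"],
    plc = sol[, "plc"],
    cum_hydrolysis_uM = sol[, "cum_hyd"],
    cum_dag_removed_uM = sol[, "cum_deg"]
  )
}

#' Peak receptor-operated current across a ladder of PIP2 affinities
#'
#' Runs the receptor cascade once, then drives the gating model with the
#' resulting lipid time course for each per-subunit dissociation constant in
#' `kd_values`, varying `k_on` at fixed `k_off` so unbinding-limited kinetics
#' stay comparable.  Currents use a common absolute scale (`po_ref = 1`), so
#' peak amplitudes are directly comparable across the ladder; the peak inward
#' current at the -50 mV holding potential is reported per Kd.
#'
#' @param cascade A [cascade_params()].
#' @param gating A supportive-mode [gating_params()]; its `kd_pip2` is
#'   overridden along the ladder.
#' @param kd_values Positive dissociation constants (uM).
#' @param duration Simulated time (s).
#' @param dt Lipid sampling interval (s).
#' @return A tibble with `kd_uM`, `peak_inward_nA` and `peak_rel` (peak
#'   relative to the smallest Kd in the ladder).
#' @export
kd_scan <- function(cascade, gating, kd_values, duration = 120, dt = 0.05) {
  stopifnot(inherits(cascade, "cascade_params"),
            inherits(gating, "gating_params"))
  if (length(kd_values) == 0L) {
    abort("`kd_values` must be non-empty.", class = "pipgate_error_precondition")
  }
  if (any(kd_values <= 0)) {
    abort("`kd_values` must be positive.", class = "pipgate_error_precondition")
  }
  if (gating$polarity != "supportive") {
    abort("`kd_scan()` requires supportive-mode gating.",
          class = "pipgate_error_precondition")
  }
  lipids <- simulate_receptor_activation(cascade, duration, dt)
  peaks <- vapply(kd_values, function(kd) {
    p <- gating_params(
      kd_pip2 = kd, k_off = gating$k_off, beta_max = gating$beta_max,
      alpha = gating$alpha, dag_ec50 = gating$dag_ec50,
      dag_hill = gating$dag_hill, polarity = gating$polarity,
      pip2_independent_fraction = gating$pip2_independent_fraction,
      g_total = gating$g_total, e_rev = gating$e_rev)
    sim <- simulate_gating(p, lipids, po_ref = 1)
    min(sim$current_nA)
  }, numeric(1))
  tibble(kd_uM = kd_values, peak_inward_nA = peaks,
         peak_rel = peaks / peaks[which.min(kd_values)])
}
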