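#' Depolarizing pulse-train voltage protocol
#'
#' Describes the standard voltage-sensitive-phosphatase (VSP) activation
#' protocol: the cell is held at a negative potential and strong depolarizing
#' steps (default +100 mV for 700 ms, every 15 s) are applied to switch the
#' phosphatase on.  All times are in seconds, potentials in mV.
#'
#' @param holding_mV Holding potential between pulses.
#' @param pulse_mV Command potential during the depolarizing step.
#' @param pulse_dur_s Duration of each depolarizing step.
#' @param period_s Interval between successive pulse onsets.
#' @param n_pulses Number of pulses in the train.
#' @param first_pulse_s Onset time of the first pulse.
#'
#' @return An object of class `voltage_protocol`.
#' @examples
#' prot <- voltage_protocol(n_pulses = 2)
#' protocol_voltage(prot, c(0, 15.1, 15.8))
#' @export
voltage_protocol <- function(holding_mV = -50, pulse_mV = 100,
                             pulse_dur_s = 0.7, period_s = 15,
                             n_pulses = 1L, first_pulse_s = 15) {
  check_pos(pulse_dur_s, "pulse_dur_s")
  check_pos(period_s, "period_s")
  check_nonneg(first_pulse_s, "first_pulse_s")
  n_pulses <- as.integer(n_pulses)
  if (n_pulses < 0L) abort("`n_pulses` must be >= 0.",
                           class = "pipgate_error_precondition")
  if (n_pulses > 1L && period_s <= pulse_dur_s) {
    abort("`period_s` must exceed `pulse_dur_s` so pulses do not overlap.",
          class = "pipgate_error_precondition")
  }
  structure(
    list(holding_mV = holding_mV, pulse_mV = pulse_mV,
         pulse_dur_s = pulse_dur_s, period_s = period_s,
         n_pulses = n_pulses, first_pulse_s = first_pulse_s),
    class = "voltage_protocol"
  )
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf(
    "<voltage_protocol> hold %g mV; %d pulse(s) to %g mV for %g ms every %g s from t = %g s\n",
    x$holding_mV, x$n_pulses, x$pulse_mV, 1000 * x$pulse_dur_s,
    x$period_s, x$first_pulse_s))
  invisible(x)
}

#' Pulse onset and offset times of a protocol
#'
#' @param protocol A [voltage_protocol()].
#' @return A tibble with one row per pulse: `pulse`, `start_s`, `end_s`.
#' @export
protocol_pulses <- function(protocol) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  if (protocol$n_pulses == 0L) {
    return(tibble(pulse = integer(), start_s = double(), end_s = double()))
  }
  start <- protocol$first_pulse_s +
    (seq_len(protocol$n_pulses) - 1L) * protocol$period_s
  tibble(pulse = seq_len(protocol$n_pulses),
         start_s = start, end_s = start + protocol$pulse_dur_s)
}

#' Command voltage at given times
#'
#' @param protocol A [voltage_protocol()].
#' @param time_s Numeric vector of times (s).
#' @return Numeric vector of command potentials (mV).
#' @export
protocol_voltage <- function(protocol, time_s) {
  pulses <- protocol_pulses(protocol)
  v <- rep(protocol$holding_mV, length(time_s))
  for (k in seq_len(nrow(pulses))) {
    v[time_s >= pulses$start_s[k] & time_s < pulses$end_s[k]] <- protocol$pulse_mV
  }
  v
}

# all voltage edge times, sorted
protocol_edges <- function(protocol) {
  pulses <- protocol_pulses(protocol)
  sort(unique(c(pulses$start_s, pulses$end_s)))
}

#' Two-rate sampling grid for a pulse protocol
#'
#' Recordings are sampled densely around each depolarizing pulse and sparsely
#' elsewhere, mimicking how stored traces keep full bandwidth only where the
#' kinetics of interest are.  The dense window runs from `window_pre_s` before
#' each pulse onset to `window_post_s` after repolarization.
#'
#' @param protocol A [voltage_protocol()].
#' @param duration_s Total trace duration (s).
#' @param fine_dt_s Sampling interval inside pulse windows.
#' @param coarse_dt_s Sampling interval elsewhere.
#' @param window_pre_s,window_post_s Dense-window margins around each pulse.
#' @return Strictly increasing numeric vector of sample times.
#' @export
sample_times <- function(protocol, duration_s, fine_dt_s = 0.001,
                         coarse_dt_s = 0.05, window_pre_s = 0.3,
                         window_post_s = 1.0) {
  check_pos(duration_s, "duration_s")
  check_pos(fine_dt_s, "fine_dt_s")
  check_pos(coarse_dt_s, "coarse_dt_s")
  tt <- seq(0, duration_s, by = coarse_dt_s)
  pulses <- protocol_pulses(protocol)
  for (k in seq_len(nrow(pulses))) {
    w0 <- max(0, pulses$start_s[k] - window_pre_s)
    w1 <- min(duration_s, pulses$end_s[k] + window_post_s)
    if (w1 > w0) tt <- c(tt, seq(w0, w1, by = fine_dt_s))
  }
  tt <- sort(unique(round(tt, 9)))
  tt
}
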