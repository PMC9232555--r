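# Fitting pipeline: logistic decay, exponential recovery, post/pre ratios,
# per-cell summaries and Hill dose-response fits.

# pick the observable column of a trace-like data frame
guess_value_col <- function(data, value_col = NULL) {
  if (!is.null(value_col)) {
    if (!value_col %in% names(data)) {
      abort(sprintf("column `%s` not found.", value_col),
            class = "pipgate_error_missing_column")
    }
    return(value_col)
  }
  for (cand in c("current_nA", "ratio", "value")) {
    if (cand %in% names(data)) return(cand)
  }
  abort("no observable column found (looked for current_nA, ratio, value).",
        class = "pipgate_error_missing_column")
}

new_kinetic_fit <- function(subclass, model, estimate, converged, reason,
                            rss = NA_real_, n = NA_integer_, data = NULL) {
  structure(
    list(model = model, estimate = estimate, converged = converged,
         reason = reason, rss = rss, n = n, data = data),
    class = c(subclass, "pipgate_fit")
  )
}

#' @export
print.pipgate_fit <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1L],
              if (x$converged) "converged" else paste("NOT converged:", x$reason)))
  if (nrow(x$estimate)) {
    for (i in seq_len(nrow(x$estimate))) {
      cat(sprintf("  %-10s %.6g\n", x$estimate$term[i], x$estimate$estimate[i]))
    }
  }
  cat(sprintf("  n = %d, rss = %.4g\n", x$n, x$rss))
  invisible(x)
}

# moving-average smoother used only for initial guesses
smooth_ma <- function(v, k = 7L) {
  if (length(v) < k) return(v)
  as.numeric(stats::filter(v, rep(1 / k, k), sides = 2L)) -> s
  s[is.na(s)] <- v[is.na(s)]
  s
}

#' Fit the logistic decay of the outward current during PIP2 depletion
#'
#' Fits `I = I_min + I_d / (1 + exp((t - t_half) / f_s))` to a trace segment
#' covering the depolarizing step, by nonlinear least squares.  `t` is
#' measured from the step onset `t0`; the first `skip_s` seconds are excluded
#' (capacitive edge).  The fit applies equally to the FRET-reported PIP2
#' depletion phase.  `t_half` and `f_s` are reported in ms.
#'
#' @param data Data frame with a time column and an observable column.
#' @param time_col Name of the time column (seconds).
#' @param value_col Observable column; guessed among `current_nA`, `ratio`,
#'   `value` when `NULL`.
#' @param t0 Step onset time; defaults to the first sample.
#' @param skip_s Initial portion after `t0` excluded from the fit (s).
#' @param baseline_s Length of pre-onset plateau included in the fit (s).
#'   Useful for observables that decay with no sigmoidal shoulder of their
#'   own (e.g. the FRET-reported PIP2 level): the plateau anchors the upper
#'   asymptote of the logistic so the half-time is well determined.
#' @param start Optional named list overriding initial guesses
#'   (`I_min`, `I_d`, `t_half_s`, `f_s_s`).
#' @param max_iter Maximum optimizer iterations.
#' @return A `decay_fit` object; see [tidy()] and [glance()] methods.
#'   Non-convergence (flat segment, optimizer failure, out-of-window
#'   half-time) is reported via `converged = FALSE` with a reason, never as
#'   an error.
#' @examples
#' tt <- seq(0, 0.7, by = 0.001)
#' y <- 0.2 + 1 / (1 + exp((tt - 0.229) / 0.040))
#' fit <- fit_decay(data.frame(time_s = tt, value = y))
#' tidy(fit)
#' @export
fit_decay <- function(data, time_col = "time_s", value_col = NULL, t0 = NULL,
                      skip_s = 0.005, baseline_s = 0, start = NULL,
                      max_iter = 500L) {
  if (!time_col %in% names(data)) {
    abort(sprintf("column `%s` not found.", time_col),
          class = "pipgate_error_missing_column")
  }
  value_col <- guess_value_col(data, value_col)
  t_raw <- data[[time_col]]
  v <- data[[value_col]]
  if (is.null(t0)) t0 <- min(t_raw)
  keep <- (t_raw >= t0 + skip_s |
             (baseline_s > 0 & t_raw >= t0 - baseline_s & t_raw <= t0)) &
    is.finite(v)
  t <- t_raw[keep] - t0
  v <- v[keep]
  empty_est <- tibble(term = c("t_half_ms", "f_s_ms", "I_min", "I_d"),
                      estimate = NA_real_)
  if (length(t) < 20L) {
    return(new_kinetic_fit("decay_fit", "logistic_decay", empty_est, FALSE,
                           "fewer than 20 samples in segment", n = length(t)))
  }
  rng <- diff(range(v))
  if (rng <= 1e-9 * max(abs(v), 1)) {
    return(new_kinetic_fit("decay_fit", "logistic_decay", empty_est, FALSE,
                           "no decay detected", n = length(t)))
  }
  vs <- smooth_ma(v)
  mid <- (max(vs) + min(vs)) / 2
  below <- which(vs <= mid)
  th0 <- if (length(below)) t[below[1L]] else stats::median(t)
  init <- list(I_min = min(v), I_d = max(v) - min(v),
               t_half_s = max(th0, min(diff(t))), f_s_s = 0.1 * diff(range(t)))
  if (!is.null(start)) init <- modifyList(init, start)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ I_min + I_d / (1 + exp((t - t_half_s) / f_s_s)),
      data = list(v = v, t = t),
      start = init,
      lower = c(I_min = -Inf, I_d = 0, t_half_s = 1e-6, f_s_s = 1e-6),
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(max_iter), ftol = 1e-12, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_kinetic_fit("decay_fit", "logistic_decay", empty_est, FALSE,
                           conditionMessage(fit), n = length(t)))
  }
  cf <- coef(fit)
  est <- tibble(term = c("t_half_ms", "f_s_ms", "I_min", "I_d"),
                estimate = c(1000 * cf[["t_half_s"]], 1000 * cf[["f_s_s"]],
                             cf[["I_min"]], cf[["I_d"]]))
  rss <- sum(stats::resid(fit)^2)
  conv <- TRUE; reason <- NA_character_
  if (cf[["t_half_s"]] > max(t) || cf[["I_d"]] <= 0) {
    conv <- FALSE
    reason <- "no decay detected within segment"
  }
  new_kinetic_fit("decay_fit", "logistic_decay", est, conv, reason,
                  rss = rss, n = length(t),
                  data = tibble(t_s = t, value = v,
                                fitted = stats::fitted(fit)))
}

#' Fit the exponential recovery of the inward current after repolarization
#'
#' Fits `I = I_0 + A * exp(-t / tau)` to the post-repolarization segment,
#' with `t` measured from the repolarization instant `t0` and the first
#' `skip_s` seconds excluded.  `I_0` is the recovered asymptote, `A` the
#' (signed) recovering amplitude, and `tau` (s) the replenishment time
#' constant; the same fit is used on the FRET-reported PIP2 replenishment.
#'
#' @inheritParams fit_decay
#' @param skip_s Initial portion excluded from the fit (s).
#' @param start Optional overrides for `I_0`, `A`, `tau_s`.
#' @return A `recovery_fit` object with terms `tau_s`, `A`, `I_0`.
#' @examples
#' tt <- seq(0, 10, by = 0.01)
#' y <- -1 + 0.5 * exp(-tt / 2.01)
#' tidy(fit_recovery(data.frame(time_s = tt, value = y)))
#' @export
fit_recovery <- function(data, time_col = "time_s", value_col = NULL,
                         t0 = NULL, skip_s = 0.020, start = NULL,
                         max_iter = 500L) {
  if (!time_col %in% names(data)) {
    abort(sprintf("column `%s` not found.", time_col),
          class = "pipgate_error_missing_column")
  }
  value_col <- guess_value_col(data, value_col)
  t_raw <- data[[time_col]]
  v <- data[[value_col]]
  if (is.null(t0)) t0 <- min(t_raw)
  keep <- t_raw >= t0 + skip_s & is.finite(v)
  t <- t_raw[keep] - t0
  v <- v[keep]
  empty_est <- tibble(term = c("tau_s", "A", "I_0"), estimate = NA_real_)
  if (length(t) < 20L) {
    return(new_kinetic_fit("recovery_fit", "exponential_recovery", empty_est,
                           FALSE, "fewer than 20 samples in segment",
                           n = length(t)))
  }
  i0_guess <- mean(tail(v, max(5L, length(v) %/% 10L)))
  a_guess <- v[1L] - i0_guess
  if (abs(a_guess) <= 1e-12 * max(abs(v), 1)) {
    return(new_kinetic_fit("recovery_fit", "exponential_recovery", empty_est,
                           FALSE, "no recovery detected", n = length(t)))
  }
  # log-linear initial guess for tau on the early part of the transient
  early <- seq_len(max(20L, round(0.6 * length(t))))
  resid0 <- v[early] - i0_guess
  ok <- sign(resid0) == sign(a_guess) & abs(resid0) > 1e-9 * abs(a_guess)
  tau0 <- if (sum(ok) >= 5L) {
    sl <- unname(coef(lm(log(abs(resid0[ok])) ~ t[early][ok]))[2L])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  init <- list(I_0 = i0_guess, A = a_guess, tau_s = tau0)
  if (!is.null(start)) init <- modifyList(init, start)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ I_0 + A * exp(-t / tau_s),
      data = list(v = v, t = t),
      start = init,
      lower = c(I_0 = -Inf, A = -Inf, tau_s = 1e-6),
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(max_iter), ftol = 1e-12, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_kinetic_fit("recovery_fit", "exponential_recovery", empty_est,
                           FALSE, conditionMessage(fit), n = length(t)))
  }
  cf <- coef(fit)
  est <- tibble(term = c("tau_s", "A", "I_0"),
                estimate = c(cf[["tau_s"]], cf[["A"]], cf[["I_0"]]))
  new_kinetic_fit("recovery_fit", "exponential_recovery", est, TRUE,
                  NA_character_, rss = sum(stats::resid(fit)^2),
                  n = length(t),
                  data = tibble(t_s = t, value = v,
                                fitted = stats::fitted(fit)))
}

fit_param <- function(fit, term) {
  fit$estimate$estimate[match(term, fit$estimate$term)]
}

#' Per-pulse kinetic analysis of a current trace
#'
#' For each depolarizing pulse: fits the logistic decay on the outward
#' current during the step, the exponential recovery on the inward current
#' after repolarization (up to the next pulse), measures the pre-pulse
#' current `I_pre` (mean over the 100 ms before the step) and defines
#' `I_post` by extrapolating the recovery fit to the repolarization instant
#' (`I_0 + A`), a measurement-window-free convention.  The inhibition ratio
#' is `I_post / I_pre`; values above 1 signal potentiation.
#'
#' @param trace A current trace (tibble with `time_s`, `current_nA`,
#'   `voltage_mV`), e.g. from [generate_cell_trace()] or [read_trace()].
#' @param protocol A [voltage_protocol()]; taken from the trace metadata when
#'   `NULL`.
#' @param pulses Integer indices of pulses to analyze (default all).
#' @param noise_floor_nA Reliability threshold: pulses whose `|I_pre|` falls
#'   below it are flagged unreliable.
#' @return A tibble with one row per pulse: fit parameters, `I_pre_nA`,
#'   `I_post_nA`, `inhibition_ratio`, convergence flags and `reliable`.
#' @export
analyze_pulses <- function(trace, protocol = NULL, pulses = NULL,
                           noise_floor_nA = 0.02) {
  meta <- trace_meta(trace)
  if (is.null(protocol)) protocol <- meta$protocol
  if (is.null(protocol)) {
    abort("no protocol given and none stored in trace metadata.",
          class = "pipgate_error_precondition")
  }
  ptab <- protocol_pulses(protocol)
  if (is.null(pulses)) pulses <- ptab$pulse
  ptab <- ptab[ptab$pulse %in% pulses, , drop = FALSE]
  t_all <- trace$time_s
  purrr::map_dfr(seq_len(nrow(ptab)), function(i) {
    st <- ptab$start_s[i]; en <- ptab$end_s[i]
    nxt <- if (i < nrow(ptab)) ptab$start_s[i + 1L] else {
      k <- which(protocol_pulses(protocol)$start_s > en)
      if (length(k)) protocol_pulses(protocol)$start_s[k[1L]] else max(t_all)
    }
    pre <- trace[t_all >= st - 0.1 & t_all < st, , drop = FALSE]
    dec_seg <- trace[t_all >= st & t_all < en, , drop = FALSE]
    rec_seg <- trace[t_all >= en & t_all <= nxt - 0.05, , drop = FALSE]
    dfit <- fit_decay(dec_seg, t0 = st)
    rfit <- fit_recovery(rec_seg, t0 = en)
    i_pre <- mean(pre$current_nA)
    i_post <- if (rfit$converged) {
      fit_param(rfit, "I_0") + fit_param(rfit, "A")
    } else if (identical(rfit$reason, "no recovery detected")) {
      # flat post-repolarization current (e.g. inactive-phosphatase control):
      # nothing to extrapolate, the early post-pulse mean is the level itself
      vv <- rec_seg$current_nA[rec_seg$time_s >= en + 0.02 &
                                 rec_seg$time_s <= en + 0.32]
      if (length(vv)) mean(vv) else NA_real_
    } else NA_real_
    tibble(
      pulse = ptab$pulse[i],
      t_half_ms = fit_param(dfit, "t_half_ms"),
      f_s_ms = fit_param(dfit, "f_s_ms"),
      I_min_nA = fit_param(dfit, "I_min"),
      I_d_nA = fit_param(dfit, "I_d"),
      tau_s = fit_param(rfit, "tau_s"),
      A_nA = fit_param(rfit, "A"),
      I_0_nA = fit_param(rfit, "I_0"),
      I_pre_nA = i_pre,
      I_post_nA = i_post,
      inhibition_ratio = i_post / i_pre,
      decay_converged = dfit$converged,
      recovery_converged = rfit$converged,
      decay_rss = dfit$rss,
      recovery_rss = rfit$rss,
      reliable = is.finite(i_pre) && abs(i_pre) >= noise_floor_nA
    )
  })
}

#' Post/pre inhibition ratio per pulse
#'
#' Convenience wrapper around [analyze_pulses()] returning only the
#' depolarization-induced inhibition (or potentiation) ratio
#' `I_post / I_pre` per pulse.
#'
#' @inheritParams analyze_pulses
#' @return A tibble with `pulse`, `I_pre_nA`, `I_post_nA`,
#'   `inhibition_ratio` and `reliable`.
#' @export
inhibition_ratio <- function(trace, protocol = NULL, pulses = NULL,
                             noise_floor_nA = 0.02) {
  res <- analyze_pulses(trace, protocol, pulses, noise_floor_nA)
  res[, c("pulse", "I_pre_nA", "I_post_nA", "inhibition_ratio", "reliable")]
}

#' Per-cell kinetic summary over plateau pulses
#'
#' Averages the per-pulse fits over the 2-4 pulses nearest the OAG plateau
#' peak (the pulses marked by the generator when present, otherwise those
#' with the largest pre-pulse current), and computes the affinity index
#' `tau / t_half` (both in ms) -- a relative proxy for the PIP2 dissociation
#' constant.  Two forms are reported: the ratio of the averaged kinetics
#' (`affinity_index`) and the average of per-pulse ratios
#' (`affinity_index_per_pulse`).
#'
#' @inheritParams analyze_pulses
#' @param n_pulses Number of plateau pulses to average (2-4 unless overridden).
#' @param construct Construct label; taken from metadata when `NULL`.
#' @return A one-row tibble (class retains plain tibble) with the construct
#'   label, mean `t_half_ms`, `tau_s`, `inhibition_ratio`, both affinity
#'   index forms, `n_pulses` used and an `incomplete` flag (fewer than two
#'   converged pulses).
#' @export
summarize_cell <- function(trace, protocol = NULL, n_pulses = 3L,
                           construct = NULL) {
  meta <- trace_meta(trace)
  if (is.null(protocol)) protocol <- meta$protocol
  if (is.null(construct)) {
    construct <- if (!is.null(meta$construct)) meta$construct else NA_character_
  }
  per_pulse <- analyze_pulses(trace, protocol)
  # a measurable pre-pulse current and a defined post/pre ratio are
  # required; individual fits may legitimately fail (rising "decays" in
  # potentiated constructs, flat recoveries in inactive-phosphatase
  # controls), leaving the corresponding kinetic means missing
  ok <- per_pulse$reliable & is.finite(per_pulse$inhibition_ratio)
  marked <- meta$truth$analysis_pulses
  cand <- if (!is.null(marked)) {
    per_pulse[per_pulse$pulse %in% marked & ok, , drop = FALSE]
  } else {
    sel <- per_pulse[ok, , drop = FALSE]
    sel[order(-abs(sel$I_pre_nA)), , drop = FALSE][
      seq_len(min(n_pulses, nrow(sel))), , drop = FALSE]
  }
  if (!is.null(marked)) {
    cand <- cand[order(-abs(cand$I_pre_nA)), , drop = FALSE][
      seq_len(min(n_pulses, nrow(cand))), , drop = FALSE]
  }
  incomplete <- nrow(cand) < 2L
  dec_ok <- cand$decay_converged & is.finite(cand$t_half_ms)
  rec_ok <- cand$recovery_converged & is.finite(cand$tau_s)
  m_thalf <- if (any(dec_ok)) mean(cand$t_half_ms[dec_ok]) else NA_real_
  m_tau <- if (any(rec_ok)) mean(cand$tau_s[rec_ok]) else NA_real_
  tibble(
    construct = construct,
    n_pulses = nrow(cand),
    t_half_ms = m_thalf,
    tau_s = m_tau,
    inhibition_ratio = mean(cand$inhibition_ratio),
    affinity_index = 1000 * m_tau / m_thalf,
    affinity_index_per_pulse = if (any(dec_ok)) {
      mean(1000 * cand$tau_s[dec_ok] / cand$t_half_ms[dec_ok])
    } else NA_real_,
    incomplete = incomplete
  )
}

#' Fit depletion and replenishment kinetics of a FRET-reported PIP2 trace
#'
#' Applies the decay/recovery fitting pair to a lipid-sensor ratio trace
#' around one depolarizing pulse: the depletion phase (pulse window, with a
#' pre-onset baseline anchoring the logistic plateau) is fitted with
#' [fit_decay()] and the replenishment phase after repolarization with
#' [fit_recovery()].  Because both fits are invariant to linear rescaling of
#' the observable, any monotone linear sensor calibration yields the same
#' kinetics.
#'
#' @param trace A `fret_trace` (or any tibble with `time_s` and a ratio
#'   column).
#' @param protocol A [voltage_protocol()]; from trace metadata when `NULL`.
#' @param pulse Pulse index to analyze.
#' @param baseline_s Pre-onset baseline included in the depletion fit (s).
#' @param window_s Length of the replenishment window (s); defaults to the
#'   time to the next pulse or the end of the trace.
#' @return A list with `depletion` (a `decay_fit`; half-time in ms) and
#'   `replenishment` (a `recovery_fit`; tau in s).
#' @export
fit_fret_episode <- function(trace, protocol = NULL, pulse = 1L,
                             baseline_s = 0.2, window_s = NULL) {
  meta <- trace_meta(trace)
  if (is.null(protocol)) protocol <- meta$protocol
  if (is.null(protocol)) {
    abort("no protocol given and none stored in trace metadata.",
          class = "pipgate_error_precondition")
  }
  ptab <- protocol_pulses(protocol)
  if (!pulse %in% ptab$pulse) {
    abort("requested pulse not in protocol.",
          class = "pipgate_error_precondition")
  }
  st <- ptab$start_s[ptab$pulse == pulse]
  en <- ptab$end_s[ptab$pulse == pulse]
  t_end <- if (!is.null(window_s)) en + window_s else {
    nxt <- ptab$start_s[ptab$start_s > en]
    if (length(nxt)) nxt[1L] else max(trace$time_s)
  }
  dep <- fit_decay(trace[trace$time_s >= st - baseline_s &
                           trace$time_s <= en, , drop = FALSE],
                   t0 = st, skip_s = 0, baseline_s = baseline_s)
  rep_ <- fit_recovery(trace[trace$time_s >= en & trace$time_s <= t_end,
                             , drop = FALSE],
                       t0 = en, skip_s = 0)
  list(depletion = dep, replenishment = rep_)
}

#' Hill dose-response fit
#'
#' Fits `R = r_max * C^n / (EC50^n + C^n)` to a dose-response table by
#' nonlinear least squares.
#'
#' @param data Data frame with a concentration column and a response column;
#'   replicate rows per concentration are used as-is.
#' @param conc_col,resp_col Column names.
#' @param start Optional overrides for `r_max`, `ec50`, `hill_n`.
#' @param max_iter Maximum optimizer iterations.
#' @return A `hill_fit` object with terms `ec50_uM`, `hill_n`, `r_max`.
#'   Requires at least four distinct concentrations; clearly non-saturating
#'   data yields `converged = FALSE` with a reason.
#' @examples
#' dr <- generate_dose_response(seed = 1, sd = 0)
#' tidy(hill_fit(dr))
#' @export
hill_fit <- function(data, conc_col = "conc_uM", resp_col = "response",
                     start = NULL, max_iter = 500L) {
  for (cl in c(conc_col, resp_col)) {
    if (!cl %in% names(data)) {
      abort(sprintf("column `%s` not found.", cl),
            class = "pipgate_error_missing_column")
    }
  }
  conc <- data[[conc_col]]
  resp <- data[[resp_col]]
  keep <- is.finite(conc) & is.finite(resp) & conc > 0
  conc <- conc[keep]; resp <- resp[keep]
  if (length(unique(conc)) < 4L) {
    abort("at least 4 distinct concentrations are required.",
          class = "pipgate_error_precondition")
  }
  empty_est <- tibble(term = c("ec50_uM", "hill_n", "r_max"),
                      estimate = NA_real_)
  means <- tapply(resp, conc, mean)
  cc <- as.numeric(names(means))
  rmax0 <- max(means)
  half <- rmax0 / 2
  above <- which(means >= half)
  ec0 <- if (length(above)) cc[above[1L]] else stats::median(cc)
  init <- list(r_max = rmax0, ec50 = max(ec0, min(cc)), hill_n = 1)
  if (!is.null(start)) init <- modifyList(init, start)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ r_max * conc^hill_n / (ec50^hill_n + conc^hill_n),
      data = list(resp = resp, conc = conc),
      start = init,
      lower = c(r_max = 0, ec50 = 1e-9, hill_n = 1e-3),
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(max_iter), ftol = 1e-12, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_kinetic_fit("hill_fit", "hill", empty_est, FALSE,
                           conditionMessage(fit), n = length(resp)))
  }
  cf <- coef(fit)
  est <- tibble(term = c("ec50_uM", "hill_n", "r_max"),
                estimate = c(cf[["ec50"]], cf[["hill_n"]], cf[["r_max"]]))
  conv <- TRUE; reason <- NA_character_
  if (cf[["ec50"]] > 10 * max(conc)) {
    conv <- FALSE
    reason <- "dose range does not saturate; EC50 unconstrained"
  }
  new_kinetic_fit("hill_fit", "hill", est, conv, reason,
                  rss = sum(stats::resid(fit)^2), n = length(resp),
                  data = tibble(conc_uM = conc, response = resp,
                                fitted = stats::fitted(fit)))
}
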