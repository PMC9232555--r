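#' Generator matrix of the tetrameric gating scheme
#'
#' Builds the 6x6 continuous-time Markov generator over states
#' `C0, C1, C2, C3, C4, O` at fixed lipid concentrations.  Along the binding
#' chain, `C_i -> C_{i+1}` proceeds at `(4 - i) * k_on * pip2` (free subunits
#' bind independently) and `C_{i+1} -> C_i` at `(i + 1) * k_off`.  In
#' supportive polarity the open state exchanges with C4
#' (`C4 -> O` at `beta(dag)`, `O -> C4` at `alpha`); in inhibitory polarity it
#' exchanges with C0 instead.  Rows sum to zero.
#'
#' @param params A [gating_params()].
#' @param pip2 PIP2 concentration (uM, scalar, >= 0).
#' @param dag DAG/OAG concentration (uM, scalar, >= 0).
#' @return A 6x6 generator matrix with dimnames `C0..C4, O`; transposing and
#'   right-multiplying the occupancy column vector gives its time derivative.
#' @examples
#' Q <- build_rate_matrix(gating_params(), pip2 = 2, dag = 50)
#' rowSums(Q)    # all zero
#' @export
build_rate_matrix <- function(params, pip2, dag) {
  stopifnot(inherits(params, "gating_params"))
  check_nonneg(pip2, "pip2")
  check_nonneg(dag, "dag")
  states <- c("C0", "C1", "C2", "C3", "C4", "O")
  Q <- matrix(0, 6, 6, dimnames = list(states, states))
  for (i in 0:3) {
    Q[i + 1L, i + 2L] <- (4 - i) * params$k_on * pip2  # C_i -> C_{i+1}
    Q[i + 2L, i + 1L] <- (i + 1) * params$k_off        # C_{i+1} -> C_i
  }
  beta <- beta_of_dag(params, dag)
  gate_from <- if (params$polarity == "supportive") 5L else 1L
  Q[gate_from, 6L] <- beta
  Q[6L, gate_from] <- params$alpha
  diag(Q) <- -rowSums(Q)
  Q
}

#' Stationary occupancy of the gating scheme
#'
#' Returns the normalized null-space vector of the generator at fixed lipid
#' concentrations.  When the chain is disconnected (no binding flux and no
#' gate flux, e.g. `pip2 = 0` with `beta = 0`) the stationary distribution is
#' not unique; the result is then flagged `degenerate` rather than raising an
#' error.
#'
#' @inheritParams build_rate_matrix
#' @return A one-row tibble with columns `C0..C4`, `O`, `Po` and `degenerate`.
#' @examples
#' steady_state(gating_params(), pip2 = 2, dag = 50)$Po
#' @export
steady_state <- function(params, pip2, dag) {
  Q <- build_rate_matrix(params, pip2, dag)
  dec <- svd(t(Q))
  d <- dec$d
  tol <- max(d) * 1e-10
  null_dim <- sum(d < tol)
  v <- dec$v[, 6L]
  v <- abs(v) / sum(abs(v))
  out <- as_tibble(as.list(setNames(v, colnames(Q))))
  out$Po <- v[6L]
  out$degenerate <- null_dim != 1L
  out
}

# lipid forcing helpers -------------------------------------------------------

# validate and normalize a lipid time course to (time_s, pip2_uM, dag_uM)
as_lipid_timecourse <- function(lipids) {
  lipids <- as_tibble(lipids)
  if (!"time_s" %in% names(lipids)) {
    abort("lipid time course needs a `time_s` column.",
          class = "pipgate_error_precondition")
  }
  if (!"pip2_uM" %in% names(lipids)) {
    abort("lipid time course needs a `pip2_uM` column.",
          class = "pipgate_error_precondition")
  }
  if (!"dag_uM" %in% names(lipids)) lipids$dag_uM <- 0
  if (any(diff(lipids$time_s) <= 0)) {
    abort("lipid time grid must be strictly increasing.",
          class = "pipgate_error_nonmonotone_time")
  }
  if (any(lipids$pip2_uM < -1e-12) || any(lipids$dag_uM < -1e-12)) {
    abort("lipid concentrations must be non-negative.",
          class = "pipgate_error_precondition")
  }
  lipids
}

#' Integrate the gating master equation along a lipid time course
#'
#' Solves the time-inhomogeneous master equation of the six-state scheme,
#' with PIP2 and DAG interpolated linearly from `lipids`, and converts open
#' probability to whole-cell current.  The current convention is ohmic:
#' `I(t) = [f + (1 - f) * Po(t) / po_ref] * g_total * (V(t) - e_rev) / 1000`
#' (nA), with `f = pip2_independent_fraction`.  By default `po_ref` is the
#' resting-reference open probability: the stationary `Po` at the initial
#' PIP2 level and the maximal DAG level of the time course (the pre-pulse
#' OAG plateau), so that the pre-pulse current at a -50 mV holding potential
#' is `-g_total * 50/1000` nA (-1 nA with the default 20 nS).
#'
#' @inheritParams build_rate_matrix
#' @param lipids Data frame with `time_s`, `pip2_uM` and optionally `dag_uM`.
#' @param protocol Optional [voltage_protocol()]; supplies `V(t)` for the
#'   current.  Without it the trace holds `holding_mV = -50`.
#' @param times Output sample times; defaults to the lipid grid joined with
#'   the protocol voltage edges.
#' @param po_ref Reference open probability for current normalization; `NULL`
#'   for the resting-reference convention above, or a number (e.g. 1 to
#'   report unnormalized `g * Po` currents, as the Kd scan does).
#' @param init Initial occupancy over `C0..C4, O`; defaults to the stationary
#'   distribution at the first lipid sample.
#' @param rtol,atol Solver tolerances.
#' @return A tibble (class `gating_sim`) with occupancy columns `C0..C4`,
#'   `O`, plus `Po`, `pip2_uM`, `dag_uM`, `voltage_mV` and `current_nA`.
#'   The maximal occupancy-sum defect before renormalization is stored in
#'   attribute `mass_defect`.
#' @export
simulate_gating <- function(params, lipids, protocol = NULL, times = NULL,
                            po_ref = NULL, init = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "gating_params"))
  lipids <- as_lipid_timecourse(lipids)
  if (is.null(times)) {
    times <- lipids$time_s
    if (!is.null(protocol)) {
      ed <- protocol_edges(protocol)
      times <- sort(unique(c(times, ed[ed >= min(times) & ed <= max(times)])))
    }
  }
  if (any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing.",
          class = "pipgate_error_nonmonotone_time")
  }
  pip2_f <- approxfun(lipids$time_s, lipids$pip2_uM, rule = 2)
  dag_f <- approxfun(lipids$time_s, lipids$dag_uM, rule = 2)

  if (is.null(init)) {
    ss <- steady_state(params, lipids$pip2_uM[1L], dag_f(times[1L]))
    init <- unlist(ss[1L, 1:6])
  }
  if (length(init) != 6L || any(init < -1e-12) || abs(sum(init) - 1) > 1e-6) {
    abort("`init` must be a probability vector over the six states.",
          class = "pipgate_error_precondition")
  }

  kon <- params$k_on; koff <- params$k_off; alpha <- params$alpha
  gate_from <- if (params$polarity == "supportive") 5L else 1L
  deriv <- function(t, y, parms) {
    pip2 <- max(pip2_f(t), 0)
    bind <- (4:1) * kon * pip2 * y[1:4]   # C_i -> C_{i+1}
    unbind <- (1:4) * koff * y[2:5]       # C_{i+1} -> C_i
    dy <- numeric(6)
    dy[1:4] <- dy[1:4] - bind + unbind
    dy[2:5] <- dy[2:5] + bind - unbind
    beta <- beta_of_dag(params, max(dag_f(t), 0))
    flux <- beta * y[gate_from] - alpha * y[6L]
    dy[gate_from] <- dy[gate_from] - flux
    dy[6L] <- dy[6L] + flux
    list(dy)
  }
  sol <- deSolve::lsoda(y = init, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    abort(sprintf("master-equation integration failed at t = %.6g s.",
                  max(sol[, 1L])),
          class = "pipgate_error_integration")
  }
  occ <- sol[, 2:7, drop = FALSE]
  mass <- rowSums(occ)
  mass_defect <- max(abs(mass - 1))
  occ <- occ / mass

  if (is.null(po_ref)) {
    po_ref <- steady_state(params, lipids$pip2_uM[1L], max(lipids$dag_uM))$Po
    if (po_ref <= 0) po_ref <- 1  # degenerate reference; report raw Po
  }
  volt <- if (is.null(protocol)) rep(-50, length(times)) else {
    protocol_voltage(protocol, times)
  }
  f <- params$pip2_independent_fraction
  po <- occ[, 6L]
  current <- (f + (1 - f) * po / po_ref) * params$g_total *
    (volt - params$e_rev) / 1000
  out <- as_tibble(occ)
  names(out) <- c("C0", "C1", "C2", "C3", "C4", "O")
  out <- dplyr::bind_cols(tibble(time_s = times), out)
  out$Po <- po
  out$pip2_uM <- pip2_f(times)
  out$dag_uM <- dag_f(times)
  out$voltage_mV <- volt
  out$current_nA <- current
  attr(out, "mass_defect") <- mass_defect
  attr(out, "po_ref") <- po_ref
  class(out) <- c("gating_sim", class(out))
  out
}

#' Stochastic (Gillespie) oracle for the gating scheme
#'
#' Simulates `n_channels` independent channels with the aggregate direct
#' method and reports occupancy fractions at requested checkpoints.  Lipid
#' concentrations are held piecewise constant between grid points of
#' `lipids` (exact for constant lipids, an approximation otherwise).  Serves
#' as an independent stochastic check on [simulate_gating()].
#'
#' @inheritParams simulate_gating
#' @param n_channels Number of independent channels (>= 1).
#' @param seed Integer RNG seed; the trajectory is reproducible given the seed.
#' @param record_times Checkpoint times at which occupancy is recorded.
#' @param init Initial occupancy (probabilities); channels are assigned
#'   deterministically by largest remainder, so `n_channels = 1` with a
#'   degenerate `init` stays put.
#' @return A tibble with `time_s`, occupancy fractions `C0..C4`, `O` and `Po`.
#' @export
gillespie_gating <- function(params, lipids, n_channels, seed,
                             record_times, init = NULL) {
  stopifnot(inherits(params, "gating_params"))
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) abort("`n_channels` must be >= 1.",
                             class = "pipgate_error_precondition")
  lipids <- as_lipid_timecourse(lipids)
  record_times <- sort(record_times)
  t_end <- max(record_times)

  if (is.null(init)) {
    ss <- steady_state(params, lipids$pip2_uM[1L], lipids$dag_uM[1L])
    init <- unlist(ss[1L, 1:6])
  }
  # largest-remainder apportionment of channels to states
  counts <- floor(init * n_channels)
  rem <- init * n_channels - counts
  short <- n_channels - sum(counts)
  if (short > 0) {
    counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  }

  gate_from <- if (params$polarity == "supportive") 5L else 1L
  # directed transitions: from, to, per-channel rate factory
  trans_from <- c(1:4, 2:5, gate_from, 6L)
  trans_to <- c(2:5, 1:4, 6L, gate_from)
  rate_of <- function(pip2, dag) {
    c((4:1) * params$k_on * pip2,   # binding C0..C3
      (1:4) * params$k_off,         # unbinding C1..C4
      beta_of_dag(params, dag),     # gate open
      params$alpha)                 # gate close
  }

  grid <- c(lipids$time_s, Inf)
  out <- matrix(NA_real_, length(record_times), 6L)
  rec_i <- 1L
  set.seed(as.integer(seed))
  t_now <- 0
  seg <- findInterval(t_now, grid)
  repeat {
    rates <- rate_of(lipids$pip2_uM[seg], lipids$dag_uM[seg])
    seg_end <- min(grid[seg + 1L], t_end)
    repeat {
      prop <- counts[trans_from] * rates
      total <- sum(prop)
      t_next <- if (total > 0) t_now + stats::rexp(1L, total) else Inf
      t_stop <- min(t_next, seg_end)
      while (rec_i <= length(record_times) && record_times[rec_i] <= t_stop) {
        out[rec_i, ] <- counts
        rec_i <- rec_i + 1L
      }
      if (t_next > seg_end) { t_now <- seg_end; break }
      t_now <- t_next
      j <- sample.int(length(prop), 1L, prob = prop)
      counts[trans_from[j]] <- counts[trans_from[j]] - 1L
      counts[trans_to[j]] <- counts[trans_to[j]] + 1L
    }
    if (t_now >= t_end || rec_i > length(record_times)) break
    seg <- seg + 1L
    if (seg >= length(grid)) break
  }
  while (rec_i <= length(record_times)) {  # fill trailing checkpoints
    out[rec_i, ] <- counts
    rec_i <- rec_i + 1L
  }
  frac <- out / n_channels
  colnames(frac) <- c("C0", "C1", "C2", "C3", "C4", "O")
  res <- dplyr::bind_cols(tibble(time_s = record_times), as_tibble(frac))
  res$Po <- res$O
  res
}
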