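#' Parameters of the tetrameric PIP2/DAG gating scheme
#'
#' The channel is a homotetramer whose four subunits bind PIP2 independently,
#' giving closed states C0..C4 indexed by the number of PIP2-occupied
#' subunits, plus a single open state O.  In the `supportive` polarity the
#' channel opens only from the fully liganded C4 (PIP2 depletion closes it);
#' in the `inhibitory` polarity it opens only from the unliganded C0, so PIP2
#' depletion potentiates the current -- the phenomenological polarity switch
#' seen when the distal TRP-box lysine is neutralized.  DAG (or its analog
#' OAG) enters only through the opening rate as a Hill factor
#' `beta(dag) = beta_max * dag^h / (ec50^h + dag^h)`.
#'
#' Rates are per second; concentrations in micromolar.  `kd_pip2 = k_off/k_on`
#' is the per-subunit PIP2 dissociation constant; supply `kd_pip2` and
#' `k_off` (the default) or `k_on` and `k_off`.
#'
#' @param kd_pip2 Per-subunit PIP2 dissociation constant (uM).
#' @param k_off PIP2 dissociation rate per bound subunit (1/s).
#' @param k_on PIP2 association rate per free subunit (1/uM/s); derived from
#'   `k_off/kd_pip2` when `NULL`.
#' @param beta_max Maximal opening rate at saturating DAG (1/s).
#' @param alpha Closing rate (1/s).
#' @param dag_ec50 DAG/OAG half-activation concentration of the opening rate (uM).
#' @param dag_hill Hill coefficient of the DAG dependence (> 0).
#' @param polarity `"supportive"` (open from C4) or `"inhibitory"` (open from C0).
#' @param pip2_independent_fraction Fraction of the whole-cell current that
#'   does not follow PIP2 occupancy, in `[0, 1]`.
#' @param g_total Whole-cell maximal conductance (nS).
#' @param e_rev Reversal potential (mV).
#'
#' @return An object of class `gating_params`.
#' @examples
#' p <- gating_params()
#' p$k_on          # k_off / kd_pip2
#' @export
gating_params <- function(kd_pip2 = 2, k_off = 10.4, k_on = NULL,
                          beta_max = 73.6, alpha = 12,
                          dag_ec50 = 46, dag_hill = 0.8,
                          polarity = c("supportive", "inhibitory"),
                          pip2_independent_fraction = 0,
                          g_total = 20, e_rev = 0) {
  polarity <- match.arg(polarity)
  check_pos(k_off, "k_off")
  if (is.null(k_on)) {
    check_pos(kd_pip2, "kd_pip2")
    k_on <- k_off / kd_pip2
  } else {
    check_pos(k_on, "k_on")
    kd <- k_off / k_on
    if (!missing(kd_pip2) &&
        abs(kd - kd_pip2) > 1e-12 * max(abs(kd), abs(kd_pip2))) {
      abort("`kd_pip2` is inconsistent with `k_off / k_on`.",
            class = "pipgate_error_precondition")
    }
    kd_pip2 <- kd
  }
  check_nonneg(beta_max, "beta_max")
  check_nonneg(alpha, "alpha")
  check_pos(dag_ec50, "dag_ec50")
  check_pos(dag_hill, "dag_hill")
  check_nonneg(pip2_independent_fraction, "pip2_independent_fraction")
  if (pip2_independent_fraction > 1) {
    abort("`pip2_independent_fraction` must be <= 1.",
          class = "pipgate_error_precondition")
  }
  check_pos(g_total, "g_total")
  structure(
    list(n_subunits = 4L, k_on = k_on, k_off = k_off, kd_pip2 = kd_pip2,
         beta_max = beta_max, alpha = alpha, dag_ec50 = dag_ec50,
         dag_hill = dag_hill, polarity = polarity,
         pip2_independent_fraction = pip2_independent_fraction,
         g_total = g_total, e_rev = e_rev),
    class = "gating_params"
  )
}

#' @export
print.gating_params <- function(x, ...) {
  cat(sprintf(
    paste0("<gating_params> tetramer, polarity %s\n",
           "  PIP2: Kd %.3g uM (k_on %.3g /uM/s, k_off %.3g /s)\n",
           "  gate: beta_max %.3g /s, alpha %.3g /s; DAG EC50 %.3g uM, h %.3g\n",
           "  current: g %.3g nS, Erev %g mV, PIP2-independent fraction %.3g\n"),
    x$polarity, x$kd_pip2, x$k_on, x$k_off, x$beta_max, x$alpha,
    x$dag_ec50, x$dag_hill, x$g_total, x$e_rev, x$pip2_independent_fraction))
  invisible(x)
}

#' DAG-dependent opening rate
#'
#' Hill modulation of the opening rate by DAG/OAG:
#' `beta(dag) = beta_max * dag^h / (ec50^h + dag^h)`.
#'
#' @param params A [gating_params()].
#' @param dag DAG/OAG concentration (uM), vectorized.
#' @return Opening rate (1/s).
#' @export
beta_of_dag <- function(params, dag) {
  if (any(dag < 0)) abort("`dag` must be non-negative.",
                          class = "pipgate_error_precondition")
  h <- params$dag_hill
  dh <- dag^h
  out <- params$beta_max * dh / (params$dag_ec50^h + dh)
  out[dag == 0] <- 0
  out
}

#' Shipped construct presets
#'
#' Packaged gating-parameter calibrations for the wild-type channel and the
#' screening mutants modeled here.  The mutants differ from wild type by their
#' per-subunit PIP2 dissociation constant (`R437Q`, `K442Q`: reduced PIP2
#' affinity, varied through `k_on` at fixed `k_off`) or by the coupling
#' polarity (`K771Q`: inhibitory mode, so VSP activation potentiates the
#' current).  The rate constants are a packaged calibration chosen so that
#' the wild-type VSP episode reproduces the reference kinetics (current decay
#' half-time about 229 ms, recovery time constant about 2.0 s, post/pre ratio
#' about 0.5) under the default [vsp_params()]; they are a calibration, not
#' measured quantities.
#'
#' @param label One of `"WT"`, `"R437Q"`, `"K442Q"`, `"K771Q"`.
#' @return A [gating_params()] object with a `construct` attribute.
#' @examples
#' trpc6_preset("R437Q")$kd_pip2
#' @export
trpc6_preset <- function(label = c("WT", "R437Q", "K442Q", "K771Q")) {
  label <- match.arg(label)
  base <- .pipgate_wt_defaults
  p <- switch(label,
    WT = do.call(gating_params, base),
    R437Q = do.call(gating_params, modifyList(base, list(kd_pip2 = 10))),
    K442Q = do.call(gating_params, modifyList(base, list(kd_pip2 = 16))),
    K771Q = do.call(gating_params, modifyList(
      base, list(polarity = "inhibitory",
                 beta_max = .pipgate_k771q_beta_max)))
  )
  attr(p, "construct") <- label
  p
}

# Packaged wild-type calibration (see trpc6_preset docs and the methods
# vignette for how these were fixed).
.pipgate_wt_defaults <- list(
  kd_pip2 = 2, k_off = 10.4, beta_max = 73.6, alpha = 12,
  dag_ec50 = 46, dag_hill = 0.8, polarity = "supportive",
  pip2_independent_fraction = 0, g_total = 20, e_rev = 0
)

# Inhibitory-mode opening rate calibrated to the potentiation ratio ~1.24.
.pipgate_k771q_beta_max <- 138644
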