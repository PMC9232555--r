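# Mutant screening stage: per-construct aggregation, many-to-one comparison
# against wild type, and phenotype classification.

.screen_metrics <- c("t_half_ms", "tau_s", "inhibition_ratio", "affinity_index")
.screen_log_metrics <- c("t_half_ms", "tau_s", "affinity_index")

#' Aggregate per-cell kinetics by construct
#'
#' Means, SD and SEM (`SD/sqrt(n)`) per construct per metric.  With a single
#' cell the SEM is reported missing.
#'
#' @param cells Tibble of per-cell summaries (one row per cell) with a
#'   `construct` column and metric columns; typically rows from
#'   [summarize_cell()].
#' @param metrics Metric columns to aggregate.
#' @return A long tibble: `construct`, `metric`, `n`, `mean`, `sd`, `sem`.
#' @export
aggregate_screen <- function(cells, metrics = .screen_metrics) {
  if (!"construct" %in% names(cells)) {
    abort("`cells` needs a `construct` column.",
          class = "pipgate_error_missing_column")
  }
  metrics <- intersect(metrics, names(cells))
  cells |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::group_by(.data$construct, .data$metric) |>
    dplyr::summarise(
      n = sum(is.finite(.data$value)),
      mean = mean(.data$value[is.finite(.data$value)]),
      sd = if (sum(is.finite(.data$value)) > 1L) {
        stats::sd(.data$value[is.finite(.data$value)])
      } else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(sem = .data$sd / sqrt(.data$n))
}

# one-way many-to-one comparison for a single metric.
# Returns per-comparator t statistics and resampling-adjusted p-values.
dunnett_one_metric <- function(values, groups, wt_label, n_draws, seed) {
  groups <- as.character(groups)
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  labs <- unique(groups)
  if (!wt_label %in% labs) {
    abort(sprintf("reference group `%s` not present.", wt_label),
          class = "pipgate_error_precondition")
  }
  comparators <- setdiff(labs, wt_label)
  n_g <- vapply(labs, function(g) sum(groups == g), integer(1))
  m_g <- vapply(labs, function(g) mean(values[groups == g]), numeric(1))
  if (any(n_g < 2L) || length(comparators) == 0L) {
    return(tibble(construct = comparators,
                  estimate = m_g[comparators] - m_g[wt_label],
                  statistic = NA_real_, p_value = NA_real_,
                  note = "insufficient replication"))
  }
  df <- sum(n_g) - length(labs)
  ss_within <- sum(vapply(labs, function(g) {
    x <- values[groups == g]; sum((x - mean(x))^2)
  }, numeric(1)))
  if (ss_within <= 0) {
    # all groups internally constant: identical groups get p = 1, any
    # mean difference is infinitely significant -> p = 0
    est <- unname(m_g[comparators] - m_g[wt_label])
    return(tibble(construct = comparators, estimate = est,
                  statistic = unname(ifelse(est == 0, 0, Inf)),
                  p_value = unname(ifelse(est == 0, 1, 0)),
                  note = "zero variance"))
  }
  s2 <- ss_within / df
  se <- sqrt(s2 * (1 / n_g[comparators] + 1 / n_g[wt_label]))
  t_obs <- (m_g[comparators] - m_g[wt_label]) / se

  # parametric resampling of the max-|t| null: group means drawn from
  # N(0, 1/n_g), pooled variance from its chi-square distribution
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n_draws * length(labs)), n_draws, length(labs))
  z <- sweep(z, 2L, sqrt(n_g), "/")
  colnames(z) <- labs
  s2_null <- rchisq(n_draws, df) / df
  tmat <- (z[, comparators, drop = FALSE] - z[, wt_label]) /
    sqrt(outer(s2_null, (1 / n_g[comparators] + 1 / n_g[wt_label])))
  max_abs_t <- apply(abs(tmat), 1L, max)
  p <- vapply(abs(t_obs), function(tk) {
    (1 + sum(max_abs_t >= tk)) / (n_draws + 1)
  }, numeric(1))
  tibble(construct = comparators,
         estimate = unname(m_g[comparators] - m_g[wt_label]),
         statistic = unname(t_obs), p_value = unname(p), note = NA_character_)
}

#' Compare each construct to wild type (many-to-one)
#'
#' For each metric, a one-way layout with pooled within-group variance and a
#' Dunnett-type many-to-one comparison of every construct against the
#' reference, with familywise adjustment by seeded parametric resampling of
#' the max-|t| null statistic.  Strictly positive right-skewed kinetics
#' (`t_half_ms`, `tau_s`, `affinity_index`) are compared on the log scale;
#' the inhibition ratio on its natural scale.  Unequal group sizes enter the
#' unbalanced statistic directly.
#'
#' @param cells Per-cell summary tibble (see [aggregate_screen()]); cells
#'   flagged `no_current` are excluded from testing.
#' @param wt_label Reference construct label.
#' @param metrics Metric columns to test.
#' @param log_metrics Subset of `metrics` compared on the log scale.
#' @param n_draws Number of null resampling draws.
#' @param seed Integer seed for the resampling null.
#' @return A tibble: `metric`, `construct`, `estimate` (mean difference on
#'   the comparison scale), `statistic`, `p_value`, `significance`
#'   (`""`, `"*"` p < 0.05, `"**"` p < 0.01) and `note`.
#' @export
compare_to_wt <- function(cells, wt_label = "WT", metrics = .screen_metrics,
                          log_metrics = .screen_log_metrics,
                          n_draws = 50000L, seed = 1L) {
  if (!"construct" %in% names(cells)) {
    abort("`cells` needs a `construct` column.",
          class = "pipgate_error_missing_column")
  }
  if ("no_current" %in% names(cells)) {
    cells <- cells[!isTRUE_vec(cells$no_current), , drop = FALSE]
  }
  if (sum(cells$construct == wt_label) < 2L) {
    abort(sprintf("reference `%s` needs at least 2 cells.", wt_label),
          class = "pipgate_error_precondition")
  }
  metrics <- intersect(metrics, names(cells))
  res <- purrr::imap_dfr(setNames(metrics, metrics), function(m, nm) {
    v <- cells[[m]]
    if (m %in% log_metrics) {
      bad <- is.finite(v) & v <= 0
      v[bad] <- NA_real_
      v <- log(v)
    }
    out <- dunnett_one_metric(v, cells$construct, wt_label,
                              n_draws = n_draws,
                              seed = derive_seed(seed, match(nm, metrics)))
    out$metric <- nm
    out
  })
  res$significance <- dplyr::case_when(
    !is.finite(res$p_value) ~ "",
    res$p_value < 0.01 ~ "**",
    res$p_value < 0.05 ~ "*",
    TRUE ~ "")
  res[, c("metric", "construct", "estimate", "statistic", "p_value",
          "significance", "note")]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Classify construct phenotypes
#'
#' Deterministic flag assignment from per-construct means and many-to-one
#' p-values: `faster_decay`/`slower_decay` (t_half vs reference, p < alpha),
#' `faster_recovery`/`slower_recovery` (tau), `reduced_inhibition`
#' (inhibition ratio significantly above the reference but still <= 1) and
#' `potentiated` (significantly above the reference with mean ratio > 1).
#' `no_current` is assigned only from the explicit marker on the input cells.
#'
#' @param aggregates Output of [aggregate_screen()].
#' @param comparisons Output of [compare_to_wt()].
#' @param wt_label Reference construct label.
#' @param alpha Significance level for flag assignment.
#' @param no_current_constructs Character vector of construct labels whose
#'   cells carried no OAG-evoked current.
#' @return A tibble with one row per non-reference construct and logical
#'   flag columns.
#' @export
classify_constructs <- function(aggregates, comparisons, wt_label = "WT",
                                alpha = 0.05, no_current_constructs = character()) {
  wt_means <- aggregates[aggregates$construct == wt_label, c("metric", "mean")]
  names(wt_means)[2L] <- "wt_mean"
  tab <- aggregates |>
    dplyr::filter(.data$construct != wt_label) |>
    dplyr::left_join(wt_means, by = "metric") |>
    dplyr::left_join(
      comparisons[, c("metric", "construct", "p_value")],
      by = c("metric", "construct"))
  flag <- function(metric, direction) {
    sub <- tab[tab$metric == metric, , drop = FALSE]
    sig <- is.finite(sub$p_value) & sub$p_value < alpha
    dirn <- if (direction == "less") sub$mean < sub$wt_mean else
      sub$mean > sub$wt_mean
    setNames(sig & dirn, sub$construct)
  }
  constructs <- union(setdiff(unique(aggregates$construct), wt_label),
                      no_current_constructs)
  fd <- flag("t_half_ms", "less"); sdn <- flag("t_half_ms", "greater")
  fr <- flag("tau_s", "less"); sr <- flag("tau_s", "greater")
  ratio_up <- flag("inhibition_ratio", "greater")
  ratio_mean <- tab$mean[tab$metric == "inhibition_ratio"]
  names(ratio_mean) <- tab$construct[tab$metric == "inhibition_ratio"]
  out <- tibble(
    construct = constructs,
    faster_decay = unname(fd[constructs] %in% TRUE),
    slower_decay = unname(sdn[constructs] %in% TRUE),
    faster_recovery = unname(fr[constructs] %in% TRUE),
    slower_recovery = unname(sr[constructs] %in% TRUE),
    reduced_inhibition = unname((ratio_up[constructs] %in% TRUE) &
                                  ratio_mean[constructs] <= 1),
    potentiated = unname((ratio_up[constructs] %in% TRUE) &
                           ratio_mean[constructs] > 1),
    no_current = constructs %in% no_current_constructs
  )
  out
}

#' Full screening stage
#'
#' Aggregates per-cell summaries, runs the many-to-one comparison against
#' the reference construct and assigns phenotype flags.  Rerunning with the
#' same seed reproduces the result exactly.
#'
#' @inheritParams compare_to_wt
#' @param alpha Significance level for classification.
#' @return An object of class `screen_result`: a list with `aggregate`,
#'   `comparisons`, `flags`, plus the seed and draw count used.
#' @export
screen_constructs <- function(cells, wt_label = "WT", n_draws = 50000L,
                              seed = 1L, alpha = 0.05) {
  no_cur <- if ("no_current" %in% names(cells)) {
    unique(cells$construct[isTRUE_vec(cells$no_current)])
  } else character()
  test_cells <- if ("no_current" %in% names(cells)) {
    cells[!isTRUE_vec(cells$no_current), , drop = FALSE]
  } else cells
  agg <- aggregate_screen(test_cells)
  cmp <- compare_to_wt(test_cells, wt_label, n_draws = n_draws, seed = seed)
  flags <- classify_constructs(agg, cmp, wt_label, alpha, no_cur)
  structure(
    list(aggregate = agg, comparisons = cmp, flags = flags,
         wt_label = wt_label, seed = as.integer(seed),
         n_draws = as.integer(n_draws), alpha = alpha),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> reference %s; %d construct(s); seed %d, %d draws\n",
              x$wt_label, nrow(x$flags), x$seed, x$n_draws))
  print(x$flags)
  invisible(x)
}
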