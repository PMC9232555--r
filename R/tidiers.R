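# broom-style accessors for fit objects and screen results.

#' Tidy a kinetic or dose-response fit
#'
#' @param x A `decay_fit`, `recovery_fit` or `hill_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.pipgate_fit <- function(x, ...) {
  x$estimate
}

#' One-row fit summary
#'
#' @param x A `decay_fit`, `recovery_fit` or `hill_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `converged`, `reason`, `rss`, `n`.
#' @exportS3Method generics::glance
glance.pipgate_fit <- function(x, ...) {
  tibble(model = x$model, converged = x$converged, reason = x$reason,
         rss = x$rss, n = x$n)
}

#' Tidy a screening result
#'
#' @param x A `screen_result` from [screen_constructs()].
#' @param ... Unused.
#' @return The many-to-one comparison table joined with per-construct means.
#' @exportS3Method generics::tidy
tidy.screen_result <- function(x, ...) {
  dplyr::left_join(
    x$comparisons,
    x$aggregate[, c("construct", "metric", "n", "mean", "sem")],
    by = c("construct", "metric"))
}

#' @exportS3Method generics::glance
glance.screen_result <- function(x, ...) {
  tibble(wt_label = x$wt_label,
         n_constructs = nrow(x$flags),
         n_flagged = sum(rowSums(as.matrix(x$flags[, -1])) > 0),
         seed = x$seed, n_draws = x$n_draws, alpha = x$alpha)
}
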