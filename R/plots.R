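# QC plotting: autoplot methods for traces, simulations, fits and screens.

#' @exportS3Method ggplot2::autoplot
autoplot.current_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$current_nA)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (nA)",
                  title = trace_meta(object)$construct) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fret_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "FRET ratio") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gating_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time_s", "Po", "pip2_uM", "dag_uM")],
    -"time_s", names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hill_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  cf <- setNames(object$estimate$estimate, object$estimate$term)
  grid <- tibble(conc_uM = exp(seq(log(min(object$data$conc_uM)),
                                   log(max(object$data$conc_uM)),
                                   length.out = 200)))
  grid$response <- cf["r_max"] * grid$conc_uM^cf["hill_n"] /
    (cf["ec50_uM"]^cf["hill_n"] + grid$conc_uM^cf["hill_n"])
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$conc_uM, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "response") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.screen_result <- function(object, ...) {
  ggplot2::ggplot(object$aggregate,
                  ggplot2::aes(x = .data$construct, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean +/- SEM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
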