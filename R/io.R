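# Trace files: CSV (time_s, value[, voltage_mV]) plus a JSON metadata
# sidecar carrying schema version, kind, construct, protocol, seed and the
# generator truth block.  All times are stored in seconds; millisecond input
# columns are accepted and converted.

sidecar_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    sub("\\.csv$", ".json", path, ignore.case = TRUE)
  } else paste0(path, ".json")
}

protocol_to_list <- function(protocol) {
  if (is.null(protocol)) return(NULL)
  unclass(protocol)
}

protocol_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  do.call(voltage_protocol, x)
}

#' Write a trace to CSV with a JSON metadata sidecar
#'
#' The CSV carries exactly the columns `time_s`, `value` and (when present)
#' `voltage_mV`; the sidecar (`<name>.json`) carries the metadata from
#' [trace_meta()], including the schema version and the generating truth.
#'
#' @param trace A `current_trace` or `fret_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- trace_meta(trace)
  if (is.null(meta$kind)) {
    meta$kind <- if ("ratio" %in% names(trace)) "fret" else "current"
    meta$schema_version <- "1.0"
  }
  value_col <- if (meta$kind == "fret") "ratio" else "current_nA"
  df <- data.frame(time_s = trace$time_s, value = trace[[value_col]])
  if ("voltage_mV" %in% names(trace)) df$voltage_mV <- trace$voltage_mV
  utils::write.csv(df, path, row.names = FALSE)
  meta_out <- meta
  meta_out$protocol <- protocol_to_list(meta$protocol)
  jsonlite::write_json(meta_out, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' Validates the schema (exact column names, strictly increasing time,
#' sidecar with `schema_version`) and reconstructs a `current_trace` or
#' `fret_trace` with its metadata.  A `time_ms` column is accepted and
#' converted to seconds.  Validation failures raise classed errors:
#' `pipgate_error_missing_column`, `pipgate_error_nonmonotone_time`,
#' `pipgate_error_schema`.
#'
#' @param path CSV path.
#' @return A trace tibble with metadata (see [trace_meta()]).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "pipgate_error_io")
  }
  df <- utils::read.csv(path, check.names = TRUE)
  if ("time_ms" %in% names(df) && !"time_s" %in% names(df)) {
    df$time_s <- df$time_ms / 1000
    df$time_ms <- NULL
  }
  for (cl in c("time_s", "value")) {
    if (!cl %in% names(df)) {
      abort(sprintf("required column `%s` missing in %s", cl, path),
            class = "pipgate_error_missing_column")
    }
  }
  extra <- setdiff(names(df), c("time_s", "value", "voltage_mV"))
  if (length(extra)) {
    abort(sprintf("unexpected column(s) in %s: %s", path,
                  paste(extra, collapse = ", ")),
          class = "pipgate_error_schema")
  }
  if (any(diff(df$time_s) <= 0)) {
    abort(sprintf("time column not strictly increasing in %s", path),
          class = "pipgate_error_nonmonotone_time")
  }
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(sprintf("metadata sidecar missing: %s", sp),
          class = "pipgate_error_schema")
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$schema_version)) {
    abort(sprintf("sidecar %s lacks `schema_version`", sp),
          class = "pipgate_error_schema")
  }
  if (is.null(meta$kind) || !meta$kind %in% c("current", "fret")) {
    abort(sprintf("sidecar %s has unknown `kind`", sp),
          class = "pipgate_error_schema")
  }
  meta$protocol <- protocol_from_list(meta$protocol)
  out <- tibble(time_s = df$time_s)
  if (meta$kind == "fret") out$ratio <- df$value else out$current_nA <- df$value
  if ("voltage_mV" %in% names(df)) out$voltage_mV <- df$voltage_mV
  new_trace(out, meta, meta$kind)
}

#' Default run configuration
#'
#' The shipped defaults for protocol, gating, VSP episode, cascade, noise,
#' panel and statistics stages, as a plain list suitable for YAML round
#' trips.  Units are explicit in field names.
#'
#' @param seed Base seed recorded in the config.
#' @return A named list (class `pipgate_config`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    schema_version = "1.0",
    seed = as.integer(seed),
    protocol = protocol_to_list(voltage_protocol(n_pulses = 6L)),
    gating_wt = .pipgate_wt_defaults,
    vsp = unclass(vsp_params()),
    cascade = unclass(cascade_params()),
    noise = list(sigma_current_nA = 0.02, baseline_drift_nA_s = 0),
    panel = list(constructs = c("WT", "R437Q"), n_cells = 6L,
                 cell_variability_cv = 0.15, oag_uM = 50),
    analysis = list(decay_skip_ms = 5, recovery_skip_ms = 20,
                    n_plateau_pulses = 3L),
    stats = list(n_draws = 50000L, alpha = 0.05)
  ), class = "pipgate_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A configuration list, e.g. [default_run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns the configuration list.  A write/read round trip is identical.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config not found: %s", path), class = "pipgate_error_io")
  }
  structure(yaml::read_yaml(path), class = "pipgate_config")
}

#' Run manifest
#'
#' Reproducibility record written next to pipeline outputs: configuration
#' hash, seeds, package version and the produced files.
#'
#' @param config Configuration list used for the run.
#' @param seed Seed actually used.
#' @param outputs Character vector of produced files.
#' @param path Optional JSON path to write the manifest to.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seed, outputs = character(), path = NULL) {
  man <- list(
    schema_version = "1.0",
    package = "pipgate",
    version = as.character(utils::packageVersion("pipgate")),
    config_hash = rlang::hash(config),
    seed = as.integer(seed),
    outputs = outputs,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}
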