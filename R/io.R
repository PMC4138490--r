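# Trace and metrics I/O: full-precision CSV with a JSON provenance
# sidecar.

#' Write a trace to CSV (with JSON sidecar)
#'
#' Values are serialised with 17 significant digits so that a
#' write-then-read round trip is bit-exact.  A JSON sidecar
#' (`<path>.meta.json`) stores the protocol attributes, configuration
#' hash and package version.
#'
#' @param trace a `ubc_trace` (or plain data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  utils::write.table(fmt, path, sep = ",", row.names = FALSE,
                     quote = FALSE, col.names = names(df))
  meta <- list(
    columns = names(df),
    stim_onset = attr(trace, "stim_onset"),
    stim_end = attr(trace, "stim_end"),
    holding_current = attr(trace, "holding_current"),
    dt = attr(trace, "dt"),
    mode = attr(trace, "mode"),
    max_occupancy_error = attr(trace, "max_occupancy_error"),
    config_hash = attr(trace, "config_hash"),
    package_version = as.character(utils::packageVersion("ubcsim")),
    units = list(time = "ms", v = "mV", ca = "mM", i = "nA",
                 ramp_slope = "mV/s")
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path; the sidecar `<path>.meta.json` is restored into
#'   attributes when present.
#' @return a `ubc_trace` data.frame.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    for (a in c("stim_onset", "stim_end", "holding_current", "dt", "mode",
                "max_occupancy_error", "config_hash"))
      attr(df, a) <- meta[[a]]
  }
  class(df) <- c("ubc_trace", "data.frame")
  df
}

#' Write metrics as JSON
#'
#' @param metrics named list (e.g. a `ubc_spike_metrics` or
#'   `ubc_lor_metrics`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
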