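#' Write / read voltage traces as CSV
#'
#' Long-format CSV (`time_ms`, `neuron_id`, `v_mv`) with the sampling
#' step recorded in a header comment; round-trips the traces exactly at
#' full double precision.
#'
#' @param traces A single numeric trace or a list of traces sharing `dt`.
#' @param path Output file.
#' @param dt Sampling step (ms); taken from the trace attribute when
#'   present.
#' @return `read_voltage_csv()` returns a list of traces with attribute
#'   `dt`; `write_voltage_csv()` its input, invisibly.
#' @export
write_voltage_csv <- function(traces, path, dt = NULL) {
  if (!is.list(traces)) traces <- list(traces)
  if (is.null(dt)) dt <- attr(traces[[1]], "dt")
  stopifnot(is.numeric(dt), dt > 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_ms=%.17g", dt), con)
  df <- do.call(rbind, lapply(seq_along(traces), function(i) {
    v <- as.numeric(traces[[i]])
    data.frame(time_ms = (seq_along(v) - 1) * dt, neuron_id = i, v_mv = v)
  }))
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "d")
  invisible(traces)
}

#' @rdname write_voltage_csv
#' @export
read_voltage_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  dt <- as.numeric(sub("# dt_ms=", "", hdr, fixed = TRUE))
  df <- utils::read.csv(path, skip = 1)
  out <- lapply(split(df$v_mv, df$neuron_id), function(v) {
    attr(v, "dt") <- dt
    v
  })
  attr(out, "dt") <- dt
  unname(out)
}

#' Write / read spike patterns as two-column text
#'
#' Spike trains are stored as (`neuron_id`, `time_ms`) rows; the shared
#' Up intervals of sleep-like patterns go to a `<path>.up` sidecar
#' (`start_ms`, `end_ms`).
#'
#' @param patterns List of `spike_pattern`s (one per neuron).
#' @param path Output file (sidecar derived from it).
#' @return `read_spike_patterns()` returns the list of patterns;
#'   `write_spike_patterns()` its input, invisibly.
#' @export
write_spike_patterns <- function(patterns, path) {
  df <- do.call(rbind, lapply(seq_along(patterns), function(i)
    if (length(patterns[[i]]$spikes))
      data.frame(neuron_id = i, time_ms = patterns[[i]]$spikes)
    else NULL))
  if (is.null(df)) df <- data.frame(neuron_id = integer(0),
                                    time_ms = numeric(0))
  attr(df, "duration_ms") <- patterns[[1]]$duration_ms
  con <- file(path, "w")
  writeLines(sprintf("# duration_ms=%.17g n_neurons=%d",
                     patterns[[1]]$duration_ms, length(patterns)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, qmethod = "d")
  close(con)
  up <- patterns[[1]]$up_intervals
  if (nrow(up)) {
    utils::write.table(
      data.frame(start_ms = up[, 1], end_ms = up[, 2]),
      paste0(path, ".up"), sep = "\t", row.names = FALSE, qmethod = "d")
  }
  invisible(patterns)
}

#' @rdname write_spike_patterns
#' @export
read_spike_patterns <- function(path) {
  hdr <- strsplit(sub("^# ", "", readLines(path, n = 1)), " ")[[1]]
  duration_ms <- as.numeric(sub("duration_ms=", "", hdr[1], fixed = TRUE))
  n_neurons <- as.integer(sub("n_neurons=", "", hdr[2], fixed = TRUE))
  df <- utils::read.delim(path, skip = 1)
  up_path <- paste0(path, ".up")
  up <- if (file.exists(up_path)) {
    u <- utils::read.delim(up_path)
    cbind(u$start_ms, u$end_ms)
  } else matrix(numeric(0), ncol = 2)
  lapply(seq_len(n_neurons), function(i)
    new_spike_pattern(df$time_ms[df$neuron_id == i], up, duration_ms))
}
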