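#' Construct an electrophysiology trace
#'
#' A trace is a tibble with a uniformly sampled `time` column (ms) and one
#' value column (current in pA or voltage in mV), carrying metadata as
#' attributes: sampling interval `dt`, `unit`, `stim_times` (ms) and a
#' `condition` label.
#'
#' @param df Data frame with a `time` column and the value column.
#' @param unit `"pA"` or `"mV"` (free-form allowed).
#' @param value_col Name of the value column, default `"current"`.
#' @param stim_times Stimulus times (ms) within the record.
#' @param condition Condition label (e.g. `"combined"`, `"tboa"`).
#' @param tol Relative tolerance for uniform sampling check.
#'
#' @return The tibble with class `"ephys_trace"` prepended.
#' @examples
#' tr <- new_trace(tibble::tibble(time = seq(0, 10, 0.1), current = 0))
#' trace_dt(tr)
#' @export
new_trace <- function(df, unit = "pA", value_col = "current",
                      stim_times = numeric(), condition = NA_character_,
                      tol = 1e-6) {
  stopifnot(is.data.frame(df), "time" %in% names(df), value_col %in% names(df))
  tt <- df$time
  if (length(tt) < 2L) stop("new_trace: need at least 2 samples", call. = FALSE)
  d <- diff(tt)
  dt <- stats::median(d)
  if (dt <= 0 || any(abs(d - dt) > tol * max(dt, 1))) {
    stop("new_trace: time column must be uniformly sampled and increasing",
         call. = FALSE)
  }
  if (any(!is.finite(df[[value_col]]))) {
    stop("new_trace: samples must be finite", call. = FALSE)
  }
  if (length(stim_times) &&
      (min(stim_times) < tt[1] - dt || max(stim_times) > tt[length(tt)] + dt)) {
    stop("new_trace: stimulus times must lie within the record", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("ephys_trace", class(out))
  attr(out, "dt") <- dt
  attr(out, "t0") <- tt[1]
  attr(out, "unit") <- unit
  attr(out, "value_col") <- value_col
  attr(out, "stim_times") <- as.numeric(stim_times)
  attr(out, "condition") <- condition
  out
}

#' @rdname new_trace
#' @param trace An `"ephys_trace"`.
#' @export
trace_dt <- function(trace) attr(trace, "dt")

#' @rdname new_trace
#' @export
trace_unit <- function(trace) attr(trace, "unit")

#' @rdname new_trace
#' @export
stim_times <- function(trace) attr(trace, "stim_times")

trace_values <- function(trace) trace[[attr(trace, "value_col") %||% "current"]]

# rebuild a trace with new samples, preserving metadata
with_values <- function(trace, values, condition = attr(trace, "condition")) {
  vc <- attr(trace, "value_col") %||% "current"
  df <- tibble::tibble(time = trace$time)
  df[[vc]] <- values
  new_trace(df, unit = attr(trace, "unit"), value_col = vc,
            stim_times = attr(trace, "stim_times"), condition = condition)
}

#' Read / write traces as delimited text with a JSON sidecar
#'
#' `write_trace()` stores the samples as a two-column comma-separated file
#' (time ms, value) plus `<path>.json` holding `dt`, `t0`, `unit`,
#' `value_col`, `stim_times` and `condition`. `read_trace()` restores the
#' trace; the round trip preserves samples to at least 12 significant digits.
#'
#' @param trace An `"ephys_trace"`.
#' @param path File path for the delimited samples (sidecar is `path` +
#'   `".json"`).
#'
#' @return `read_trace()` returns the trace; `write_trace()` returns `path`
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ephys_trace"))
  vc <- attr(trace, "value_col")
  df <- data.frame(time = trace$time, value = trace[[vc]])
  names(df)[2] <- vc
  utils::write.csv(format(df, digits = 15, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(dt = attr(trace, "dt"), t0 = attr(trace, "t0"),
               unit = attr(trace, "unit"), value_col = vc,
               stim_times = attr(trace, "stim_times"),
               condition = attr(trace, "condition"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("read_trace: no such file: ", path, call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("read_trace: missing JSON sidecar ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  if (ncol(df) != 2L || names(df)[1] != "time") {
    stop("read_trace: expected two columns starting with `time`", call. = FALSE)
  }
  if (anyNA(df)) stop("read_trace: ragged or non-numeric rows", call. = FALSE)
  new_trace(df, unit = meta$unit %||% "pA",
            value_col = names(df)[2],
            stim_times = meta$stim_times %||% numeric(),
            condition = meta$condition %||% NA_character_)
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %d samples @ dt %.4g ms (%s), %d stimuli%s\n",
              nrow(x), attr(x, "dt"), attr(x, "unit"),
              length(attr(x, "stim_times")),
              if (is.na(attr(x, "condition"))) ""
              else paste0(", condition \"", attr(x, "condition"), "\"")))
  NextMethod()
}
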