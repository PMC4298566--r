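# Percent dF/F0 normalization of fluorescence traces, with the two F0
# conventions used by plate-reader and stopped-flow recordings, and
# buffer-control subtraction.

#' Fluorescence trace container
#'
#' @param times sample times (s), strictly increasing.
#' @param values intensities (arbitrary units), finite.
#' @param event_index 1-based index of the first post-event sample (compound
#'   addition for plate-reader traces; mixing start for stopped-flow, where
#'   the whole trace is post-mixing and the index is typically 1).
#' @param instrument `"plate_reader"` or `"stopped_flow"`.
#' @param excitation optional per-sample excitation wavelength (nm); in the
#'   alternating-excitation plate-reader protocol the indicator is read at
#'   520 nm while 485-nm samples only serve photo-activation.
#' @return an object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, values, event_index = NULL,
                               instrument = c("plate_reader", "stopped_flow"),
                               excitation = NULL) {
  instrument <- match.arg(instrument)
  stopifnot(length(times) == length(values), all(is.finite(values)),
            all(diff(times) > 0))
  if (instrument == "plate_reader") {
    if (is.null(event_index) || event_index <= 1 ||
        event_index > length(values))
      stop("plate-reader traces need 1 < event_index <= length")
  } else if (length(values) < 3) {
    stop("stopped-flow traces need at least 3 samples")
  }
  if (!is.null(excitation)) stopifnot(length(excitation) == length(values))
  structure(list(times = times, values = values,
                 event_index = if (is.null(event_index)) NULL
                               else as.integer(event_index),
                 instrument = instrument, excitation = excitation),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat("Fluorescence trace (", x$instrument, "): ", length(x$values),
      " samples", sep = "")
  if (!is.null(x$event_index)) cat(", event at sample", x$event_index)
  cat("\n")
  invisible(x)
}

# Restrict an alternating-excitation trace to its measurement samples.
measurement_samples <- function(trace, measure_nm = 520) {
  if (is.null(trace$excitation)) return(trace)
  keep <- trace$excitation == measure_nm
  if (!any(keep)) stop("no samples at the measurement wavelength ", measure_nm)
  e <- trace$event_index
  new_e <- if (is.null(e)) NULL else sum(which(keep) < e) + 1L
  fluorescence_trace(trace$times[keep], trace$values[keep],
                     event_index = new_e, instrument = trace$instrument)
}

new_normalized_trace <- function(times, dff0, f0, convention, event_index,
                                 control_subtracted = FALSE) {
  structure(list(times = times, dff0_percent = dff0, f0 = f0,
                 convention = convention, event_index = event_index,
                 control_subtracted = control_subtracted),
            class = "normalized_trace")
}

#' Plate-reader dF/F0 (%)
#'
#' F0 is the mean basal fluorescence before application of buffer or
#' compounds: the mean of all samples preceding `event_index`. Samples taken
#' at the 485-nm activation wavelength (when tagged) are excluded.
#'
#' @param trace a [fluorescence_trace()] with `instrument = "plate_reader"`.
#' @param measure_nm measurement excitation wavelength used to filter tagged
#'   traces.
#' @return an object of class `normalized_trace` (convention
#'   `"pre_event_mean"`).
#' @export
dff0_platereader <- function(trace, measure_nm = 520) {
  stopifnot(trace$instrument == "plate_reader")
  trace <- measurement_samples(trace, measure_nm)
  e <- trace$event_index
  if (e < 3) stop("need at least 2 samples before the event")
  f0 <- mean(trace$values[seq_len(e - 1)])
  if (f0 <= 0) stop("normalization error: F0 <= 0")
  new_normalized_trace(trace$times, 100 * (trace$values - f0) / f0, f0,
                       "pre_event_mean", e)
}

#' Stopped-flow dF/F0 (%)
#'
#' F0 is the mean of the first three data points recorded immediately after
#' mixing.
#'
#' @param trace a [fluorescence_trace()] with `instrument = "stopped_flow"`.
#' @return an object of class `normalized_trace` (convention
#'   `"first_three_mean"`).
#' @export
dff0_stoppedflow <- function(trace) {
  stopifnot(trace$instrument == "stopped_flow")
  f0 <- mean(trace$values[1:3])
  if (f0 <= 0) stop("normalization error: F0 <= 0")
  new_normalized_trace(trace$times, 100 * (trace$values - f0) / f0, f0,
                       "first_three_mean", trace$event_index)
}

#' Normalize a fluorescence trace by the convention of its instrument
#'
#' @param trace a [fluorescence_trace()].
#' @param ... passed to the instrument-specific routine.
#' @return a `normalized_trace`.
#' @export
dff0 <- function(trace, ...) {
  switch(trace$instrument,
         plate_reader = dff0_platereader(trace, ...),
         stopped_flow = dff0_stoppedflow(trace))
}

#' Subtract a buffer-control dF/F0 signal
#'
#' Pointwise difference of the percent signals; both traces must share the
#' F0 convention, length and time base.
#'
#' @param signal,control `normalized_trace` objects.
#' @return a `normalized_trace` with `control_subtracted = TRUE`.
#' @export
subtract_control <- function(signal, control) {
  if (signal$convention != control$convention)
    stop("alignment error: traces use different F0 conventions")
  if (length(signal$dff0_percent) != length(control$dff0_percent))
    stop("alignment error: traces differ in length")
  dt <- stats::median(diff(signal$times))
  if (any(abs(signal$times - control$times) > dt))
    stop("alignment error: time bases differ by more than one sample interval")
  new_normalized_trace(signal$times,
                       signal$dff0_percent - control$dff0_percent,
                       signal$f0, signal$convention, signal$event_index,
                       control_subtracted = TRUE)
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat("dF/F0 trace (", x$convention, "): ", length(x$dff0_percent),
      " samples, F0 = ", sprintf("%.3f", x$f0), sep = "")
  if (isTRUE(x$control_subtracted)) cat(", control-subtracted")
  cat("\n")
  invisible(x)
}

#' @export
plot.normalized_trace <- function(x, ...) {
  graphics::plot(x$times, x$dff0_percent, type = "l",
                 xlab = "time (s)", ylab = expression(Delta * F / F[0] ~ "(%)"),
                 ...)
  if (!is.null(x$event_index))
    graphics::abline(v = x$times[x$event_index], lty = 2, col = "red")
  invisible(x)
}

#' Read a delimited fluorescence trace
#'
#' Expects columns `time`, `value` and optionally `excitation`.
#'
#' @param path CSV path.
#' @param event_index 1-based first post-event sample.
#' @param instrument instrument tag.
#' @return a [fluorescence_trace()].
#' @export
read_trace <- function(path, event_index = NULL,
                       instrument = c("plate_reader", "stopped_flow")) {
  df <- utils::read.csv(path)
  fluorescence_trace(df$time, df$value, event_index = event_index,
                     instrument = match.arg(instrument),
                     excitation = df$excitation)
}

#' Write a normalized trace as CSV
#'
#' @param x a `normalized_trace`.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_normalized_trace <- function(x, path) {
  utils::write.csv(data.frame(time = x$times, dff0_percent = x$dff0_percent),
                   path, row.names = FALSE)
  invisible(path)
}
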