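#' Periodic flow waveform
#'
#' A sampled scalar flow rate over one cardiac cycle. Samples are taken at
#' strictly increasing times within `[0, period)`; the waveform is periodic
#' and the closing sample at `t = period` (equal to the first sample) is
#' implicit, never stored. Flow is signed: positive means flow in the forward
#' direction of the owning plane or tear.
#'
#' @param time_s Sample times in seconds, strictly increasing, all `< period`.
#' @param flow_L_min Signed flow rate samples in L/min, same length.
#' @param period_s Cycle period in seconds; defaults to the implied uniform
#'   extension `time_s[n] + mean(diff(time_s))`.
#' @return An object of class `flow_waveform`.
#' @examples
#' w <- flow_waveform(seq(0, 0.75, by = 0.05), sin(seq(0, 0.75, by = 0.05) * 2 * pi / 0.8),
#'                    period_s = 0.8)
#' cycle_mean(w)
#' rfi(w)
#' @export
flow_waveform <- function(time_s, flow_L_min, period_s = NULL) {
  stopifnot(is.numeric(time_s), is.numeric(flow_L_min),
            length(time_s) == length(flow_L_min), length(time_s) >= 2)
  if (any(!is.finite(time_s)) || any(!is.finite(flow_L_min)))
    stop("waveform samples must be finite")
  if (any(diff(time_s) <= 0))
    stop("time samples must be strictly increasing (duplicate or reversed time stamps)")
  if (is.null(period_s)) period_s <- time_s[length(time_s)] + mean(diff(time_s))
  stopifnot(period_s > time_s[length(time_s)])
  structure(list(time_s = as.numeric(time_s),
                 flow = as.numeric(flow_L_min),
                 period_s = as.numeric(period_s)),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("Flow waveform: %d samples over T = %.4g s; mean %.4g, range [%.4g, %.4g] L/min\n",
              length(x$time_s), x$period_s, cycle_mean(x),
              min(x$flow), max(x$flow)))
  invisible(x)
}

#' @export
plot.flow_waveform <- function(x, ..., xlab = "time (s)", ylab = "flow (L/min)") {
  graphics::plot(c(x$time_s, x$period_s), c(x$flow, x$flow[1]), type = "l",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# Trapezoid integral of f(t) over one full period, closing the cycle with the
# periodic wrap segment from the last sample back to the first.
trapz_period <- function(time_s, values, period_s) {
  tt <- c(time_s, period_s)
  vv <- c(values, values[1])
  sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
}

#' Cycle-mean flow of a waveform
#'
#' Trapezoid integral over one period (with periodic closure) divided by the
#' period.
#'
#' @param w A [flow_waveform()].
#' @return Cycle-mean flow in L/min.
#' @export
cycle_mean <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  trapz_period(w$time_s, w$flow, w$period_s) / w$period_s
}

#' Read / write a waveform as CSV
#'
#' Plain CSV with columns `time_s`, `flow_L_per_min`; the period is stored as
#' a commented header line `# period_s: <T>`.
#'
#' @param w A [flow_waveform()].
#' @param path File path.
#' @return `write_waveform_csv` returns `path` invisibly;
#'   `read_waveform_csv` returns a [flow_waveform()].
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "flow_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s: %.17g", w$period_s), con)
  utils::write.csv(data.frame(time_s = w$time_s, flow_L_per_min = w$flow),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  period <- if (grepl("^# period_s:", hdr))
    as.numeric(sub("^# period_s:", "", hdr)) else NULL
  d <- utils::read.csv(path, comment.char = "#")
  flow_waveform(d$time_s, d$flow_L_per_min, period_s = period)
}
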