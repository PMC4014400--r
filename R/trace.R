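#' Uniformly sampled recording trace
#'
#' Container for a uniformly sampled time series: an injected-current record
#' (pA) or a membrane-potential record (mV). All times are in milliseconds
#' package-wide.
#'
#' @param samples Numeric vector of sample values (pA for current, mV for
#'   voltage). Must be finite and non-empty.
#' @param dt Sample interval in ms (> 0).
#' @param t0 Time of the first sample in ms.
#' @param kind One of `"current"` or `"voltage"`.
#' @return An object of class `"trace"`: a list with elements `samples`, `dt`,
#'   `t0` and `kind`.
#' @examples
#' tr <- trace(c(0, 5, 5), dt = 1, kind = "current")
#' trace_duration(tr)
#' @export
trace <- function(samples, dt, t0 = 0, kind = c("current", "voltage")) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must all be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (ms)")
  structure(list(samples = samples, dt = dt, t0 = t0, kind = kind),
            class = "trace")
}

#' @rdname trace
#' @param x A `trace` object.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$samples) - 1) * x$dt
}

#' @rdname trace
#' @export
trace_duration <- function(x) {
  stopifnot(inherits(x, "trace"))
  length(x$samples) * x$dt
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace: %s, %d samples, dt = %g ms, t0 = %g ms, %.4g ms total>\n",
              x$kind, length(x$samples), x$dt, x$t0, trace_duration(x)))
  invisible(x)
}

#' Spike train
#'
#' Strictly increasing spike times (ms) within a recording span.
#'
#' @param times Numeric vector of spike times in ms, strictly increasing.
#' @param span Length-2 numeric `(start, end)` in ms containing all spike
#'   times. Defaults to the range of `times` (or `c(0, 0)` when empty).
#' @return An object of class `"spike_train"`.
#' @examples
#' st <- spike_train(c(10, 110, 215), span = c(0, 300))
#' isis(st)
#' @export
spike_train <- function(times, span = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (is.null(span)) {
    span <- if (length(times)) range(times) else c(0, 0)
  }
  span <- as.numeric(span)
  if (length(span) != 2L || span[2] < span[1])
    stop("span must be (start, end) with end >= start")
  if (length(times) && (times[1] < span[1] || times[length(times)] > span[2]))
    stop("all spike times must lie within span")
  structure(list(times = times, span = span), class = "spike_train")
}

#' @rdname spike_train
#' @param x A `spike_train`.
#' @export
isis <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  diff(x$times)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes over [%g, %g] ms>\n",
              length(x$times), x$span[1], x$span[2]))
  invisible(x)
}

# ---- delimited-text trace i/o -------------------------------------------

# Header lines start with '#'; keys are "key = value". Two dialects:
#   two-column      : time_ms <delim> value, dt inferred from the time column
#   single-column   : one value per row, '# dt_ms = <dt>' header required
# Delimiter may be a comma, a tab, or whitespace.
.parse_header <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

.split_fields <- function(x) strsplit(trimws(x), "[,\t ]+")

#' Read a trace from delimited text
#'
#' Reads either a two-column file (`time_ms, value`; the sample interval is
#' inferred from the time column and checked for uniformity) or a
#' single-column file whose `# dt_ms = ...` header declares the interval.
#' Header lines are prefixed with `#`; fields may be separated by commas,
#' tabs or whitespace.
#'
#' @param path Path to the file.
#' @param kind Trace kind; overrides any `# kind = ...` header.
#' @param tol Relative tolerance on time-column uniformity, as a fraction of
#'   the median interval.
#' @return A [trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, kind = NULL, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- .parse_header(lines)
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  fields <- .split_fields(body)
  ncol <- lengths(fields)
  if (any(ncol != ncol[1]))
    stop("inconsistent column count at row ", which(ncol != ncol[1])[1])
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad)) stop("non-numeric data at row ", bad[1], ": ", body[bad[1]])
  m <- do.call(rbind, vals)
  if (is.null(kind)) kind <- if (!is.null(hdr$kind)) hdr$kind else "current"
  if (ncol[1] == 2L) {
    tt <- m[, 1]; samples <- m[, 2]
    if (nrow(m) < 2L) stop("two-column trace needs at least 2 rows to infer dt")
    dts <- diff(tt)
    dt <- stats::median(dts)
    dev <- abs(dts - dt)
    if (any(dev > tol * dt)) {
      i <- which.max(dev)
      stop(sprintf(paste0("non-uniform sampling: interval before row %d deviates by ",
                          "%.3g ms from dt = %.6g ms (max deviation %.3g ms)"),
                   i + 1L, dts[i] - dt, dt, max(dev)))
    }
    trace(samples, dt = dt, t0 = tt[1], kind = kind)
  } else if (ncol[1] == 1L) {
    if (is.null(hdr$dt_ms))
      stop("single-column trace requires a '# dt_ms = ...' header in ", path)
    dt <- as.numeric(hdr$dt_ms)
    t0 <- if (!is.null(hdr$t0_ms)) as.numeric(hdr$t0_ms) else 0
    trace(m[, 1], dt = dt, t0 = t0, kind = kind)
  } else {
    stop("expected 1 or 2 columns, found ", ncol[1])
  }
}

#' Write a trace to delimited text
#'
#' @param x A [trace()].
#' @param path Output path.
#' @param format `"single"` writes one sample per row with a `dt_ms` header;
#'   `"two_col"` writes `time<TAB>value` rows. Both round-trip through
#'   [read_trace()] at full double precision.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, format = c("single", "two_col")) {
  stopifnot(inherits(x, "trace"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "single") {
    writeLines(c(sprintf("# dt_ms = %.17g", x$dt),
                 sprintf("# t0_ms = %.17g", x$t0),
                 sprintf("# kind = %s", x$kind),
                 sprintf("%.17g", x$samples)), con)
  } else {
    writeLines(c(sprintf("# kind = %s", x$kind),
                 sprintf("%.17g\t%.17g", trace_times(x), x$samples)), con)
  }
  invisible(path)
}

#' Read/write spike trains as one spike time (ms) per line
#'
#' An optional `# span_ms = start end` header records the recording span.
#'
#' @param path File path.
#' @return [read_spike_train()] returns a [spike_train()];
#'   [write_spike_train()] returns `path` invisibly.
#' @export
read_spike_train <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- .parse_header(lines)
  body <- lines[!grepl("^\\s*#", lines)]
  body <- trimws(body[nzchar(trimws(body))])
  times <- suppressWarnings(as.numeric(body))
  if (anyNA(times)) stop("non-numeric spike time at row ", which(is.na(times))[1])
  span <- if (!is.null(hdr$span_ms))
    as.numeric(strsplit(trimws(hdr$span_ms), "[,\t ]+")[[1]]) else NULL
  spike_train(times, span = span)
}

#' @rdname read_spike_train
#' @param x A [spike_train()].
#' @export
write_spike_train <- function(x, path) {
  stopifnot(inherits(x, "spike_train"))
  writeLines(c(sprintf("# span_ms = %.17g %.17g", x$span[1], x$span[2]),
               sprintf("%.17g", x$times)), path)
  invisible(path)
}

#' Detect spikes in a voltage trace by threshold crossing
#'
#' A spike is the first sample at or above `threshold` in each upward
#' crossing; further crossings within the refractory window are suppressed.
#' Spike times are reported at the sample (no sub-sample interpolation),
#' matching sampled acquisition.
#'
#' @param v A voltage [trace()].
#' @param threshold Threshold in mV. Must exceed the minimum of the trace.
#' @param refractory Refractory window in ms (>= `v$dt`).
#' @return A [spike_train()] spanning the trace.
#' @export
detect_spikes <- function(v, threshold, refractory = 2) {
  stopifnot(inherits(v, "trace"))
  if (v$kind != "voltage") stop("detect_spikes requires a voltage trace")
  if (refractory < v$dt) stop("refractory must be >= the sample interval")
  s <- v$samples
  if (threshold <= min(s))
    stop("threshold is at or below the trace minimum; every sample would cross")
  above <- s >= threshold
  onset <- which(above & !c(FALSE, above[-length(above)]))
  tt <- v$t0 + (onset - 1) * v$dt
  keep <- logical(length(tt))
  last <- -Inf
  for (i in seq_along(tt)) {
    if (tt[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- tt[i]
    }
  }
  span <- c(v$t0, v$t0 + trace_duration(v))
  spike_train(tt[keep], span = span)
}

#' Pulse-slope linearity check for a noise-stimulated recording
#'
#' For brief current pulses delivered to a well-compensated electrode, the
#' membrane-potential transient within each pulse is nearly a linear ramp
#' whose slope is proportional to the pulse amplitude (slope = I/C for an
#' ideal capacitor). This quality check fits a least-squares slope to the
#' voltage within each pulse — excluding the first sample of the pulse, which
#' carries the capacitative onset transient — and regresses the per-pulse
#' slopes on the pulse amplitudes.
#'
#' @param v Voltage [trace()].
#' @param i Current [trace()] sharing `dt` and span with `v`.
#' @param d Pulse duration in ms; must be a multiple of the sample interval,
#'   with pulse boundaries at multiples of `d`.
#' @return An object of class `"qc_report"`: per-pulse slopes (mV/ms) and
#'   amplitudes (pA), the linearity slope ((mV/ms)/pA) and its R².
#' @examples
#' # ideal 100 pF capacitor: slope per pulse = I/C, linearity exact
#' dt <- 0.05; d <- 1; amps <- c(-40, 10, 60, -90, 25)
#' i <- trace(rep(amps, each = d / dt), dt = dt, kind = "current")
#' v <- trace(-60 + cumsum(i$samples / 100 * dt), dt = dt, kind = "voltage")
#' pulse_slope_qc(v, i, d = d)
#' @export
pulse_slope_qc <- function(v, i, d) {
  stopifnot(inherits(v, "trace"), inherits(i, "trace"))
  if (v$kind != "voltage" || i$kind != "current")
    stop("pulse_slope_qc needs a voltage trace and a current trace")
  if (abs(v$dt - i$dt) > 1e-12 || length(v$samples) != length(i$samples))
    stop("voltage and current traces must share dt and length")
  n_per <- d / v$dt
  if (abs(n_per - round(n_per)) > 1e-9)
    stop("pulse duration d must be a multiple of the sample interval")
  n_per <- as.integer(round(n_per))
  if (n_per < 3L) stop("need at least 3 samples per pulse to fit a slope")
  n_pulse <- length(v$samples) %/% n_per
  if (n_pulse < 3L) stop("need at least 3 pulses for the linearity regression")
  slope <- amp <- numeric(n_pulse)
  tt <- (seq_len(n_per) - 1) * v$dt
  for (p in seq_len(n_pulse)) {
    idx <- ((p - 1L) * n_per + 1L):(p * n_per)
    amp[p] <- stats::median(i$samples[idx])
    # drop the first sample of the pulse (capacitative onset transient)
    slope[p] <- stats::coef(stats::lm.fit(cbind(1, tt[-1]), v$samples[idx][-1]))[2]
  }
  if (stats::sd(amp) == 0)
    stop("all pulse amplitudes identical; linearity regression is degenerate")
  fit <- stats::lm(slope ~ amp)
  structure(list(per_pulse_slope = slope,
                 per_pulse_amplitude = amp,
                 linearity_slope = unname(stats::coef(fit)[2]),
                 linearity_se = unname(summary(fit)$coefficients[2, 2]),
                 linearity_r2 = summary(fit)$r.squared,
                 n_pulses = n_pulse),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Pulse-slope linearity check\n")
  cat(sprintf("  pulses          : %d\n", x$n_pulses))
  cat(sprintf("  linearity slope : %.6g (mV/ms)/pA\n", x$linearity_slope))
  cat(sprintf("  linearity R^2   : %.6f\n", x$linearity_r2))
  invisible(x)
}

#' @rdname pulse_slope_qc
#' @param x A `qc_report`.
#' @param path Output path for the key/value text report.
#' @export
write_qc_report <- function(x, path) {
  stopifnot(inherits(x, "qc_report"))
  writeLines(c(sprintf("n_pulses = %d", x$n_pulses),
               sprintf("linearity_slope = %.10g", x$linearity_slope),
               sprintf("linearity_r2 = %.10g", x$linearity_r2),
               sprintf("per_pulse_amplitude = %s",
                       paste(sprintf("%.10g", x$per_pulse_amplitude), collapse = " ")),
               sprintf("per_pulse_slope = %s",
                       paste(sprintf("%.10g", x$per_pulse_slope), collapse = " "))),
             path)
  invisible(path)
}
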