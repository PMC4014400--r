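#' Predict spike times from a PRC and a recorded current
#'
#' Restarting the phase model at each actual spike, φ is integrated from 0
#' under the recorded injected current (held constant within each recorded
#' sample) with a fine time step; the first crossing of φ = 1 gives the
#' predicted next spike. Comparing predicted against actual interval
#' durations quantifies how much of the spike-time variance the phase model
#' accounts for.
#'
#' If φ fails to cross 1 within five mean periods the interval is marked
#' unpredicted (`NA`) and counted.
#'
#' @param prc A [tabulated_prc()].
#' @param current Injected-current [trace()] covering every actual interval.
#' @param actual Actual [spike_train()] of the episode.
#' @param omega Drift rate in spikes/ms; defaults to the reciprocal of the
#'   episode's mean ISI (the cell's average rate during the episode).
#' @param dt Integration step, ms (default 0.05).
#' @param refine Linear interpolation of the crossing within the final step
#'   (default `TRUE`; makes noiseless self-prediction exact).
#' @return An object of class `"prediction_report"`: `predicted_isis`,
#'   `actual_isis`, `variance_explained`, `n_unpredicted`, `dt_used`, `omega`.
#' @export
predict_spike_times <- function(prc, current, actual, omega = NULL,
                                dt = 0.05, refine = TRUE) {
  stopifnot(inherits(prc, "prc"), inherits(current, "trace"),
            inherits(actual, "spike_train"))
  st <- actual$times
  if (length(st) < 2L) stop("need at least 2 actual spikes")
  isi <- diff(st)
  if (is.null(omega)) omega <- 1 / mean(isi)
  if (omega <= 0) stop("omega must be > 0")
  k <- .prc_knots(prc)
  horizon <- 5 / omega
  pred <- vapply(seq_along(isi), function(a) {
    res <- cpp_phase_integrate(k$x, k$y, omega, dt, st[a], st[a] + horizon,
                               current$samples, current$t0, current$dt,
                               FALSE, refine, FALSE, 0)
    if (length(res$spikes)) res$spikes[1] - st[a] else NA_real_
  }, numeric(1))
  ve <- if (sum(!is.na(pred)) >= 3L)
    tryCatch(variance_explained(pred[!is.na(pred)], isi[!is.na(pred)]),
             error = function(e) NA_real_)   # e.g. clock-like train: SS_total = 0
  else NA_real_
  structure(list(predicted_isis = pred, actual_isis = isi,
                 variance_explained = ve,
                 n_unpredicted = sum(is.na(pred)),
                 dt_used = dt, omega = omega),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("Spike-time prediction from the phase model\n")
  cat(sprintf("  intervals          : %d (%d unpredicted)\n",
              length(x$actual_isis), x$n_unpredicted))
  cat(sprintf("  variance explained : %.4f\n", x$variance_explained))
  cat(sprintf("  omega              : %g spikes/ms (dt = %g ms)\n",
              x$omega, x$dt_used))
  invisible(x)
}

#' Proportion of interval variance explained by a prediction
#'
#' Sum-of-squares R²: 1 − SS_residual / SS_total, with SS_total taken about
#' the mean actual interval. This penalizes bias (it can be negative for
#' poor predictions), unlike the squared Pearson correlation, which is also
#' available.
#'
#' @param predicted,actual Paired interval durations, ms (>= 3 pairs).
#' @param method `"rss"` (default) or `"pearson"`.
#' @return A value in `(-Inf, 1]`.
#' @export
variance_explained <- function(predicted, actual, method = c("rss", "pearson")) {
  method <- match.arg(method)
  if (length(predicted) != length(actual)) stop("lengths differ")
  if (length(actual) < 3L) stop("need at least 3 interval pairs")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("actual intervals have zero variance")
  if (method == "rss") {
    1 - sum((actual - predicted)^2) / ss_tot
  } else {
    stats::cor(predicted, actual)^2
  }
}

#' Coefficient of variation of interspike intervals
#'
#' SD(ISI)/mean(ISI) with the n−1 denominator. The standard measure of
#' firing irregularity: ~0 for clock-like firing, 1 for a Poisson process.
#'
#' @param x A [spike_train()] (or a numeric vector of ISIs in ms) with at
#'   least 3 intervals.
#' @return The CV (dimensionless).
#' @export
isi_cv <- function(x) {
  v <- if (inherits(x, "spike_train")) isis(x) else as.numeric(x)
  if (length(v) < 3L) stop("need at least 3 interspike intervals")
  stats::sd(v) / mean(v)
}

#' Spike-train autocorrelogram
#'
#' Histogram of all ordered pairwise spike-time differences up to `max_lag`
#' (positive lags only; zero-lag self-pairs excluded). Periodic peaks at
#' multiples of the period indicate rhythmic firing; a flat profile beyond
#' the refractory gap indicates Poisson-like irregularity.
#'
#' @param spikes A [spike_train()].
#' @param binwidth Bin width, ms.
#' @param max_lag Maximum lag, ms (>= `binwidth`).
#' @param normalization `"counts"` (default) or `"rate"` (counts divided by
#'   n_spikes × binwidth, in spikes/ms).
#' @return An object of class `"autocorrelogram"`: `breaks` (bin edges, ms),
#'   `counts`, `normalization`.
#' @export
autocorrelogram <- function(spikes, binwidth = 2, max_lag = 500,
                            normalization = c("counts", "rate")) {
  stopifnot(inherits(spikes, "spike_train"))
  normalization <- match.arg(normalization)
  if (binwidth <= 0) stop("binwidth must be > 0")
  if (max_lag < binwidth) stop("max_lag must be >= binwidth")
  st <- spikes$times
  n_bins <- ceiling(max_lag / binwidth)
  breaks <- (0:n_bins) * binwidth
  counts <- numeric(n_bins)
  n <- length(st)
  if (n >= 2L) {
    hi <- findInterval(st + max_lag, st)   # last partner index per spike
    for (i in seq_len(n - 1L)) {
      if (hi[i] > i) {
        lags <- st[(i + 1L):hi[i]] - st[i]
        lags <- lags[lags <= max_lag]
        idx <- pmin(floor(lags / binwidth) + 1L, n_bins)
        tab <- tabulate(idx, nbins = n_bins)
        counts <- counts + tab
      }
    }
  }
  if (normalization == "rate" && n > 0) counts <- counts / (n * binwidth)
  structure(list(breaks = breaks, counts = counts,
                 normalization = normalization, n_spikes = n),
            class = "autocorrelogram")
}

#' @export
print.autocorrelogram <- function(x, ...) {
  cat(sprintf("<autocorrelogram: %d bins of %g ms, %s normalization, %d spikes>\n",
              length(x$counts), diff(x$breaks[1:2]), x$normalization, x$n_spikes))
  invisible(x)
}

#' @export
plot.autocorrelogram <- function(x, ...) {
  mids <- x$breaks[-1] - diff(x$breaks) / 2
  graphics::plot(mids, x$counts, type = "h", xlab = "lag (ms)",
                 ylab = x$normalization, ...)
  invisible(x)
}

#' Mean firing rate of a spike train
#'
#' (n − 1) spikes over the time from first to last spike, in spikes/s.
#'
#' @param spikes A [spike_train()] with at least 2 spikes.
#' @return Rate in spikes/s.
#' @export
mean_rate <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train"))
  st <- spikes$times
  if (length(st) < 2L) stop("need at least 2 spikes to estimate a rate")
  (length(st) - 1) / (st[length(st)] - st[1]) * 1000
}
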