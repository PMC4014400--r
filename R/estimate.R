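#' Number of phase bins for the charge regression
#'
#' The number of equal phase bins is the mean interspike interval divided by
#' the noise pulse duration (one pulse per bin on average, keeping the charge
#' regressors statistically independent), capped at 50.
#'
#' @param mean_isi Mean interspike interval, ms.
#' @param d Noise pulse duration, ms.
#' @return Integer bin count in `[2, 50]`.
#' @export
choose_n_bins <- function(mean_isi, d) {
  if (mean_isi <= 0 || d <= 0) stop("mean_isi and d must be > 0")
  n <- min(floor(mean_isi / d), 50)
  if (n < 2) stop("mean ISI shorter than two noise pulses; cannot form phase bins")
  as.integer(n)
}

#' Interpolated phase of a time point within an interspike interval
#'
#' The time since the previous spike divided by the length of that
#' particular interval — the proportion of the interval elapsed. Unlike
#' mapping time through the average period, this keeps the phase estimate
#' from drifting off late in long or short intervals.
#'
#' @param t Time(s) in ms, within `[spike_prev, spike_next]`.
#' @param spike_prev,spike_next Bounding spike times, ms.
#' @return Phase(s) in `[0, 1]`.
#' @export
interpolated_phase <- function(t, spike_prev, spike_next) {
  if (spike_next <= spike_prev) stop("spike_next must exceed spike_prev")
  if (any(t < spike_prev | t > spike_next))
    stop("t must lie within [spike_prev, spike_next]")
  (t - spike_prev) / (spike_next - spike_prev)
}

#' Per-phase-bin charge matrix
#'
#' Divides each interspike interval into `n_bins` equal phase bins and
#' integrates the injected current over the samples falling in each bin,
#' giving the charge Q\[α, i\] (pA·ms) delivered in bin i of interval α.
#' Each current sample is assigned to the bin containing its start time.
#'
#' Two time-to-phase mappings:
#' * `"interpolated"`: phase = time since the previous spike divided by that
#'   interval's own length; every sample of every interval lands in a bin, so
#'   row sums conserve the total charge injected during the interval.
#' * `"mean_period"`: phase = time since the previous spike divided by the
#'   mean interval; samples mapping past bin `n_bins` (intervals longer than
#'   the mean period) are discarded.
#'
#' The dependent variable `y` is each interval's duration normalized by the
#' mean interval.
#'
#' @param current Injected-current [trace()] covering all intervals.
#' @param spikes A [spike_train()] with at least 2 spikes.
#' @param n_bins Number of phase bins, or `"auto"` ([choose_n_bins()]; needs `d`).
#' @param mode Binning mode.
#' @param d Noise pulse duration, ms (only for `n_bins = "auto"`).
#' @return An object of class `"charge_matrix"`: `Q` (n_intervals × n_bins),
#'   `y`, `isis`, `mean_isi`, `n_bins`, `mode`.
#' @export
bin_charges <- function(current, spikes, n_bins = "auto",
                        mode = c("interpolated", "mean_period"), d = NULL) {
  stopifnot(inherits(current, "trace"), inherits(spikes, "spike_train"))
  mode <- match.arg(mode)
  st <- spikes$times
  if (length(st) < 2L) stop("need at least 2 spikes (1 interval)")
  isi <- diff(st)
  if (any(isi < current$dt)) stop("an ISI is shorter than one current sample")
  mean_isi <- mean(isi)
  if (identical(n_bins, "auto")) {
    if (is.null(d)) stop("n_bins = \"auto\" requires the pulse duration d")
    n_bins <- choose_n_bins(mean_isi, d)
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  n_isi <- length(isi)

  tt <- trace_times(current)
  keep <- tt >= st[1] & tt < st[length(st)]
  tt <- tt[keep]
  ii <- current$samples[keep]
  alpha <- findInterval(tt, st)            # interval index of each sample
  phase <- if (mode == "interpolated") {
    (tt - st[alpha]) / isi[alpha]
  } else {
    (tt - st[alpha]) / mean_isi
  }
  bin <- floor(phase * n_bins) + 1L
  if (mode == "interpolated") {
    bin <- pmin(bin, n_bins)               # guard against rounding at phase 1
    drop <- rep(FALSE, length(bin))
  } else {
    drop <- bin > n_bins                   # charge past the mean period: discarded
  }
  Q <- matrix(0, nrow = n_isi, ncol = n_bins)
  if (any(!drop)) {
    g <- (bin[!drop] - 1L) * n_isi + alpha[!drop]   # column-major linear index
    acc <- rowsum(ii[!drop] * current$dt, group = g)
    Q[as.integer(rownames(acc))] <- acc
  }
  structure(list(Q = Q, y = isi / mean_isi, isis = isi, mean_isi = mean_isi,
                 n_bins = n_bins, mode = mode),
            class = "charge_matrix")
}

#' @export
print.charge_matrix <- function(x, ...) {
  cat(sprintf("<charge_matrix: %d intervals x %d phase bins, %s binning>\n",
              nrow(x$Q), x$n_bins, x$mode))
  invisible(x)
}

#' Fit the PRC by multiple linear regression on binned charge
#'
#' Ordinary least squares of the normalized interval durations `y` on the
#' columns of the charge matrix, with a freely estimated intercept
#' (expected near 1). Because excess phase advance shortens the interval,
#' the PRC values are the negated regression coefficients:
#' Z(φᵢ) = −bᵢ, in cycles per pA·ms. Standard errors are the classical OLS
#' standard errors of the coefficients (residual variance × diagonal of the
#' inverse normal matrix, square-rooted), and R² is the multiple-regression
#' coefficient of determination — the proportion of ISI variance accounted
#' for by the injected noise.
#'
#' @param cm A [bin_charges()] result.
#' @return An object of class `"prc_fit"`. Use [coef()], [summary()],
#'   [plot()], [residuals()], [fitted()], [predict()][predict.prc_fit] and
#'   [simulate()][simulate.prc_fit] on it; the tabulated curve itself is in
#'   `$prc`.
#' @seealso [estimate_prc()] for the one-call interface from a current trace
#'   and spike train.
#' @export
fit_prc <- function(cm) {
  stopifnot(inherits(cm, "charge_matrix"))
  Q <- cm$Q
  n <- nrow(Q); p <- ncol(Q)
  if (n < p + 2L)
    stop(sprintf("too few intervals: %d rows for %d bins (+ intercept); need >= %d",
                 n, p, p + 2L))
  colnames(Q) <- sprintf("bin%02d", seq_len(p))
  fit <- stats::lm(cm$y ~ Q)
  if (fit$rank < p + 1L) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("charge matrix is rank deficient; offending columns: ",
         paste(sub("^Q", "", bad), collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  z <- -ct[-1, "Estimate"]
  se <- ct[-1, "Std. Error"]
  centers <- (seq_len(p) - 0.5) / p
  structure(list(
    prc = tabulated_prc(centers, z, se = unname(se), r_squared = sm$r.squared),
    coefficients = stats::setNames(z, sprintf("phase_%.4f", centers)),
    se = unname(se),
    intercept = unname(ct[1, "Estimate"]),
    intercept_se = unname(ct[1, "Std. Error"]),
    r_squared = sm$r.squared,
    sigma_resid = sm$sigma,
    n_intervals = n, n_bins = p, mode = cm$mode,
    mean_isi = cm$mean_isi,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit))),
    class = "prc_fit")
}

#' Estimate a PRC from a noise-perturbed spike train
#'
#' The one-call modelling interface: builds the per-phase-bin charge matrix
#' ([bin_charges()]) and fits the multiple regression ([fit_prc()]). As a
#' guard against underdetermined fits it requires at least `n_bins + 10`
#' interspike intervals.
#'
#' @inheritParams bin_charges
#' @return A `"prc_fit"` (see [fit_prc()]).
#' @examples
#' z <- make_type1_prc(sensitivity_target = 4e-7)
#' nz <- generate_pulsed_noise(60, d = 1, duration = 60000, dt = 1, seed = 2)
#' sim <- simulate_trajectory(z, omega = 0.01, current = nz, record_phase = FALSE)
#' fit <- estimate_prc(nz, sim$spikes, n_bins = "auto", d = 1)
#' fit
#' @export
estimate_prc <- function(current, spikes, n_bins = "auto",
                         mode = c("interpolated", "mean_period"), d = NULL) {
  cm <- bin_charges(current, spikes, n_bins = n_bins, mode = mode, d = d)
  if (nrow(cm$Q) < cm$n_bins + 10L)
    stop(sprintf("need >= n_bins + 10 = %d intervals, have %d",
                 cm$n_bins + 10L, nrow(cm$Q)))
  fit_prc(cm)
}

#' @export
print.prc_fit <- function(x, ...) {
  cat("PRC estimate by charge-matrix regression\n")
  cat(sprintf("  binning     : %s phase, %d bins\n", x$mode, x$n_bins))
  cat(sprintf("  intervals   : %d (mean ISI %.4g ms)\n", x$n_intervals, x$mean_isi))
  cat(sprintf("  R^2         : %.4f   intercept: %.4f (SE %.2g)\n",
              x$r_squared, x$intercept, x$intercept_se))
  cat(sprintf("  sensitivity : %.4g cycles^2/(pA^2 ms^2)\n", sensitivity(x$prc)))
  cat(sprintf("  peak Z      : %.4g cycles/(pA ms) at phase %.3f\n",
              max(x$coefficients), x$prc$bin_centers[which.max(x$coefficients)]))
  invisible(x)
}

#' @export
summary.prc_fit <- function(object, ...) {
  tab <- data.frame(phase = object$prc$bin_centers,
                    Z = unname(object$coefficients),
                    se = object$se,
                    t = unname(object$coefficients) / object$se)
  structure(list(table = tab, fit = object,
                 sensitivity = sensitivity(object$prc),
                 centroid = if (sum(object$coefficients) != 0)
                   centroid(object$prc) else NA_real_),
            class = "summary.prc_fit")
}

#' @export
print.summary.prc_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  centroid    : %.4f\n\n", x$centroid))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.prc_fit <- function(object, ...) object$coefficients

#' @export
residuals.prc_fit <- function(object, ...) object$residuals

#' @export
fitted.prc_fit <- function(object, ...) object$fitted

#' @export
plot.prc_fit <- function(x, ...) {
  plot(x$prc, ...)
  graphics::title(sub = sprintf("%s binning, %d intervals, R^2 = %.3f",
                                x$mode, x$n_intervals, x$r_squared))
  invisible(x)
}

#' Predict spike times from a fitted PRC
#'
#' Applies [predict_spike_times()] with the estimated curve: for each actual
#' spike the phase model is restarted at 0 and integrated under the recorded
#' current, and the crossing of φ = 1 is the predicted next spike.
#'
#' @param object A `"prc_fit"`.
#' @param current Injected-current [trace()] of the episode to predict.
#' @param spikes Actual [spike_train()] of that episode.
#' @param omega Drift rate, spikes/ms; defaults to the reciprocal of the
#'   episode's mean ISI.
#' @param dt Integration step, ms.
#' @param ... Passed to [predict_spike_times()].
#' @return A `"prediction_report"` (see [predict_spike_times()]).
#' @export
predict.prc_fit <- function(object, current, spikes, omega = NULL,
                            dt = 0.05, ...) {
  predict_spike_times(object$prc, current = current, actual = spikes,
                      omega = omega, dt = dt, ...)
}

#' Simulate spike trains from a fitted PRC
#'
#' Draws fresh pulsed-noise episodes and runs the phase model in restart
#' mode with the estimated curve.
#'
#' @param object A `"prc_fit"`.
#' @param nsim Number of episodes.
#' @param seed RNG seed.
#' @param omega Drift rate, spikes/ms; defaults to 1/mean ISI of the fit data.
#' @param sigma Noise SD, pA.
#' @param d Pulse duration, ms.
#' @param duration Episode duration, ms.
#' @param dt Integration step, ms.
#' @param ... Unused.
#' @return A list of `nsim` lists, each with `current` and `spikes`.
#' @export
simulate.prc_fit <- function(object, nsim = 1, seed = 1, omega = NULL,
                             sigma = 60, d = 1, duration = 60000, dt = d, ...) {
  if (is.null(omega)) omega <- 1 / object$mean_isi
  lapply(seq_len(nsim), function(e) {
    nz <- generate_pulsed_noise(sigma, d, duration, dt = dt,
                                seed = seed + e - 1L)
    sim <- simulate_trajectory(object$prc, omega, nz, dt = dt,
                               mode = "restart", record_phase = FALSE)
    list(current = nz, spikes = sim$spikes)
  })
}

#' JSON fit report for a PRC estimate
#'
#' @param x A `"prc_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(x, path) {
  stopifnot(inherits(x, "prc_fit"))
  jsonlite::write_json(list(r_squared = x$r_squared,
                            n_intervals = x$n_intervals,
                            n_bins = x$n_bins,
                            mode = x$mode,
                            intercept = x$intercept,
                            mean_isi_ms = x$mean_isi,
                            sensitivity = sensitivity(x$prc),
                            centroid = tryCatch(centroid(x$prc),
                                                error = function(e) NA)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
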