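#' Generate pulsed Gaussian current noise
#'
#' Contiguous current pulses of fixed duration `d`, the amplitude of each an
#' independent draw from a zero-mean Gaussian with standard deviation
#' `sigma`. All samples within a pulse are equal.
#'
#' @param sigma Pulse-amplitude SD in pA (>= 0).
#' @param d Pulse duration in ms; must be an integer multiple of `dt`.
#' @param duration Total duration in ms; a multiple of `d`.
#' @param dt Sample interval in ms.
#' @param seed Optional RNG seed for reproducible noise.
#' @param t0 Start time in ms.
#' @return A current [trace()].
#' @examples
#' nz <- generate_pulsed_noise(sigma = 60, d = 0.5, duration = 100, dt = 0.25, seed = 1)
#' @export
generate_pulsed_noise <- function(sigma, d, duration, dt = d, seed = NULL, t0 = 0) {
  if (sigma < 0) stop("sigma must be >= 0")
  k <- d / dt
  if (abs(k - round(k)) > 1e-9) stop("pulse duration d must be a multiple of dt")
  k <- as.integer(round(k))
  n_pulses <- duration / d
  if (abs(n_pulses - round(n_pulses)) > 1e-9)
    stop("duration must be a multiple of the pulse duration")
  n_pulses <- as.integer(round(n_pulses))
  if (!is.null(seed)) set.seed(seed)
  amps <- stats::rnorm(n_pulses, mean = 0, sd = sigma)
  trace(rep(amps, each = k), dt = dt, t0 = t0, kind = "current")
}

#' Simulate one phase-model trajectory
#'
#' First-order (Euler) integration of dφ/dt = ω + Z(φ)·I(t), with the
#' injected current held constant within each of its samples:
#' φ ← φ + Δt·(ω + Z(φ)·I). A spike is recorded when φ crosses 1.
#'
#' Two crossing conventions:
#' * `mode = "restart"`: φ resets to 0 at each crossing, producing a spike
#'   train under continuing input;
#' * `mode = "drift"`: only the first crossing is recorded; the input is then
#'   disconnected and φ advances at ω alone, so phases above 1 map onto time
#'   since the spike (the Monte Carlo ensemble convention).
#'
#' Negative phase excursions (possible under large negative pulses where Z is
#' large) are clamped at 0 and counted in `n_clamped`.
#'
#' @param prc A [tabulated_prc()].
#' @param omega Intrinsic drift rate in spikes/ms (the unperturbed firing
#'   rate; 10 spikes/s = 0.01 spikes/ms).
#' @param current Injected-current [trace()] (pA).
#' @param dt Integration step in ms; defaults to the current's sample
#'   interval, and the current interval must be a multiple of `dt`.
#' @param mode Crossing convention (see above).
#' @param refine If `TRUE`, the crossing time is linearly interpolated within
#'   the final integration step; otherwise it is the first grid time at which
#'   φ >= 1.
#' @param t_end End of integration (ms from `current$t0`); defaults to the
#'   current duration.
#' @param record_phase Keep the full phase trajectory.
#' @return A list of class `"phase_trajectory"`: `spikes` (a [spike_train()]),
#'   `phases`, `times`, and `n_clamped`.
#' @examples
#' z <- make_type1_prc(sensitivity_target = 4e-7)
#' nz <- generate_pulsed_noise(60, d = 1, duration = 5000, dt = 1, seed = 1)
#' tr <- simulate_trajectory(z, omega = 0.01, current = nz)
#' isis(tr$spikes)
#' @export
simulate_trajectory <- function(prc, omega, current, dt = current$dt,
                                mode = c("restart", "drift"), refine = FALSE,
                                t_end = NULL, record_phase = TRUE) {
  stopifnot(inherits(prc, "prc"), inherits(current, "trace"))
  mode <- match.arg(mode)
  if (omega <= 0) stop("omega must be > 0 (spikes/ms)")
  r <- current$dt / dt
  if (abs(r - round(r)) > 1e-9)
    stop("the current's sample interval must be a multiple of the integration step")
  if (is.null(t_end)) t_end <- current$t0 + trace_duration(current)
  k <- .prc_knots(prc)
  res <- cpp_phase_integrate(k$x, k$y, omega, dt, current$t0, t_end,
                             current$samples, current$t0, current$dt,
                             mode == "restart", refine, record_phase, 0)
  n_steps <- floor((t_end - current$t0) / dt + 1e-9)
  structure(list(
    spikes = spike_train(res$spikes, span = c(current$t0, t_end)),
    phases = res$phases,
    times = if (record_phase) current$t0 + (0:n_steps) * dt else NULL,
    n_clamped = res$n_clamped,
    omega = omega, dt = dt, mode = mode),
    class = "phase_trajectory")
}

#' Simulate a Monte Carlo ensemble of phase trajectories
#'
#' Runs `n_traj` independent trajectories of the phase model from φ = 0 under
#' independent pulsed Gaussian noise, in the drift-after-crossing convention:
#' each trajectory's first crossing of φ = 1 is its spike time, after which
#' its input is disconnected and phase drifts at ω. The distribution of
#' crossing times is the interspike-interval distribution; vertical slices
#' through the trajectories give latent-phase distributions at any time.
#'
#' Per-trajectory noise is seeded as `seed + trajectory index − 1`, so the
#' ensemble is bit-reproducible and independent of execution order.
#'
#' @param prc A [tabulated_prc()].
#' @param omega Drift rate, spikes/ms.
#' @param sigma Noise pulse-amplitude SD, pA.
#' @param d Noise pulse duration, ms (a multiple of `dt`).
#' @param n_traj Number of trajectories (>= 2).
#' @param dt Integration step, ms.
#' @param t_max Simulated horizon, ms; defaults to 3 mean periods.
#' @param seed Base RNG seed.
#' @param refine Linear sub-step interpolation of the crossing time.
#' @param keep_phases Store the full (n_steps+1) × n_traj phase matrix
#'   (needed by [phase_distribution_at()]).
#' @return An object of class `"phase_ensemble"` with `crossing_times`,
#'   `times`, optional `phases` matrix, and the simulation parameters.
#' @examples
#' z <- make_type1_prc(sensitivity_target = 4e-7)
#' ens <- simulate_ensemble(z, omega = 0.001, sigma = 10, d = 1,
#'                          n_traj = 200, dt = 1, seed = 1)
#' stats::sd(ens$crossing_times) / mean(ens$crossing_times)  # ISI CV
#' @export
simulate_ensemble <- function(prc, omega, sigma, d, n_traj = 5000, dt = 1,
                              t_max = 3 / omega, seed = 1, refine = FALSE,
                              keep_phases = TRUE) {
  stopifnot(inherits(prc, "prc"))
  if (n_traj < 2) stop("n_traj must be >= 2")
  if (omega <= 0) stop("omega must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  kk <- d / dt
  if (abs(kk - round(kk)) > 1e-9) stop("d must be a multiple of dt")
  n_steps <- as.integer(floor(t_max / dt + 1e-9))
  n_pulses <- as.integer(ceiling(n_steps * dt / d - 1e-9))
  # per-trajectory seeded amplitudes; rows = trajectories for fast column slices
  amps <- matrix(0, nrow = n_traj, ncol = max(n_pulses, 1L))
  for (i in seq_len(n_traj)) {
    set.seed(seed + i - 1L)
    amps[i, ] <- stats::rnorm(n_pulses, 0, sigma)
  }
  k <- .prc_knots(prc)
  phi <- numeric(n_traj)
  crossed <- logical(n_traj)
  crossing <- rep(NA_real_, n_traj)
  n_clamped <- 0L
  phases <- if (keep_phases) matrix(0, nrow = n_steps + 1L, ncol = n_traj) else NULL
  pulse_of_step <- pmin(as.integer(floor((seq_len(n_steps) - 1L) * dt / d + 1e-9)) + 1L,
                        n_pulses)
  for (s in seq_len(n_steps)) {
    z <- stats::approx(k$x, k$y, xout = pmin(phi, 1), rule = 2)$y
    z[crossed | phi >= 1] <- 0
    phi_old <- phi
    phi <- phi + dt * (omega + z * amps[, pulse_of_step[s]] * !crossed)
    neg <- phi < 0
    if (any(neg)) { n_clamped <- n_clamped + sum(neg); phi[neg] <- 0 }
    newly <- !crossed & phi >= 1
    if (any(newly)) {
      crossing[newly] <- if (refine)
        (s - 1) * dt + dt * (1 - phi_old[newly]) / (phi[newly] - phi_old[newly])
      else s * dt
      crossed[newly] <- TRUE
    }
    if (keep_phases) phases[s + 1L, ] <- phi
  }
  if (anyNA(crossing))
    warning(sum(is.na(crossing)), " trajectories did not cross phase 1 within t_max")
  structure(list(crossing_times = crossing,
                 phases = phases,
                 times = (0:n_steps) * dt,
                 omega = omega, sigma = sigma, d = d, dt = dt,
                 n_traj = n_traj, seed = seed, n_clamped = n_clamped),
            class = "phase_ensemble")
}

#' @export
print.phase_ensemble <- function(x, ...) {
  ct <- x$crossing_times
  cat(sprintf("<phase_ensemble: %d trajectories, omega = %g spikes/ms, sigma = %g pA, d = %g ms>\n",
              x$n_traj, x$omega, x$sigma, x$d))
  cat(sprintf("  crossing times: mean %.4g ms, CV %.4g\n",
              mean(ct, na.rm = TRUE),
              stats::sd(ct, na.rm = TRUE) / mean(ct, na.rm = TRUE)))
  invisible(x)
}

#' Latent-phase distribution at a time slice
#'
#' Moments and histogram of the ensemble's phases at the sample nearest `t`
#' — a vertical slice through the trajectories.
#'
#' @param ensemble A [simulate_ensemble()] result with `keep_phases = TRUE`.
#' @param t Time in ms, within the simulated horizon.
#' @param breaks Passed to [graphics::hist()] (computation only).
#' @return A list with `t` (the snapped time), `mean`, `var`, `phases`, and
#'   `histogram`.
#' @export
phase_distribution_at <- function(ensemble, t, breaks = 30) {
  stopifnot(inherits(ensemble, "phase_ensemble"))
  if (is.null(ensemble$phases))
    stop("ensemble was simulated with keep_phases = FALSE")
  if (t < 0 || t > max(ensemble$times))
    stop("t is beyond the simulated horizon")
  k <- which.min(abs(ensemble$times - t))
  ph <- ensemble$phases[k, ]
  list(t = ensemble$times[k],
       mean = mean(ph),
       var = stats::var(ph),
       phases = ph,
       histogram = graphics::hist(ph, breaks = breaks, plot = FALSE))
}
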