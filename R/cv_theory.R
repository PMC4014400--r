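#' Closed-form prediction of interspike-interval CV under pulsed noise
#'
#' For a phase oscillator at rate ω perturbed by contiguous zero-mean
#' Gaussian current pulses of duration d and amplitude SD σ, each pulse
#' contributes an effective variance d²σ², and an average interval contains
#' 1/(dω) pulses, so charge variance accumulates at rate d·σ²/ω per interval.
#' Scaled by the sensitivity S = ∫₀¹Z² and converted from phase variance to
#' interval variance by 1/ω², the coefficient of variation of interspike
#' intervals is
#'
#'   CV = σ · sqrt(d · S / ω).
#'
#' CV is exactly linear in σ, grows as √d, and falls as 1/√ω. The
#' approximation assumes the phase distribution stays narrow; it degrades
#' once the predicted CV is large (roughly above 0.4 for typical type-1
#' curves).
#'
#' @param sigma Pulse-amplitude SD, pA.
#' @param d Pulse duration, ms.
#' @param omega Firing rate, spikes/ms.
#' @param sensitivity ∫Z², cycles²/(pA²·ms²); see [sensitivity()].
#' @return Predicted CV (dimensionless).
#' @examples
#' predicted_cv(sigma = 60, d = 1, omega = 0.01, sensitivity = 4e-7)
#' @export
predicted_cv <- function(sigma, d, omega, sensitivity) {
  if (any(omega <= 0)) stop("omega must be > 0")
  if (any(sigma < 0) || any(d < 0) || any(sensitivity < 0))
    stop("sigma, d and sensitivity must be >= 0")
  sigma * sqrt(d * sensitivity / omega)
}

#' Predicted evolution of latent-phase variance within the mean interval
#'
#' The variance of the latent-phase distribution at time t after a spike is
#' the accumulated noise variance weighted by the squared PRC along the mean
#' phase trajectory ωt:
#'
#'   Var(t) = (d·σ²/ω) · ∫₀^{ωt} Z(u)² du,
#'
#' the running-integral form of the small-noise variance approximation. At
#' t = 1/ω this equals d·σ²·S/ω, consistent with [predicted_cv()] squared.
#'
#' @param prc A [tabulated_prc()].
#' @param omega Firing rate, spikes/ms.
#' @param sigma Pulse-amplitude SD, pA.
#' @param d Pulse duration, ms.
#' @param t Time(s) since the spike, ms (in `[0, 1/omega]`).
#' @return Phase variance (cycles²) at each `t`.
#' @export
phase_variance_evolution <- function(prc, omega, sigma, d, t) {
  stopifnot(inherits(prc, "prc"))
  if (any(t < 0)) stop("t must be >= 0")
  if (omega <= 0) stop("omega must be > 0")
  (d * sigma^2 / omega) * .cum_sq_integral(prc, pmin(omega * t, 1))
}

# Running integral of the squared pinned-endpoint piecewise-linear PRC,
# exact per segment (the square of a linear segment is quadratic).
.cum_sq_integral <- function(prc, u) {
  k <- .prc_knots(prc)
  x1 <- k$x[-length(k$x)]; x2 <- k$x[-1]
  v1 <- k$y[-length(k$y)]; v2 <- k$y[-1]
  w <- x2 - x1
  seg <- w * (v1^2 + v1 * v2 + v2^2) / 3
  cum <- c(0, cumsum(seg))
  vapply(u, function(ui) {
    j <- findInterval(ui, k$x, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(w))
    if (ui <= k$x[1]) return(0)
    f <- (ui - x1[j]) / w[j]               # fraction of segment j covered
    vm <- v1[j] + f * (v2[j] - v1[j])      # Z at ui
    cum[j] + f * w[j] * (v1[j]^2 + v1[j] * vm + vm^2) / 3
  }, numeric(1))
}

#' Predicted CV over a grid of noise amplitudes
#'
#' Evaluates [predicted_cv()] pointwise using the sensitivity of `prc`,
#' optionally adding a Monte Carlo column from [simulate_ensemble()].
#'
#' @param prc A [tabulated_prc()].
#' @param omega Firing rate, spikes/ms.
#' @param d Pulse duration, ms.
#' @param sigma_grid Noise SDs, pA (nonempty).
#' @param monte_carlo Also simulate an ensemble per grid point.
#' @param n_traj,dt,seed Ensemble parameters when `monte_carlo = TRUE`.
#' @return A data frame with columns `sigma`, `cv` and (optionally) `cv_mc`.
#' @export
cv_curve <- function(prc, omega, d, sigma_grid, monte_carlo = FALSE,
                     n_traj = 5000, dt = min(d, 1), seed = 1) {
  stopifnot(inherits(prc, "prc"))
  if (!length(sigma_grid)) stop("sigma_grid must be nonempty")
  S <- sensitivity(prc)
  out <- data.frame(sigma = sigma_grid,
                    cv = predicted_cv(sigma_grid, d, omega, S))
  if (monte_carlo) {
    out$cv_mc <- vapply(seq_along(sigma_grid), function(i) {
      ens <- simulate_ensemble(prc, omega, sigma_grid[i], d,
                               n_traj = n_traj, dt = dt,
                               seed = seed + 1000L * (i - 1L),
                               keep_phases = FALSE)
      ct <- ens$crossing_times
      stats::sd(ct, na.rm = TRUE) / mean(ct, na.rm = TRUE)
    }, numeric(1))
  }
  out
}
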