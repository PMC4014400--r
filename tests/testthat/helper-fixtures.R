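# shared fixtures: all generated in code, nothing read from disk

# standard raised-cosine type-1 curve at the mid-range sensitivity scale
fix_prc <- function(S = 4e-7) make_type1_prc(sensitivity_target = S)

# a noise-driven restart-mode spike train plus its injected current
fix_noisy_train <- function(prc, omega, sigma, d, duration, dt = d, seed = 1,
                            intrinsic_sigma = 0) {
  inj <- generate_pulsed_noise(sigma, d, duration, dt = dt, seed = seed)
  drive <- if (intrinsic_sigma > 0) {
    hidden <- generate_pulsed_noise(intrinsic_sigma, d, duration, dt = dt,
                                    seed = seed + 4096L)
    trace(inj$samples + hidden$samples, dt = dt, kind = "current")
  } else inj
  sim <- simulate_trajectory(prc, omega, drive, dt = dt, mode = "restart",
                             record_phase = FALSE)
  list(current = inj, spikes = sim$spikes)
}

# ensemble ISI CV from crossing times
ens_cv <- function(ens) {
  ct <- ens$crossing_times
  stats::sd(ct, na.rm = TRUE) / mean(ct, na.rm = TRUE)
}
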