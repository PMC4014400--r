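test_that("spike-time prediction matches closed forms and is self-consistent", {
  z <- fix_prc()
  st <- spike_train(seq(0, 1000, by = 100), span = c(0, 1000))
  quiet <- trace(rep(0, 1100), dt = 1, kind = "current")
  rep0 <- predict_spike_times(z, quiet, st, omega = 0.01, dt = 0.05)
  expect_true(all(abs(rep0$predicted_isis - 100) < 1e-6))

  # constant current with a constant-Z curve: ISI = 1/(omega + Z I)
  c0 <- 1.5e-4
  zc <- tabulated_prc(c(1e-6, 0.5, 1 - 1e-6), rep(c0, 3))
  const <- trace(rep(30, 1100), dt = 1, kind = "current")
  repc <- predict_spike_times(zc, const, st, omega = 0.01, dt = 0.05)
  expect_true(all(abs(repc$predicted_isis - 1 / (0.01 + c0 * 30)) < 0.06))

  # data generated by the same phase model, no intrinsic noise: near-perfect
  nz <- generate_pulsed_noise(60, 1, 60000, dt = 1, seed = 81)
  sim <- simulate_trajectory(z, 0.01, nz, dt = 1, record_phase = FALSE)
  repp <- predict_spike_times(z, nz, sim$spikes, omega = 0.01, dt = 1,
                              refine = FALSE)
  expect_equal(repp$predicted_isis, repp$actual_isis)
  expect_gt(repp$variance_explained, 0.999)
  expect_identical(repp$n_unpredicted, 0L)
})

test_that("variance explained is SS-based, with the analytic noise expectation", {
  a <- c(80, 100, 120, 95, 105)
  expect_equal(variance_explained(a, a), 1)
  expect_equal(variance_explained(rep(mean(a), 5), a), 0)
  expect_error(variance_explained(a[1:2], a[1:2]), "3")
  # actual = predicted + noise(var v): E[R^2] = 1 - v / Var(actual)
  set.seed(91)
  v <- 16
  vals <- replicate(200, {
    p <- rnorm(100, 100, 10)
    act <- p + rnorm(100, 0, sqrt(v))
    variance_explained(p, act)
  })
  expect_equal(mean(vals), 1 - v / (100 + v), tolerance = 0.02)
})

test_that("ISI CV matches hand arithmetic and Poisson theory", {
  periodic <- spike_train(seq(0, 500, by = 50))
  expect_equal(isi_cv(periodic), 0)
  expect_equal(isi_cv(c(1, 3, 1, 3)), sd(c(1, 3, 1, 3)) / 2)
  expect_equal(isi_cv(c(1, 3, 1, 3, 1, 3)), 0.5477226, tolerance = 1e-6)
  set.seed(8)
  expect_lt(abs(isi_cv(rexp(1e4, 0.01)) - 1), 0.03)
  expect_error(isi_cv(spike_train(c(0, 10))), "3")
})

test_that("the autocorrelogram is periodic for clock trains and flat for Poisson", {
  empty <- autocorrelogram(spike_train(numeric(0)), binwidth = 2, max_lag = 100)
  expect_true(all(empty$counts == 0))
  one <- autocorrelogram(spike_train(5), binwidth = 2, max_lag = 100)
  expect_true(all(one$counts == 0))

  per <- spike_train(seq(0, 2000, by = 50))
  acg <- autocorrelogram(per, binwidth = 5, max_lag = 200)
  mids <- acg$breaks[-1] - 2.5
  peaks <- which(acg$counts > 0)
  # lags at k*50 fall in the left-closed bins [50,55), ...; the lag equal to
  # max_lag lands in the final bin
  expect_setequal(mids[peaks], c(52.5, 102.5, 152.5, 197.5))

  set.seed(17)
  pois <- spike_train(cumsum(rexp(4000, rate = 0.02)))
  acgp <- autocorrelogram(pois, binwidth = 10, max_lag = 300)
  expect_gt(chisq.test(acgp$counts)$p.value, 0.01)
})

test_that("mean rate converts spike counts to spikes per second", {
  expect_equal(mean_rate(spike_train(c(0, 100, 200))), 10)
  expect_error(mean_rate(spike_train(5)), "2 spikes")
  z <- fix_prc()
  quiet <- trace(rep(0, 5000), dt = 1, kind = "current")
  s <- simulate_trajectory(z, 0.01, quiet, refine = TRUE, record_phase = FALSE)
  expect_equal(mean_rate(s$spikes), 10, tolerance = 1e-3)
})

test_that("the estimated PRC predicts held-out firing better than a generic shape", {
  # ground truth skewed late; generic = raised cosine rescaled to matched
  # sensitivity, so the comparison isolates PRC *shape*
  zskew <- make_type1_prc("beta", sensitivity_target = 4e-7, p = 3, q = 1.5)
  ve_est <- ve_gen <- numeric(10)
  for (r in 1:10) {
    ex <- synth_experiment(prc = zskew, n_episodes = 2, episode_s = 30,
                           seed = 300 + r)
    fit <- estimate_prc(ex$episodes[[1]]$current, ex$episodes[[1]]$spikes, d = ex$d)
    generic <- make_type1_prc(sensitivity_target = sensitivity(fit$prc))
    ep2 <- ex$episodes[[2]]
    ve_est[r] <- predict(fit, ep2$current, ep2$spikes)$variance_explained
    ve_gen[r] <- predict_spike_times(generic, ep2$current,
                                     ep2$spikes)$variance_explained
  }
  expect_gt(mean(ve_est), mean(ve_gen))
})

test_that("simulated CV sits near its closed-form prediction at fixture scale", {
  z <- fix_prc()
  ep <- fix_noisy_train(z, 0.01, sigma = 60, d = 0.5, duration = 60000, seed = 111)
  cv_mc <- isi_cv(ep$spikes)
  cv_th <- predicted_cv(60, 0.5, 0.01, sensitivity(z))
  expect_lt(abs(cv_mc - cv_th) / cv_th, 0.15)
  # and noise-free fixture trains are nearly clock-like
  quietsim <- fix_noisy_train(z, 0.01, sigma = 0, d = 0.5, duration = 20000, seed = 1)
  expect_lt(isi_cv(quietsim$spikes), 0.01)
})
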