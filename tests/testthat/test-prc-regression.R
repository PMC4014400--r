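test_that("bin-count rule divides the mean ISI by the pulse size, capped at 50", {
  expect_identical(choose_n_bins(100, 1), 50L)
  expect_identical(choose_n_bins(40, 1), 40L)
  expect_identical(choose_n_bins(40, 2), 20L)
  expect_error(choose_n_bins(3, 2), "two")
})

test_that("interpolated phase is the elapsed fraction of the interval", {
  expect_equal(interpolated_phase(10, 10, 110), 0)
  expect_equal(interpolated_phase(110, 10, 110), 1)
  expect_equal(interpolated_phase(60, 10, 110), 0.5)
  expect_error(interpolated_phase(5, 10, 110), "within")
})

test_that("charge binning conserves charge and places pulses in the right bins", {
  # zero current: all-zero matrix, y from the ISIs alone
  st <- spike_train(c(0, 90, 200, 310), span = c(0, 320))
  quiet <- trace(rep(0, 320), dt = 1, kind = "current")
  cm <- bin_charges(quiet, st, n_bins = 10)
  expect_true(all(cm$Q == 0))
  expect_equal(cm$y, diff(st$times) / mean(diff(st$times)))

  # constant current over an ISI: every bin gets I*T/n in interpolated mode
  stc <- spike_train(c(0, 100, 200), span = c(0, 200))
  const <- trace(rep(5, 200), dt = 1, kind = "current")
  cmc <- bin_charges(const, stc, n_bins = 10, mode = "interpolated")
  expect_true(all(abs(cmc$Q - 5 * 100 / 10) < 1e-12))

  # a single pulse fully inside bin 3 of interval 2 (oracle: direct sum)
  ii <- rep(0, 300)
  ii[126:130] <- 8            # t in [125, 130): phase in [0.25, 0.30) of ISI 2
  one <- trace(ii, dt = 1, kind = "current")
  st2 <- spike_train(c(0, 100, 200, 300), span = c(0, 300))
  cm2 <- bin_charges(one, st2, n_bins = 10)
  expect_equal(cm2$Q[2, 3], 8 * 5)
  expect_equal(sum(cm2$Q), 8 * 5)

  # row sums conserve total injected charge per interval (interpolated mode)
  nz <- generate_pulsed_noise(40, 1, 3000, dt = 1, seed = 11)
  z <- fix_prc()
  sim <- simulate_trajectory(z, 0.01, nz, record_phase = FALSE)
  cm3 <- bin_charges(nz, sim$spikes, n_bins = 25)
  st3 <- sim$spikes$times
  tt <- trace_times(nz)
  direct <- vapply(seq_len(length(st3) - 1), function(a) {
    sum(nz$samples[tt >= st3[a] & tt < st3[a + 1]]) * nz$dt
  }, numeric(1))
  expect_equal(rowSums(cm3$Q), direct)
})

test_that("fit_prc solves a noiseless linear system exactly, with R^2 = 1", {
  set.seed(21)
  n_bins <- 8; n <- 60
  Q <- matrix(rnorm(n * n_bins, 0, 30), n, n_bins)
  z_true <- seq(1, 8) * 1e-4
  y <- as.numeric(1 - Q %*% z_true)
  cm <- structure(list(Q = Q, y = y, isis = y * 100, mean_isi = 100,
                       n_bins = n_bins, mode = "interpolated"),
                  class = "charge_matrix")
  fit <- suppressWarnings(fit_prc(cm))   # lm warns on an essentially perfect fit
  expect_equal(unname(coef(fit)), z_true, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$prc$bin_centers, (1:8 - 0.5) / 8)
})

test_that("coefficients are null-calibrated when the ISIs ignore the charge", {
  # y independent of Q: |Z| < 3 SE for >= 95% of bins over repeated draws
  set.seed(31)
  fracs <- replicate(20, {
    n_bins <- 10; n <- 120
    Q <- matrix(rnorm(n * n_bins, 0, 30), n, n_bins)
    y <- rnorm(n, 1, 0.05)
    cm <- structure(list(Q = Q, y = y, isis = y * 100, mean_isi = 100,
                         n_bins = n_bins, mode = "interpolated"),
                    class = "charge_matrix")
    fit <- fit_prc(cm)
    mean(abs(coef(fit)) < 3 * fit$se)
  })
  expect_gte(mean(fracs), 0.95)
})

test_that("the fit is invariant to permuting the interval order", {
  z <- fix_prc()
  ep <- fix_noisy_train(z, 0.01, sigma = 40, d = 1, duration = 30000, seed = 41)
  cm <- bin_charges(ep$current, ep$spikes, n_bins = 20)
  fit1 <- fit_prc(cm)
  set.seed(1)
  perm <- sample(nrow(cm$Q))
  cmp <- cm
  cmp$Q <- cm$Q[perm, , drop = FALSE]
  cmp$y <- cm$y[perm]
  cmp$isis <- cm$isis[perm]
  fit2 <- fit_prc(cmp)
  expect_equal(coef(fit2), coef(fit1))
  expect_equal(fit2$se, fit1$se)
  expect_equal(fit2$r_squared, fit1$r_squared)
})

test_that("estimated curves recover the generating PRC in the small-noise regime", {
  # low-sensitivity cell at 20 spikes/s: sigma = 60 pA is a small perturbation
  z <- fix_prc(S = 1e-7)
  ep <- fix_noisy_train(z, 0.02, sigma = 60, d = 1, duration = 60000, seed = 101)
  fit <- estimate_prc(ep$current, ep$spikes, d = 1)
  truth <- prc_interpolate(z, fit$prc$bin_centers)
  expect_gt(fit$r_squared, 0.95)
  expect_equal(sensitivity(fit$prc), 1e-7, tolerance = 0.12)
  expect_gt(mean(abs(coef(fit) - truth) <= 2 * fit$se), 0.7)
  # sign convention: a type-1 curve comes out positive where it is large
  expect_true(all(coef(fit)[truth > max(truth) / 2] > 0))
})

test_that("interpolated-phase binning beats mean-period binning, most at late phases", {
  z <- fix_prc()
  ep <- fix_noisy_train(z, 0.001, sigma = 15, d = 1, duration = 400000, seed = 51)
  fi <- estimate_prc(ep$current, ep$spikes, d = 1, mode = "interpolated")
  fm <- estimate_prc(ep$current, ep$spikes, d = 1, mode = "mean_period")
  expect_lt(mean(fi$se), mean(fm$se))
  # the mean-period penalty concentrates in the late-phase bins
  late <- fi$prc$bin_centers > 0.75
  early <- fi$prc$bin_centers < 0.25
  expect_gt(mean(fm$se[late]) / mean(fi$se[late]),
            mean(fm$se[early]) / mean(fi$se[early]))
})

test_that("recovered sensitivity is stable across 40-100 pA in the valid regime", {
  z <- fix_prc(S = 1e-7)
  sens <- vapply(c(40, 70, 100), function(sg) {
    ep <- fix_noisy_train(z, 0.02, sigma = sg, d = 0.5, duration = 60000,
                          seed = 61, intrinsic_sigma = 30)
    sensitivity(estimate_prc(ep$current, ep$spikes, d = 0.5)$prc)
  }, numeric(1))
  expect_lt((max(sens) - min(sens)) / mean(sens), 0.2)
})

test_that("regression R^2 rises with noise amplitude then saturates against intrinsic noise", {
  z <- fix_prc()
  r2 <- vapply(c(10, 60, 100), function(sg) {
    ep <- fix_noisy_train(z, 0.012, sigma = sg, d = 0.5, duration = 45000,
                          seed = 71, intrinsic_sigma = 30)
    estimate_prc(ep$current, ep$spikes, d = 0.5)$r_squared
  }, numeric(1))
  expect_gt(r2[2] - r2[1], 0.1)            # steep rise out of the intrinsic floor
  expect_lt(abs(r2[3] - r2[2]), 0.1)       # then approximately flat
})
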