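test_that("two-column files parse and dt is inferred", {
  f <- withr::local_tempfile()
  writeLines(c("0,0", "1,5", "2,5"), f)
  tr <- read_trace(f)
  expect_equal(tr$dt, 1)
  expect_equal(tr$samples, c(0, 5, 5))
  expect_equal(tr$t0, 0)
})

test_that("trace round-trips at full precision in both dialects", {
  tr <- trace(c(pi, exp(1), -1 / 3, 1e-17), dt = 0.05, t0 = 2.5, kind = "voltage")
  for (fmt in c("single", "two_col")) {
    f <- withr::local_tempfile()
    write_trace(tr, f, format = fmt)
    back <- read_trace(f)
    expect_identical(back$samples, tr$samples)
    expect_equal(back$dt, tr$dt)
    expect_equal(back$t0, tr$t0)
    expect_identical(back$kind, "voltage")
  }
})

test_that("timestamp jitter beyond tolerance is rejected, naming the row", {
  f <- withr::local_tempfile()
  tt <- 0:9
  tt[6] <- tt[6] + 0.01
  writeLines(sprintf("%.6f\t%g", tt, seq_along(tt)), f)
  expect_error(read_trace(f), "non-uniform sampling.*row")
})

test_that("spike trains round-trip and validate ordering", {
  st <- spike_train(c(3.25, 110.5, 260), span = c(0, 300))
  f <- withr::local_tempfile()
  write_spike_train(st, f)
  back <- read_spike_train(f)
  expect_identical(back$times, st$times)
  expect_equal(back$span, st$span)
  expect_error(spike_train(c(5, 5)), "strictly increasing")
  expect_error(spike_train(c(5, 4)), "strictly increasing")
  expect_error(spike_train(10, span = c(0, 5)), "within span")
})

test_that("detect_spikes finds threshold crossings with refractory suppression", {
  flat <- trace(rep(-60, 100), dt = 0.1, kind = "voltage")
  expect_error(detect_spikes(flat, threshold = -70), "minimum")
  expect_length(detect_spikes(flat, threshold = -20)$times, 0)

  # single triangular excursion crossing -20 mV at t = 10
  v <- rep(-60, 301)
  v[96:105] <- seq(-60, -15, length.out = 10)   # rises; first sample >= -20 at t = 10
  v[106:115] <- seq(-20, -60, length.out = 10)
  tri <- trace(v, dt = 0.1, kind = "voltage")
  st <- detect_spikes(tri, threshold = -20, refractory = 1)
  expect_length(st$times, 1)
  expect_equal(st$times, 10, tolerance = 0.11)

  # 50 Hz sinusoid: one crossing per cycle (brute-force count as oracle)
  dt <- 0.1
  tt <- seq(0, 1000 - dt, by = dt)
  vv <- -40 + 30 * sin(2 * pi * tt / 20)
  above <- vv >= -20
  n_crossings <- sum(above & !c(FALSE, above[-length(above)]))
  sine <- trace(vv, dt = dt, kind = "voltage")
  expect_length(detect_spikes(sine, threshold = -20, refractory = 5)$times,
                n_crossings)
  expect_equal(n_crossings, 50)
})

test_that("detect_spikes is invariant to a joint constant offset", {
  set.seed(4)
  vv <- -55 + 10 * sin(2 * pi * seq(0, 500, by = 0.5) / 47) + rnorm(1001)
  v1 <- trace(vv, dt = 0.5, kind = "voltage")
  v2 <- trace(vv + 17.3, dt = 0.5, kind = "voltage")
  expect_identical(detect_spikes(v1, -50, refractory = 10)$times,
                   detect_spikes(v2, -50 + 17.3, refractory = 10)$times)
})

test_that("pulse_slope_qc is exact on an ideal capacitor", {
  # C = 100 pF: dV/dt = I/C, so linearity slope = 0.01 (mV/ms)/pA
  dt <- 0.05; d <- 1; C <- 100
  amps <- c(-40, 10, 60, -90, 25, 75, -15, 50)
  i <- trace(rep(amps, each = d / dt), dt = dt, kind = "current")
  v <- trace(-60 + cumsum(i$samples / C * dt), dt = dt, kind = "voltage")
  qc <- pulse_slope_qc(v, i, d = d)
  expect_equal(qc$per_pulse_slope, amps / C, tolerance = 1e-10)
  expect_equal(qc$linearity_slope, 1 / C, tolerance = 1e-10)
  expect_equal(qc$linearity_r2, 1, tolerance = 1e-12)
  expect_error(pulse_slope_qc(v, trace(rep(0, length(i$samples)), dt = dt,
                                       kind = "current"), d = d),
               "identical")
})

test_that("pulse_slope_qc on a noisy RC membrane matches the noiseless oracle", {
  dt <- 0.05; d <- 1; C <- 120; R <- 150 # Mohm; tau = 18 ms >> d
  set.seed(7)
  amps <- rnorm(40, 0, 60)
  i <- trace(rep(amps, each = d / dt), dt = dt, kind = "current")
  # explicit RC: dv/dt = I/C - v/tau with tau = R*C in ms
  v_clean <- numeric(length(i$samples))
  tau <- R * C / 1000
  v <- 0
  for (k in seq_along(i$samples)) {
    v <- v + dt * (i$samples[k] / C - v / tau)
    v_clean[k] <- v
  }
  clean <- pulse_slope_qc(trace(v_clean, dt = dt, kind = "voltage"), i, d = d)
  noisy <- pulse_slope_qc(trace(v_clean + rnorm(length(v_clean), 0, 0.05),
                                dt = dt, kind = "voltage"), i, d = d)
  expect_lt(abs(noisy$linearity_slope - clean$linearity_slope),
            3 * noisy$linearity_se)
  expect_lt(abs(clean$linearity_slope - 1 / C) / (1 / C), 0.05)
})
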