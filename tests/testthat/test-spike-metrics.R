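# Spike-train statistics: detector, classifier, IFR, bursts, PRC, filters.

test_that("spike detection finds constructed events and nothing else", {
  tt <- seq(0, 400, by = 0.025)
  v <- rep(-65, length(tt))
  for (mu in c(100, 200, 300)) v <- v + 85 * exp(-(tt - mu)^2 / (2 * 0.5^2))
  spk <- detect_spikes(v, time = tt)
  expect_equal(length(spk$times), 3L)
  expect_lt(max(abs(spk$times - c(100, 200, 300))), 1.5)
  # flat trace and out-of-range threshold give empty trains
  expect_equal(length(detect_spikes(rep(-65, 100), time = 1:100)$times), 0L)
  expect_equal(length(detect_spikes(v, threshold = 50, time = tt)$times), 0L)
  # refractory window suppresses double counts on a noisy rise
  v2 <- rep(-65, length(tt))
  v2[tt > 100 & tt < 100.5] <- 20
  v2[tt > 100.6 & tt < 101] <- 20  # re-crossing within 1 ms
  expect_equal(length(detect_spikes(v2, time = tt)$times), 1L)
})

test_that("ISI CoV matches closed forms", {
  reg <- gen_fixture_trains(list(kind = "regular", rate = 50), duration = 5000)
  expect_equal(isi_cov(reg), 0)
  # exponential ISIs: CoV -> 1
  pois <- gen_fixture_trains(list(kind = "gamma", rate = 20, shape = 1),
                             duration = 2e5, seed = 3)
  expect_lt(abs(isi_cov(pois) - 1), 0.05)
  # gamma(shape = 4): CoV -> 0.5
  g4 <- gen_fixture_trains(list(kind = "gamma", rate = 20, shape = 4),
                           duration = 2e5, seed = 4)
  expect_lt(abs(isi_cov(g4) - 0.5), 0.03)
  # fewer than 3 spikes: undefined marker, not an error
  expect_true(is.na(isi_cov(spike_train(c(10, 20), 0, 100))))
})

test_that("pattern classifier reproduces the published rules", {
  # regular 20-ms ISIs: dense
  expect_equal(classify_pattern(spike_train(seq(20, 2000, 20), 0, 2000)),
               "dense")
  # max ISI 150 ms with CoV 1.0: irregular (constructed fixture)
  tt <- cumsum(c(10, rep(c(10, 150, 30, 40), 12)))
  tr <- spike_train(tt, 0, max(tt) + 10)
  expect_gt(isi_cov(tr), 0.5); expect_lt(isi_cov(tr), 2)
  expect_equal(classify_pattern(tr), "irregular")
  # a short volley then thousands of ms of silence: sparse (CoV > 3)
  tr2 <- spike_train(c(seq(10, 19), 5019), 0, 9000)
  expect_gt(isi_cov(tr2), 3)
  expect_equal(classify_pattern(tr2), "sparse")
  # bursting: tight 2-ms ISIs inside bursts with 500-ms gaps
  b <- gen_fixture_trains(list(kind = "burst", n_bursts = 8,
                               spikes_per_burst = 10, intra_isi = 2,
                               gap = 500), duration = 4000)
  expect_gt(isi_cov(b), 2)
  expect_equal(classify_pattern(b), "bursting")
})

test_that("classifier agrees with an independent rule table on random fixtures", {
  set.seed(11)
  for (i in 1:1000) {
    n <- sample(0:60, 1)
    t1 <- runif(1, 500, 8000)
    times <- sort(runif(n, 0, t1))
    times <- times[!duplicated(round(times, 6))]
    tr <- spike_train(times, 0, t1)
    expect_identical(classify_pattern(tr), oracle_classify(times, 0, t1))
  }
})

test_that("classification is a pure function of the ISI statistics", {
  # permuting the ISIs preserves CoV and max ISI, hence non-sparse labels
  set.seed(5)
  for (i in 1:50) {
    isi <- rexp(40, 1 / 40) + 5
    t1 <- sum(isi) + 50
    tr1 <- spike_train(cumsum(isi), 0, t1)
    tr2 <- spike_train(cumsum(sample(isi)), 0, t1)
    l1 <- classify_pattern(tr1); l2 <- classify_pattern(tr2)
    if (!"sparse" %in% c(l1, l2)) expect_identical(l1, l2)
  }
})

test_that("IFR integrates to the spike count and plateaus at the rate", {
  tr <- spike_train(seq(100, 2000, by = 10), 0, 2100)
  f <- ifr_trace(tr)
  tt <- seq(0, 2100, by = 0.5)
  integral <- sum(f(tt)) * 0.5 / 1000  # Hz * ms -> spikes
  expect_lt(abs(integral - length(tr$times)) / length(tr$times), 0.01)
  # regular 10-ms train plateaus near 100 Hz mid-train; the kernel comb
  # leaves a bounded ripple around the plateau
  mid <- f(seq(800, 1200, by = 1))
  expect_lt(abs(mean(mid) - 100) / 100, 0.01)
  expect_lt(max(abs(mid - 100)) / 100, 0.12)
  expect_error(ifr_trace(spike_train(c(1, 2), 0, 10)), "at least 3")
})

test_that("transmission delay returns the first post-stimulus latency", {
  tr <- spike_train(c(100, 150, 208.5, 250), 0, 400)
  expect_equal(transmission_delay(200, tr), 8.5)
  expect_true(is.na(transmission_delay(300, tr)))   # nothing follows
  expect_true(is.na(transmission_delay(200, tr, window = 5)))
})

test_that("silence period excludes spikelets and flags absent recovery", {
  tr <- spike_train(c(100, 105, 112, 552.6), 0, 1000)
  expect_equal(silence_period(tr, 102), 450.6)
  expect_true(is.na(silence_period(spike_train(c(100, 105), 0, 9000), 102)))
  expect_error(silence_period(tr, NA), "marker")
})

test_that("burst decomposition matches the definitions and its oracle", {
  tr <- spike_train(c(0.1, 5, 9, 100, 104), 0.05, 200)
  d <- burst_decompose(tr)
  expect_equal(nrow(d$bursts), 2L)
  expect_equal(d$t_burst, 95)
  expect_equal(d$t_intv, 91)
  expect_equal(d$t_spike, c(8.9, 4))
  # identity T_burst(k) = T_intv(k) + T_spike(k+1)
  expect_equal(d$t_burst, d$t_intv + d$t_spike[-1])
  # single burst: one row, no intervals
  d1 <- burst_decompose(spike_train(c(1, 4, 8), 0, 50))
  expect_equal(nrow(d1$bursts), 1L)
  expect_equal(length(d1$t_burst), 0L)
  # empty train handled
  expect_equal(nrow(burst_decompose(spike_train(numeric(0), 0, 10))$bursts), 0L)
})

test_that("burst decomposition agrees with a gap-scan oracle on random trains", {
  set.seed(21)
  for (i in 1:500) {
    n <- sample(2:80, 1)
    isi <- sample(c(runif(n, 1, 8), runif(n, 15, 400)), n)
    times <- cumsum(isi)
    tr <- spike_train(times, 0, sum(isi) + 10)
    d <- burst_decompose(tr)
    o <- oracle_bursts(times)
    expect_equal(d$bursts$first, o$first)
    expect_equal(d$bursts$last, o$last)
    expect_equal(d$bursts$n, o$n)
    if (nrow(o) >= 2)
      expect_equal(d$t_burst, d$t_intv + d$t_spike[-1])
  }
})

test_that("relay fidelity counts spikes per pulse in the analysis window", {
  stim <- pulse_train(seq(50, 2000, by = 50))
  # perfect relay
  out <- spike_train(seq(50, 2000, by = 50) + 2, 0, 2005)
  expect_equal(relay_fidelity(out, stim), 1)
  # half-miss fixture
  out2 <- spike_train(seq(50, 2000, by = 100) + 2, 0, 2005)
  expect_equal(relay_fidelity(out2, stim), 0.5)
  expect_error(relay_fidelity(out, pulse_train(numeric(0))), "empty stimulus")
})

test_that("PRC estimator recovers a leaky-integrate-and-fire closed form", {
  # unperturbed regular oscillator: flat zero PRC
  reg <- spike_train(seq(10, 5000, by = 20), 0, 5010)
  pert <- pulse_train(seq(505, 4500, by = 97))
  prc0 <- estimate_prc(reg, pert, mean_period = 20)
  expect_lt(max(abs(prc0$shift), na.rm = TRUE), 1e-12)

  # LIF driven to period T; an instantaneous kick dV at phase phi advances
  # the next spike by a closed-form amount
  tau <- 20; vth <- 10; vinf <- 14; dv <- 0.8
  T <- tau * log(vinf / (vinf - vth))
  set.seed(99)
  spike_t <- 0
  kick_times <- c(); spikes <- 0
  while (spike_t < 2e5) {
    kick <- runif(1) < 0.35
    if (kick) {
      s <- runif(1, 0.02, 0.95) * T
      v_s <- vinf * (1 - exp(-s / tau)) + dv
      isi <- if (v_s >= vth) s else s + tau * log((vinf - v_s) / (vinf - vth))
      kick_times <- c(kick_times, spike_t + s)
    } else isi <- T
    spike_t <- spike_t + isi
    spikes <- c(spikes, spike_t)
  }
  tr <- spike_train(spikes[-1], 0, max(spikes) + 1)
  prc <- estimate_prc(tr, pulse_train(kick_times), mean_period = T)
  phi <- prc$phase
  v_s <- vinf * (1 - exp(-phi * T / tau)) + dv
  shift_exp <- ifelse(v_s >= vth, 1 - phi,
                      (T - (phi * T + tau * log((vinf - v_s) / (vinf - vth)))) / T)
  ok <- !is.na(prc$shift) & prc$n > 20
  expect_gt(sum(ok), 10)
  expect_lt(max(abs(prc$shift[ok] - shift_exp[ok])), 0.02)
})

test_that("the 30-Hz low-pass filter has the expected transfer function", {
  dt <- 1  # 1 kHz sampling
  tt <- seq(0, 5000, by = dt)
  # DC passes unchanged away from the forward-backward edge transients
  dc <- filter_compound_current(rep(2.5, length(tt)), dt)
  mid0 <- seq(1000, 4000)
  expect_lt(max(abs(dc[mid0] - 2.5)), 1e-6)
  # 100-Hz sine attenuated by more than 20 dB (zero-phase doubles the order)
  s100 <- sin(2 * pi * 100 / 1000 * seq_along(tt))
  out <- filter_compound_current(s100, dt)
  mid <- seq(1000, 4000)
  expect_lt(max(abs(out[mid])), 0.1)
  # 1-Hz sine passes with gain ~ 1
  s1 <- sin(2 * pi * 1 / 1000 * seq_along(tt))
  out1 <- filter_compound_current(s1, dt)
  expect_gt(max(out1[mid]) / max(s1[mid]), 0.98)
  expect_error(filter_compound_current(s1, dt = 40), "sampling rate")
})

test_that("charge-density differences follow the integral definition", {
  tt <- seq(0, 300, by = 0.025)
  a <- matrix(0.2, length(tt), 1)
  # identical traces: zero
  expect_equal(unname(charge_density_delta(tt, a, a, 50, 250)), 0)
  # constant offset delta over window W gives delta * W (in uC/cm^2)
  b <- a + 0.05
  expect_equal(unname(charge_density_delta(tt, a, b, 50, 250)),
               0.05 * 200 * 1e-3, tolerance = 1e-9)
  # trapezoid agrees with a high-order quadrature on a smooth trace
  f <- function(t) 0.1 * sin(t / 30) + 0.02 * t / 300
  ref <- stats::integrate(f, 50, 250, rel.tol = 1e-10)$value
  got <- charge_density_delta(tt, matrix(f(tt)), matrix(0 * tt), 50, 250)
  expect_lt(abs(unname(got) - ref * 1e-3) / (ref * 1e-3), 1e-3)
  expect_error(charge_density_delta(tt, a, a[-1, , drop = FALSE], 0, 10),
               "mismatched")
})
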