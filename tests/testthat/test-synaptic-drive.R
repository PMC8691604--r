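# Synaptic kernels, pulse trains, and the stock drive configurations.

test_that("alpha kernel is normalised and vanishes for non-positive lags", {
  a <- alpha_kernel(0.6, 1.0)
  expect_equal(a(0), 0)
  expect_equal(a(-5), 0)
  # closed-form peak location, cross-checked by dense grid maximisation
  zstar <- 0.6 * 1.0 / (1.0 - 0.6) * log(1.0 / 0.6)
  expect_equal(a(zstar), 1, tolerance = 1e-12)
  zg <- seq(0.001, 10, by = 1e-4)
  expect_lt(abs(zg[which.max(a(zg))] - zstar), 1e-3)
  expect_lt(max(a(zg)), 1 + 1e-9)
  # tau2 -> infinity limit approaches a saturating rise on bounded z
  a_inf <- alpha_kernel(0.6, 5000)
  A <- alpha_norm(0.6, 5000)
  z <- seq(0.1, 3, by = 0.1)
  expect_equal(a_inf(z), A * (exp(-z / 5000) - exp(-z / 0.6)),
               tolerance = 1e-12)
  expect_error(alpha_kernel(1.0, 0.6), "tau1 < tau2")
})

test_that("syn_current follows the conductance-times-driving-force rule", {
  sp <- synapse_spec(1, 0.6, 1.0, 0, target = 1)
  tr <- pulse_train(10)
  tt <- seq(0, 30, by = 0.01)
  # reversal: V == E_syn -> zero current
  expect_equal(syn_current(sp, tr, v = 0, time = tt), numeric(length(tt)))
  # single event at clamped -60 mV with g = 1 uS -> peak |I| = 60 nA at z*
  I <- syn_current(sp, tr, v = -60, time = tt)
  expect_equal(min(I), -60, tolerance = 1e-4)
  zstar <- 0.6 / 0.4 * log(1 / 0.6)
  expect_lt(abs(tt[which.min(I)] - (10 + zstar)), 0.02)
  # two well-separated events superpose as identical transients
  tr2 <- pulse_train(c(10, 200))
  I2 <- syn_current(sp, tr2, v = -60, time = tt)
  expect_equal(I2, I, tolerance = 1e-9)  # second event outside window
})

test_that("compound current is additive over synapses and linear in gain", {
  glut <- list(list(spec = synapse_spec(2.5e-4, 0.6, 1.0, 0, 1),
                    train = pulse_train(c(5, 12))),
               list(spec = synapse_spec(2.5e-4, 0.6, 1.0, 0, 2),
                    train = pulse_train(8)))
  gaba <- list(list(spec = synapse_spec(1e-3, 1.0, 5.0, -80, 3),
                    train = pulse_train(c(6, 15))))
  tt <- seq(0, 40, by = 0.05)
  # empty sets give zero
  expect_equal(compound_current(list(), list(), -60, tt),
               numeric(length(tt)))
  # GABA-only at its reversal gives zero
  expect_equal(compound_current(list(), gaba, -80, tt),
               numeric(length(tt)))
  # equals the signed sum of per-synapse currents
  ref <- Reduce(`+`, lapply(glut, function(s)
          syn_current(s$spec, s$train, -60, tt))) -
         syn_current(gaba[[1]]$spec, gaba[[1]]$train, -60, tt)
  expect_equal(compound_current(glut, gaba, -60, tt), ref, tolerance = 1e-12)
  # delta_syn = +0.6 scales the clamped-voltage current by exactly 1.6
  expect_equal(compound_current(glut, gaba, -60, tt, delta_syn = 0.6),
               1.6 * compound_current(glut, gaba, -60, tt), tolerance = 1e-12)
})

test_that("exponential trains have the prescribed rate and are reproducible", {
  # empty window
  expect_equal(length(gen_exp_train(2, 2, 100, 100, seed = 1)$times), 0)
  # law of large numbers: mean IPI = t_r + lambda within 3 S.E.
  tr <- gen_exp_train(50, 0, 0, 1e5, seed = 42)
  ipi <- diff(tr$times)
  se <- 50 / sqrt(length(ipi))
  expect_lt(abs(mean(ipi) - 50), 3 * se)
  # shifted-exponential rate for the complex-spike recipe
  tr2 <- gen_exp_train(2, 2, 0, 2e4, seed = 7)
  ipi2 <- diff(tr2$times)
  expect_lt(abs(mean(ipi2) - 4), 3 * 2 / sqrt(length(ipi2)))
  expect_gt(min(ipi2), 2)  # refractory offset respected
  # the 15-ms CS-like window typically holds a handful of pulses
  tr3 <- gen_exp_train(2, 2, 300, 315, seed = 1)
  expect_gte(length(tr3$times), 2)
  expect_lte(length(tr3$times), 8)
  # bit-identical under the same seed; different otherwise
  expect_identical(gen_exp_train(50, 0, 0, 1000, seed = 5)$times,
                   gen_exp_train(50, 0, 0, 1000, seed = 5)$times)
  expect_false(identical(gen_exp_train(50, 0, 0, 1000, seed = 5)$times,
                         gen_exp_train(50, 0, 0, 1000, seed = 6)$times))
})

test_that("scenario drives build the documented synapse layouts", {
  dcn <- dcn_model()
  d1 <- gen_scenario_drives("dcn_inhibition", dcn, seed = 1)
  expect_equal(length(d1$synapses), 450L)
  # one per dendritic compartment plus 50 at the soma
  tg <- vapply(d1$synapses, function(s) s$spec$target, 0L)
  soma <- ctdcs:::soma_index(dcn)
  expect_equal(sum(tg == soma), 50L)
  expect_equal(length(unique(tg[tg != soma])), 400L)
  # all share the common train, which spans <= 15 ms from 300 ms
  trains <- lapply(d1$synapses, function(s) s$train$times)
  expect_true(all(vapply(trains, identical, TRUE, trains[[1]])))
  expect_gte(min(trains[[1]]), 300)
  expect_lt(max(trains[[1]]), 315)

  pc <- pc_model()
  d3 <- gen_scenario_drives("pc_scenario3", pc, seed = 1, stop = 1000)
  expect_equal(length(d3$synapses), 1100L)
  tg3 <- vapply(d3$synapses, function(s) s$spec$target, 0L)
  expect_equal(length(unique(tg3)), 1100L)  # non-overlapping placement
  lab <- vapply(d3$synapses, function(s) s$spec$label, "")
  expect_equal(sum(lab == "glut"), 1000L)
  expect_equal(sum(lab == "GABA"), 100L)
  expect_equal(d3$delta_syn, 0)
  # identity scaling at delta_syn = 0: conductances at hat values
  gg <- vapply(d3$synapses, function(s) s$spec$g_syn, 0)
  expect_true(all(gg[lab == "glut"] == 2.5e-4))
  expect_true(all(gg[lab == "GABA"] == 1e-3))
  # same seed reproduces the whole configuration
  d3b <- gen_scenario_drives("pc_scenario3", pc, seed = 1, stop = 1000)
  expect_identical(lapply(d3$synapses, function(s) s$train$times),
                   lapply(d3b$synapses, function(s) s$train$times))

  cf <- gen_scenario_drives("pc_cf", pc)
  thick <- pc$morph$compartments$diam >= 3.5 &
    pc$morph$compartments$section == "dendrite"
  expect_equal(length(cf$synapses), sum(thick))
  expect_true(all(vapply(cf$synapses, function(s) s$spec$g_syn, 0) == 1.59e-3))

  grc <- grc_model()
  mf <- gen_scenario_drives("grc_mf", grc, f_stim = 20)
  expect_equal(length(mf$synapses), 2L)
  expect_equal(vapply(mf$synapses, function(s) s$spec$g_syn, 0),
               c(2.88e-3, 4.51e-4))
})

test_that("scenario drives error when the morphology cannot host them", {
  small <- passive_cable(n = 10)
  expect_error(gen_scenario_drives("pc_scenario3", small, stop = 100),
               "fewer eligible")
  expect_error(gen_scenario_drives("dcn_inhibition", small), "400 dendritic")
  expect_error(gen_scenario_drives("pc_cf", small), "diameter >= 3.5")
})

test_that("drive configuration validates its parts", {
  expect_error(drive_config(list(), delta_syn = -1.2), "delta_syn > -1")
  expect_error(pulse_train(c(3, 2, 5)), "strictly increasing")
  expect_error(pulse_train(-1), "non-negative")
  expect_error(synapse_spec(1, 2, 1, 0, 1))  # tau1 >= tau2
})

test_that("drive configurations export their trains as two-column CSV", {
  d <- gen_scenario_drives("grc_mf", grc_model(), f_stim = 10, stop = 600)
  f <- file.path(tempdir(), "drive.csv")
  write_drive_csv(d, f)
  tab <- read.csv(f)
  expect_equal(names(tab), c("synapse", "time_ms"))
  expect_equal(sum(tab$synapse == 1), length(d$synapses[[1]]$train$times))
})
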