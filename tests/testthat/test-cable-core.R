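# Core simulator: passive closed forms, reference-integrator cross-check,
# field coupling, polarization properties.

test_that("passive compartment charges with the RC closed form", {
  m <- passive_soma()
  area <- surface_area(m)
  R_mohm <- 1 / (1e-4 * area * 1e6)        # MOhm
  tau_ms <- 1 * area * 1e3 / (1e-4 * area * 1e6)  # nF / uS = ms
  sim <- simulate_cell(m, duration = 200, v_init = -65,
                       injections = data.frame(comp = 1, t0 = 0, t1 = 300,
                                               amp_nA = 0.1))
  v_inf <- -65 + 0.1 * R_mohm
  # closed form at a handful of times, within 0.1 %
  for (t in c(25, 50, 100, 195)) {
    v_exp <- v_inf + (-65 - v_inf) * exp(-t / tau_ms)
    v_got <- sim$v[which.min(abs(sim$time - t)), 1]
    expect_lt(abs(v_got - v_exp) / abs(v_inf + 65), 1e-3)
  }
})

test_that("leak-only membrane stays at the leak reversal", {
  m <- passive_soma(e_leak = -70)
  sim <- simulate_cell(m, duration = 300, v_init = -70)
  expect_lt(max(abs(sim$v + 70)), 1e-9)
  expect_lt(max(abs(sim$v_drift)), 1e-12)
})

test_that("squid-type soma firing rate matches an adaptive-step reference", {
  skip_if_not_installed("deSolve")
  m <- squid_soma()
  amp <- 0.15
  sim <- simulate_cell(m, duration = 1200, dt = 0.01, v_init = -65,
                       injections = data.frame(comp = 1, t0 = 0, t1 = 1300,
                                               amp_nA = amp))
  spk <- detect_spikes(sim)
  rate_be <- 1000 * sum(spk$times > 200) / 1000

  # independent high-accuracy reference: same ODEs, adaptive lsoda
  ch <- m$channels
  gates <- function(v, ch_i) {
    g <- ch[[ch_i]]$gates
    lapply(g, function(gt) {
      inf <- 1 / (1 + exp(-(v - gt$vh) / gt$k))
      tau <- if (gt$tauform == 0) gt$tau0
             else gt$tau0 + gt$amp / (exp((v - gt$vd) / gt$s1) +
                                      exp(-(v - gt$vd) / gt$s2))
      c(inf = inf, tau = tau)
    })
  }
  area <- surface_area(m)
  gna <- 0.12 * area * 1e6; gk <- 0.036 * area * 1e6
  gl <- 3e-4 * area * 1e6; cap <- 1 * area * 1e3  # nF
  rhs <- function(t, y, parms) {
    v <- y[1]; mm <- y[2]; h <- y[3]; n <- y[4]
    gna_t <- gna * mm^3 * h; gk_t <- gk * n^4
    ina <- gna_t * (v - 50); ik <- gk_t * (v + 77); il <- gl * (v + 54.4)
    dv <- (-ina - ik - il + amp) / cap
    gm <- gates(v, 1); gk2 <- gates(v, 2)
    dm <- (gm[[1]]["inf"] - mm) / gm[[1]]["tau"]
    dh <- (gm[[2]]["inf"] - h) / gm[[2]]["tau"]
    dn <- (gk2[[1]]["inf"] - n) / gk2[[1]]["tau"]
    list(c(dv, dm, dh, dn))
  }
  g0m <- gates(-65, 1); g0k <- gates(-65, 2)
  y0 <- c(-65, g0m[[1]]["inf"], g0m[[2]]["inf"], g0k[[1]]["inf"])
  out <- deSolve::lsoda(y0, seq(0, 1200, by = 0.05), rhs, NULL,
                        rtol = 1e-8, atol = 1e-8)
  vref <- out[, 2]
  up <- which(vref[-1] >= 0 & vref[-length(vref)] < 0) + 1
  tref <- out[up, 1]
  rate_ref <- 1000 * sum(tref > 200) / 1000
  expect_lt(abs(rate_be - rate_ref) / rate_ref, 0.01)
})

test_that("extracellular potentials follow the quasi-uniform rule", {
  m <- passive_cable(n = 10, total_L = 100)
  # zero field
  expect_equal(extracellular_potentials(m, field_spec(0)),
               numeric(11))
  # compartment 100 um from the soma along the field at +1.5 V/m -> 0.15 mV
  ve <- extracellular_potentials(m$morph, field_spec(1.5))
  mid <- ctdcs:::morph_midpoints(m$morph)
  far <- which.min(abs((mid[, 1] - mid[1, 1]) - 100))
  expect_equal(ve[far], 1.5 * (mid[far, 1] - mid[1, 1]) * 1e-3,
               tolerance = 1e-12)
  # field perpendicular to every compartment axis -> all zero
  ve90 <- extracellular_potentials(m$morph, field_spec(1.5, theta = 90))
  expect_lt(max(abs(ve90)), 1e-12)
})

test_that("degenerate somato-axonal axis is rejected", {
  df <- data.frame(id = 1L, parent = 0L, x0 = 0, y0 = 0, z0 = 0,
                   x1 = 20, y1 = 0, z1 = 0, diam = 20, section = "soma")
  expect_error(morphology(df, c(0, 0, 0)), "degenerate")
})

test_that("polarization profile is antisymmetric, linear, and zero at E = 0", {
  m <- passive_cable()
  pp_pos <- polarization_profile(m, field_spec(1.5))
  pp_neg <- polarization_profile(m, field_spec(-1.5))
  pp_half <- polarization_profile(m, field_spec(0.75))
  expect_lt(max(abs(pp_pos + pp_neg)), 1e-8)          # antisymmetry
  expect_lt(max(abs(pp_pos - 2 * pp_half)), 1e-8)     # linearity
  expect_equal(polarization_profile(m, field_spec(0)),
               numeric(nrow(m$morph$compartments)))
})

test_that("polarization length fits with R^2 > 0.999 and handles edge cases", {
  m <- passive_cable()
  pl <- polarization_length(m, intensities = seq(-1.5, 1.5, length.out = 13))
  expect_gt(pl$r_squared, 0.999)
  expect_gt(pl$s, 0)
  # single symmetric compartment has no preferred axis: s ~ 0
  m0 <- passive_soma()
  pl0 <- polarization_length(m0, intensities = c(-1.5, 0, 1.5))
  expect_lt(pl0$s, 1e-6)
  expect_error(polarization_length(m, intensities = c(-1, 1)), "at least 3")
})

test_that("block_channels blocks, errors on unknown names, leaves input intact", {
  m <- squid_soma()
  mb <- block_channels(m, "Na")
  expect_equal(mb$channels[[1]]$gmax, 0)
  expect_gt(m$channels[[1]]$gmax, 0)  # original unchanged
  expect_error(block_channels(m, "Nav9"), "unknown channel")
  # block all -> leak only -> no spikes under strong drive
  mall <- block_channels(m, "all")
  sim <- simulate_cell(mall, duration = 300, v_init = -65,
                       injections = data.frame(comp = 1, t0 = 10, t1 = 300,
                                               amp_nA = 0.05))
  expect_equal(length(detect_spikes(sim)$times), 0)
  # block nothing -> identical traces
  s1 <- simulate_cell(m, duration = 100, v_init = -65)
  s2 <- simulate_cell(block_channels(m, character(0)), duration = 100,
                      v_init = -65)
  expect_identical(s1$v, s2$v)
})

test_that("integration failure reports the time of divergence", {
  m <- passive_soma()
  expect_error(
    simulate_cell(m, duration = 100, v_init = -65,
                  injections = data.frame(comp = 1, t0 = 0, t1 = 100,
                                          amp_nA = 1e5)),
    "integration failure")
})

test_that("grid refinement leaves stimulus-locked spike times nearly unchanged", {
  # the early, stimulus-locked spikes of a 2-s tonic response shift by less
  # than 0.1 ms when dt is halved; over the full 2 s an autonomous
  # oscillator accumulates phase, so the per-period drift is checked instead
  m <- squid_soma()
  inj <- data.frame(comp = 1, t0 = 0, t1 = 2100, amp_nA = 0.15)
  s1 <- simulate_cell(m, duration = 2000, dt = 0.025, v_init = -65,
                      injections = inj)
  s2 <- simulate_cell(m, duration = 2000, dt = 0.0125, v_init = -65,
                      injections = inj)
  t1 <- detect_spikes(s1)$times
  t2 <- detect_spikes(s2)$times
  expect_lt(max(abs(t1[1:3] - t2[1:3])), 0.1)
  n <- min(length(t1), length(t2))
  drift_per_period <- abs(t1[n] - t2[n]) / n
  expect_lt(drift_per_period, 0.1)
})

test_that("membrane charge is conserved on a leak-only tree", {
  m <- passive_cable()
  sim <- simulate_cell(m, duration = 1000, v_init = -65)
  # zero net injected current, started at rest: no drift anywhere
  expect_lt(max(abs(sim$v_final + 65)), 1e-9)
})
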