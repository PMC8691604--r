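# Shared fixtures. Models and expensive simulations are built once per test
# run and cached here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

pc_model <- function() cached("pc", build_reduced_pc())
dcn_model <- function() cached("dcn", build_reduced_dcn())
grc_model <- function() cached("grc", build_grc())

# single passive compartment (20 um sphere-equivalent cylinder)
passive_soma <- function(g_leak = 1e-4, e_leak = -65) {
  df <- data.frame(id = 1L, parent = 0L, x0 = 0, y0 = 0, z0 = 0,
                   x1 = 20, y1 = 0, z1 = 0, diam = 20, section = "soma")
  neuron_model(morphology(df, c(1, 0, 0)),
               passive = list(cm = 1, ra = 150, g_leak = g_leak,
                              e_leak = e_leak))
}

# straight passive cable: soma plus n axon compartments along +x
passive_cable <- function(n = 50, total_L = 500, diam = 2, g_leak = 5e-5) {
  df <- data.frame(id = 1L, parent = 0L, x0 = 0, y0 = 0, z0 = 0,
                   x1 = 20, y1 = 0, z1 = 0, diam = 20,
                   section = "soma", region = "soma")
  ch <- ctdcs:::morph_chain(list(df), 1L, c(20, 0, 0), n, total_L, diam,
                            c(1, 0, 0), "axon")
  neuron_model(morphology(do.call(rbind, ch$rows), c(1, 0, 0)),
               passive = list(cm = 1, ra = 150, g_leak = g_leak,
                              e_leak = -65))
}

# squid-type single-compartment Na/K soma used for the reference-integrator
# cross-check; rate parameters follow the classical formulation, shifted so
# the resting potential is -65 mV
squid_soma <- function() {
  m <- passive_soma(g_leak = 3e-4, e_leak = -54.4)
  m$channels <- list(
    channel("Na", "soma", 0.12, 50, gates = list(
      gate_v(3, vh = -40, k = 9, tau0 = 0.04, amp = 0.45, vd = -38,
             s1 = 12, s2 = 12),
      gate_v(1, vh = -62, k = -7, tau0 = 0.35, amp = 7, vd = -62,
             s1 = 14, s2 = 14))),
    channel("K", "soma", 0.036, -77, gates = list(
      gate_v(4, vh = -53, k = 15, tau0 = 0.6, amp = 5, vd = -50,
             s1 = 25, s2 = 25))))
  m
}

# Independent rule-table classifier used as the brute-force oracle for
# classify_pattern: same published rules, separate implementation.
oracle_classify <- function(times, t0, t1) {
  n <- length(times)
  cv <- if (n >= 3) {
    isi <- diff(times); sd(isi) / mean(isi)
  } else NA_real_
  silent <- if (n == 0) t1 - t0 else max(c(diff(times), t1 - times[n]))
  if (silent > 3000 && (is.na(cv) || cv > 3)) return("sparse")
  if (n < 3) return(if (n == 0 && t1 - t0 > 3000) "sparse" else "unclassified")
  mx <- max(diff(times))
  if (mx > 200 && cv > 2) return("bursting")
  if (mx > 80 && mx <= 200 && cv > 0.5 && cv <= 2) return("irregular")
  if (mx < 80 && cv < 0.5) return("dense")
  "unclassified"
}

# Brute-force burst scan oracle: walks the train accumulating runs whose
# consecutive ISIs stay below the gap.
oracle_bursts <- function(times, gap = 10, min_spikes = 2) {
  if (!length(times)) return(data.frame(first = numeric(0), last = numeric(0),
                                        n = integer(0)))
  runs <- list()
  cur <- times[1]
  for (t in times[-1]) {
    if (t - cur[length(cur)] < gap) cur <- c(cur, t)
    else { runs <- c(runs, list(cur)); cur <- t }
  }
  runs <- c(runs, list(cur))
  runs <- Filter(function(r) length(r) >= min_spikes, runs)
  data.frame(first = vapply(runs, min, 0), last = vapply(runs, max, 0),
             n = vapply(runs, length, 0L))
}
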