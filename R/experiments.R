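# Experiment runners: one function per stock experiment, plus a config
# dispatcher. All runners are deterministic given their seeds.

the <- new.env(parent = emptyenv())

#' Shipped calibrated models (memoised)
#'
#' Builds the calibrated reduced PC / DCN / GrC models once per session.
#' @param cell one of "PC", "DCN", "GrC"
#' @export
default_model <- function(cell = c("PC", "DCN", "GrC")) {
  cell <- match.arg(cell)
  key <- paste0("model_", cell)
  if (is.null(the[[key]])) {
    the[[key]] <- switch(cell,
      PC = build_reduced_pc(),
      DCN = build_reduced_dcn(),
      GrC = build_grc())
  }
  the[[key]]
}

#' Tonic firing rate at rest
#'
#' Simulates the cell with no synaptic input, optionally under a field,
#' and reports the spike rate after discarding the transient.
#'
#' @param model the cell model
#' @param E field intensity, V/m (0 = no field)
#' @param theta field angle, degrees
#' @param duration simulated time, ms
#' @param transient discarded initial window, ms
#' @param bias optional [bias_spec()]
#' @param dt integration step, ms
#' @return list with `rate_hz`, `spikes`, `cov`
#' @export
exp_tonic_rate <- function(model, E = 0, theta = 0, duration = 5000,
                           transient = 1000, bias = NULL, dt = 0.025) {
  f <- if (E != 0) field_spec(E, theta) else NULL
  sim <- simulate_cell(model, field = f, bias = bias, duration = duration,
                       dt = dt, v_init = model$passive$e_leak)
  spk <- detect_spikes(sim)
  sel <- spk$times > transient
  sub <- spike_train(spk$times[sel], transient, duration)
  list(rate_hz = firing_rate(sub), spikes = spk, cov = isi_cov(sub))
}

#' Polarization experiment: somatic steady-state shift over a field grid
#'
#' @param model the cell model
#' @param intensities field grid, V/m
#' @param theta field angle, degrees
#' @return data.frame with `E` and `dv_soma` (mV)
#' @export
exp_polarization <- function(model, intensities = seq(-1.5, 1.5, length.out = 13),
                             theta = 0) {
  soma <- soma_index(model)
  dv <- vapply(intensities, function(E) {
    if (E == 0) 0 else polarization_profile(model, field_spec(E, theta))[soma]
  }, 0)
  data.frame(E = intensities, dv_soma = dv)
}

#' DCN rebound-firing experiment
#'
#' GABAergic complex-spike-like volley on the DCN model (450 synapses,
#' common train at 300 ms spanning 15 ms), followed by after-
#' hyperpolarisation rebound. Reports the rebound IFR and where its peak
#' falls relative to the first rebound spike.
#'
#' @param model the DCN model
#' @param E field intensity, V/m
#' @param seed train seed
#' @param duration simulated time, ms
#' @return list with `sim`, `spikes`, `ifr` (function), `rebound` (first
#'   rebound spike time), `peak_spike_offset` (spikes between the first
#'   rebound spike and the IFR peak), `max_ifr_hz`, `pre_rate_hz`
#' @export
exp_dcn_rebound <- function(model, E = 0, seed = 1, duration = 1500) {
  drive <- gen_scenario_drives("dcn_inhibition", model, seed = seed)
  f <- if (E != 0) field_spec(E) else NULL
  sim <- simulate_cell(model, drive = drive, field = f, duration = duration,
                       v_init = model$passive$e_leak)
  spk <- detect_spikes(sim)
  pre <- spk$times[spk$times < 300]
  pre_rate <- 1000 * length(pre[pre > 100]) / 200
  post <- spk$times[spk$times > 315]
  if (length(post) < 4) stop("no rebound firing detected")
  ifr <- ifr_trace(spk)
  # IFR evaluated at the post-volley spike times
  vals <- ifr(post)
  pk <- which.max(vals[seq_len(min(15, length(vals)))])
  list(sim = sim, spikes = spk, ifr = ifr, rebound = post[1],
       peak_spike_offset = pk - 1L, max_ifr_hz = max(vals),
       pre_rate_hz = pre_rate)
}

#' Granule-cell relay-fidelity experiment
#'
#' Regular mossy-fibre train at `f_stim` onto the GrC dendrite; relay ratio
#' over the final 2,000 ms.
#'
#' @param model the GrC model
#' @param f_stim stimulation frequency, Hz
#' @param E field intensity, V/m
#' @param duration simulated time, ms (train starts at 100 ms)
#' @return list with `r`, `spikes`, `train`
#' @export
exp_grc_relay <- function(model, f_stim, E = 0, duration = 2300) {
  drive <- gen_scenario_drives("grc_mf", model, f_stim = f_stim,
                               stop = duration)
  f <- if (E != 0) field_spec(E) else NULL
  sim <- simulate_cell(model, drive = drive, field = f, duration = duration,
                       v_init = model$passive$e_leak)
  spk <- detect_spikes(sim, threshold = -20)
  list(r = relay_fidelity(spk, drive$synapses[[1]]$train, window = 2000),
       spikes = spk, train = drive$synapses[[1]]$train)
}

#' Purkinje-cell transmission-delay experiment (dendrite-to-soma latency)
#'
#' Axonal-initial-segment sodium channels blocked, membrane held at
#' -65 mV; a 0.5-nA, 0.5-ms pulse at the most distal dendritic
#' compartment at `pulse_time`; the delay is the latency to the first
#' somatic spike.
#'
#' @param model the PC model
#' @param E field intensity, V/m
#' @param theta field angle, degrees
#' @param pulse_time pulse onset, ms
#' @param duration simulated time, ms
#' @return list with `t_d` (ms, `NA` if no spike), `spikes`, `sim`
#' @export
exp_pc_td <- function(model, E = 0, theta = 0, pulse_time = 500,
                      duration = 1000) {
  blocked <- block_channels(model, c("NaV1.6_AIS", "NaP_AIS"))
  target <- most_distal_dendrite(model)
  f <- if (E != 0) field_spec(E, theta) else NULL
  sim <- simulate_cell(blocked, field = f,
    injections = data.frame(comp = target, t0 = pulse_time,
                            t1 = pulse_time + 0.5, amp_nA = 0.5),
    duration = duration, v_init = -65)
  spk <- detect_spikes(sim, threshold = -20)
  list(t_d = transmission_delay(pulse_time, spk), spikes = spk, sim = sim)
}

#' Purkinje-cell phase-response-curve experiment
#'
#' Weak parallel-fibre-like synapse at the most distal dendrite, Poisson
#' pulses (`lambda = 50` ms); the PRC is estimated from the perturbed
#' inter-spike intervals. At rest the model's tonic rate already falls in
#' the 50-70 Hz band, so no bias current is applied.
#'
#' @param model the PC model
#' @param E field intensity, V/m
#' @param seed train seed
#' @param duration simulated time, ms (pulses start at 2,000 ms)
#' @param nbins phase bins
#' @return list with `prc` (data.frame), `rate_hz`, `spikes`
#' @export
exp_pc_prc <- function(model, E = 0, seed = 1, duration = 30000, nbins = 20) {
  drive <- gen_scenario_drives("pc_scenario2", model, seed = seed,
                               stop = duration)
  f <- if (E != 0) field_spec(E) else NULL
  sim <- simulate_cell(model, drive = drive, field = f, duration = duration,
                       v_init = model$passive$e_leak)
  spk <- detect_spikes(sim)
  tonic <- spike_train(spk$times[spk$times > 500 & spk$times < 2000], 500, 2000)
  prc <- estimate_prc(spk, drive$synapses[[1]]$train)
  list(prc = prc, rate_hz = firing_rate(tonic), spikes = spk)
}

#' Purkinje-cell polysynaptic-drive experiment
#'
#' 1,000 glutamatergic and 100 GABAergic synapses on random non-overlapping
#' dendritic compartments, each driven by its own exponential train;
#' repeated over the drive configurations (seeds) and averaged. The field
#' (when applied) starts at `field_onset`; with-field statistics use the
#' post-onset window, baseline statistics the full post-transient window.
#'
#' @param model the PC model
#' @param E field intensity, V/m
#' @param delta_syn synaptic gain offset
#' @param seeds drive-configuration seeds
#' @param duration simulated time per seed, ms
#' @param field_onset field onset, ms
#' @param transient discarded window for baseline statistics, ms
#' @return list with `rate_hz`, `rate_sd`, `cov`, `cov_sd`, `patterns`,
#'   `max_ifr_hz`, `per_seed` (data.frame)
#' @export
exp_pc_scenario3 <- function(model, E = 0, delta_syn = 0, seeds = c(1, 2, 3),
                             duration = 10000, field_onset = 2000,
                             transient = 500) {
  t0 <- if (E != 0) field_onset else transient
  rows <- lapply(seeds, function(sd) {
    drive <- gen_scenario_drives("pc_scenario3", model, seed = sd,
                                 stop = duration, delta_syn = delta_syn)
    f <- if (E != 0) field_spec(E, onset = field_onset) else NULL
    sim <- simulate_cell(model, drive = drive, field = f, duration = duration,
                         v_init = model$passive$e_leak)
    spk <- detect_spikes(sim)
    sub <- spike_train(spk$times[spk$times > t0], t0, duration)
    mi <- if (length(sub$times) >= 3) max(ifr_trace(sub)(sub$times)) else NA_real_
    data.frame(seed = sd, rate_hz = firing_rate(sub), cov = isi_cov(sub),
               pattern = classify_pattern(sub), max_ifr_hz = mi)
  })
  per <- do.call(rbind, rows)
  list(rate_hz = mean(per$rate_hz), rate_sd = sd(per$rate_hz),
       cov = mean(per$cov, na.rm = TRUE), cov_sd = sd(per$cov),
       patterns = per$pattern, max_ifr_hz = mean(per$max_ifr_hz, na.rm = TRUE),
       per_seed = per)
}

#' Purkinje-cell complex-spike experiment
#'
#' Climbing-fibre drive (common pulse onto all thick dendritic
#' compartments) evoking a complex spike followed by a silence period.
#'
#' @param model the PC model
#' @param E field intensity, V/m
#' @param bias optional [bias_spec()] applied instead of / on top of a field
#' @param pulse_time climbing-fibre pulse, ms
#' @param duration simulated time, ms
#' @param record_currents record somatic current densities
#' @return list with `t_sp` (ms, `NA` if no simple spike follows),
#'   `cs_peak`, `spikes`, `sim`
#' @export
exp_pc_cs <- function(model, E = 0, bias = NULL, pulse_time = 500,
                      duration = 2500, record_currents = FALSE) {
  drive <- gen_scenario_drives("pc_cf", model, pulse_time = pulse_time)
  f <- if (E != 0) field_spec(E) else NULL
  sim <- simulate_cell(model, drive = drive, field = f, bias = bias,
                       duration = duration, v_init = model$passive$e_leak,
                       record_currents = record_currents)
  spk <- detect_spikes(sim)
  pk <- cs_peak_time(sim, pulse_time)
  list(t_sp = silence_period(spk, pk), cs_peak = pk, spikes = spk, sim = sim)
}

#' Purkinje-cell transient-bursting experiment
#'
#' 2-nA depolarising step into the soma at 200 ms; bursts are decomposed
#' with the 10-ms gap rule.
#'
#' @param model the PC model
#' @param E field intensity, V/m
#' @param bias optional [bias_spec()]
#' @param amp_nA step amplitude (default 2)
#' @param onset step onset, ms
#' @param duration simulated time, ms (step stays on)
#' @return list with `burst_count`, `mean_t_burst` (over the first five
#'   bursts), `decomposition`, `sequence_duration`, `spikes`, `sim`
#' @export
exp_pc_burst <- function(model, E = 0, bias = NULL, amp_nA = 2, onset = 200,
                         duration = 3000) {
  f <- if (E != 0) field_spec(E) else NULL
  soma <- soma_index(model)
  sim <- simulate_cell(model, field = f, bias = bias,
    injections = data.frame(comp = soma, t0 = onset, t1 = duration,
                            amp_nA = amp_nA),
    duration = duration, v_init = model$passive$e_leak)
  spk <- detect_spikes(sim)
  post <- spike_train(spk$times[spk$times > onset], onset, duration)
  dec <- burst_decompose(post)
  nb <- nrow(dec$bursts)
  list(burst_count = nb,
       mean_t_burst = if (nb >= 2) mean(head(dec$t_burst, 5)) else NA_real_,
       decomposition = dec,
       sequence_duration = if (nb >= 1)
         dec$bursts$last[nb] - dec$bursts$first[1] else NA_real_,
       spikes = spk, sim = sim)
}

#' Selective-bias sweep emulating the field-equivalent polarization
#'
#' For each field intensity the equivalent somatic bias
#' `V_bias = -0.215 * E / 1.5` mV (the polarization the field imposes on
#' the somatic channels; anodal, negative `E`, depolarises) is applied at
#' the chosen scope with no field, and the chosen experiment is re-run.
#'
#' @param model the PC model
#' @param scope `"soma"` (compartment scope), or a character vector of
#'   channel names (channel scope, e.g. `"NaV1.6_soma"`)
#' @param experiment `"cs"` (silence period) or `"burst"`
#' @param intensities field grid, V/m
#' @param ... passed to the experiment runner
#' @return data.frame with `E`, `v_bias` and the experiment's headline
#'   metric
#' @export
exp_vbias_sweep <- function(model, scope = "soma", experiment = c("cs", "burst"),
                            intensities = seq(-1.5, 1.5, length.out = 13),
                            ...) {
  experiment <- match.arg(experiment)
  soma <- soma_index(model)
  rows <- lapply(intensities, function(E) {
    vb <- -0.215 * E / 1.5
    b <- if (E == 0) NULL
         else if (identical(scope, "soma")) bias_spec(vb, compartments = soma)
         else bias_spec(vb, channels = scope)
    if (experiment == "cs") {
      r <- exp_pc_cs(model, bias = b, ...)
      data.frame(E = E, v_bias = vb, t_sp = r$t_sp)
    } else {
      r <- exp_pc_burst(model, bias = b, ...)
      data.frame(E = E, v_bias = vb, burst_count = r$burst_count,
                 mean_t_burst = r$mean_t_burst)
    }
  })
  do.call(rbind, rows)
}

#' Spatial-mapping experiment on synthetic geometry
#'
#' Generates the folded cortical shell and its point-source field, extracts
#' the iso-surface, projects the field onto the Purkinje axes, and maps the
#' supplied sensitivity curves.
#'
#' @param curves named list of sensitivity curves (see
#'   [build_sensitivity_curve()] / [sensitivity_curve()])
#' @param shell_spec a [cortical_shell_spec()]
#' @param electrodes electrode table (default [default_electrodes()])
#' @return list with `grid`, `surface`, `projections`, `maps` (named list
#'   of `ctdcs_metric_map`), `summaries`
#' @export
exp_spatial_map <- function(curves, shell_spec = cortical_shell_spec(),
                            electrodes = NULL) {
  grid <- gen_folded_cortex(shell_spec)
  if (is.null(electrodes)) electrodes <- default_electrodes(grid)
  grid <- gen_voxel_field(grid, electrodes)
  surf <- extract_surface(grid)
  proj <- project_field(surf, grid)
  maps <- lapply(curves, function(cv) map_metric(proj, cv))
  list(grid = grid, surface = surf, projections = proj, maps = maps,
       summaries = lapply(maps, summarize_map))
}

#' Run a named experiment from a config list
#'
#' `config` is a hierarchical key-value list: `experiment` (one of
#' polarization, tonic_rate, dcn_rebound, grc_fi, grc_relay, pc_td, pc_prc,
#' pc_scenario3, pc_cs, pc_burst, vbias_sweep, spatial_map), `cell`
#' (defaults to the experiment's natural cell), `params` (passed to the
#' runner) and optionally `out_dir` for CSV outputs plus a JSON-like run
#' manifest. Identical configs produce identical outputs.
#'
#' @param config config list (or a path to a YAML file if the yaml package
#'   is installed)
#' @return the runner's result, invisibly when writing outputs
#' @export
run_experiment <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  exp <- config$experiment
  if (is.null(exp)) stop("config error: missing key 'experiment'")
  cell <- config$cell
  if (is.null(cell))
    cell <- switch(exp, dcn_rebound = "DCN", grc_fi = "GrC", grc_relay = "GrC",
                   spatial_map = "PC", "PC")
  model <- default_model(cell)
  params <- config$params
  if (is.null(params)) params <- list()
  res <- switch(exp,
    polarization = do.call(exp_polarization, c(list(model), params)),
    tonic_rate = do.call(exp_tonic_rate, c(list(model), params)),
    dcn_rebound = do.call(exp_dcn_rebound, c(list(model), params)),
    grc_fi = do.call(fi_curve, c(list(model), params)),
    grc_relay = do.call(exp_grc_relay, c(list(model), params)),
    pc_td = do.call(exp_pc_td, c(list(model), params)),
    pc_prc = do.call(exp_pc_prc, c(list(model), params)),
    pc_scenario3 = do.call(exp_pc_scenario3, c(list(model), params)),
    pc_cs = do.call(exp_pc_cs, c(list(model), params)),
    pc_burst = do.call(exp_pc_burst, c(list(model), params)),
    vbias_sweep = do.call(exp_vbias_sweep, c(list(model), params)),
    spatial_map = do.call(exp_spatial_map, params),
    stop("config error: unknown experiment '", exp, "'"))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tab <- if (is.data.frame(res)) res
           else if (!is.null(res$per_seed)) res$per_seed
           else NULL
    if (!is.null(tab))
      write.csv(tab, file.path(config$out_dir, paste0(exp, ".csv")),
                row.names = FALSE)
    manifest <- list(experiment = exp, cell = cell, params = params,
                     dt = 0.025, package_version = "0.1.0",
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    writeLines(paste0("{", paste(sprintf('"%s": "%s"', names(manifest),
                                         vapply(manifest, function(x)
                                           paste(deparse(x), collapse = " "), "")),
                                 collapse = ", "), "}"),
               file.path(config$out_dir, paste0(exp, "_manifest.json")))
    return(invisible(res))
  }
  res
}
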