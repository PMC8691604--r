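# Synaptic kernels, pulse-train generators, and the drive configurations
# used by the experiments.

#' Normalisation constant of the difference-of-exponentials kernel
#'
#' `alpha(z) = A (exp(-z/tau2) - exp(-z/tau1))` peaks at
#' `z* = tau1 tau2 / (tau2 - tau1) * log(tau2/tau1)`; `A` is chosen so the
#' peak value is 1.
#'
#' @param tau1 rise time constant, ms (`0 < tau1 < tau2`)
#' @param tau2 decay time constant, ms
#' @return the constant `A`
#' @export
alpha_norm <- function(tau1, tau2) {
  if (!(tau1 > 0 && tau2 > tau1)) stop("need 0 < tau1 < tau2")
  zstar <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  1 / (exp(-zstar / tau2) - exp(-zstar / tau1))
}

#' Normalised synaptic activation kernel
#'
#' Returns the function `alpha(z)` with unit peak, zero for `z <= 0`.
#'
#' @inheritParams alpha_norm
#' @return vectorised function of the lag `z` (ms)
#' @export
alpha_kernel <- function(tau1, tau2) {
  A <- alpha_norm(tau1, tau2)
  function(z) ifelse(z > 0, A * (exp(-z / tau2) - exp(-z / tau1)), 0)
}

#' Synapse specification
#'
#' @param g_syn maximum conductance, uS
#' @param tau1,tau2 kernel time constants, ms
#' @param e_syn reversal potential, mV
#' @param target compartment id the synapse attaches to
#' @param label transmitter label (free-form, e.g. "AMPA", "GABA")
#' @export
synapse_spec <- function(g_syn, tau1, tau2, e_syn, target, label = "glut") {
  stopifnot(g_syn >= 0, tau1 > 0, tau2 > tau1, is.finite(e_syn), target >= 1)
  structure(list(g_syn = g_syn, tau1 = tau1, tau2 = tau2, e_syn = e_syn,
                 target = as.integer(target), label = label),
            class = "ctdcs_synapse")
}

#' Presynaptic pulse train
#'
#' @param times sorted arrival times, ms (all `>= 0`, strictly increasing)
#' @param meta generator metadata (lambda, t_r, f_stim, seed, ...)
#' @export
pulse_train <- function(times, meta = list()) {
  times <- as.numeric(times)
  if (length(times)) {
    if (any(times < 0)) stop("pulse times must be non-negative")
    if (any(diff(times) <= 0)) stop("pulse times must be strictly increasing")
  }
  structure(list(times = times, meta = meta), class = "ctdcs_pulse_train")
}

#' Drive configuration
#'
#' A set of (synapse, pulse train) pairs plus the common gain offset
#' `delta_syn`: every conductance is applied as `(1 + delta_syn) * g_syn`.
#'
#' @param synapses list of `list(spec = synapse_spec, train = pulse_train)`
#' @param delta_syn dimensionless gain offset, `> -1` (experiments use
#'   -0.6..+0.6)
#' @export
drive_config <- function(synapses, delta_syn = 0) {
  stopifnot(delta_syn > -1)
  for (s in synapses) {
    stopifnot(inherits(s$spec, "ctdcs_synapse"),
              inherits(s$train, "ctdcs_pulse_train"))
  }
  structure(list(synapses = synapses, delta_syn = delta_syn),
            class = "ctdcs_drive")
}

#' @export
print.ctdcs_drive <- function(x, ...) {
  nev <- sum(vapply(x$synapses, function(s) length(s$train$times), 0))
  cat(sprintf("Drive: %d synapses, %d presynaptic events, delta_syn = %+.2f\n",
              length(x$synapses), nev, x$delta_syn))
  invisible(x)
}

#' Synaptic current of one synapse for a given voltage trace
#'
#' `I(t) = g_syn * sum_r alpha(t - tau_r) * (V - E_syn)` in nA
#' (uS times mV); positive values are outward.
#'
#' @param spec a [synapse_spec()]
#' @param train a [pulse_train()]
#' @param v membrane potential, mV: a scalar (voltage clamp) or a vector
#'   aligned with `time`
#' @param time evaluation grid, ms
#' @return current at `time`, nA
#' @export
syn_current <- function(spec, train, v, time) {
  a <- alpha_kernel(spec$tau1, spec$tau2)
  g <- numeric(length(time))
  for (tau in train$times) g <- g + a(time - tau)
  spec$g_syn * g * (v - spec$e_syn)
}

#' Compound synaptic current of mixed excitatory/inhibitory populations
#'
#' The combined drive diagnostic used for whole-population inputs:
#' glutamatergic minus GABAergic contributions,
#' `I(t) = sum_j g_glut sum_r alpha(t - tau) (V - E_glut)
#'        - sum_k g_GABA sum_r alpha(t - tau) (V - E_GABA)`.
#' Additive over synapses: it equals the signed sum of [syn_current()] calls.
#'
#' @param glut_set,gaba_set lists of `list(spec, train)` pairs (may be empty)
#' @param v membrane potential (scalar or vector aligned with `time`), mV
#' @param time evaluation grid, ms
#' @param delta_syn gain offset applied to every conductance
#' @return compound current, nA
#' @export
compound_current <- function(glut_set, gaba_set, v, time, delta_syn = 0) {
  out <- numeric(length(time))
  for (s in glut_set)
    out <- out + (1 + delta_syn) * syn_current(s$spec, s$train, v, time)
  for (s in gaba_set)
    out <- out - (1 + delta_syn) * syn_current(s$spec, s$train, v, time)
  out
}

# evaluate expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Exponentially spaced pulse train
#'
#' Inter-pulse intervals are drawn as `T = t_r + Exp(1/lambda)` (shifted
#' exponential; mean rate `1 / (t_r + lambda)`). The first pulse falls at
#' `start`; pulses strictly before `stop` are kept. Reproducible per seed.
#'
#' @param lambda exponential mean, ms
#' @param t_r refractory offset, ms
#' @param start,stop window, ms
#' @param seed RNG seed for this train
#' @return a [pulse_train()]
#' @export
gen_exp_train <- function(lambda, t_r, start, stop, seed) {
  stopifnot(lambda > 0, t_r >= 0, stop >= start)
  times <- numeric(0)
  if (stop > start) {
    times <- with_seed(seed, {
      block <- ceiling((stop - start) / (t_r + lambda) * 1.5) + 25
      tt <- start + cumsum(c(0, t_r + rexp(block, rate = 1 / lambda)))
      while (tt[length(tt)] < stop)
        tt <- c(tt, tt[length(tt)] +
                  cumsum(t_r + rexp(block, rate = 1 / lambda)))
      tt[tt < stop]
    })
  }
  pulse_train(times, meta = list(lambda = lambda, t_r = t_r, seed = seed))
}

#' Regular pulse train
#'
#' @param f_stim stimulation frequency, Hz
#' @param start,stop window, ms; first pulse at `start`
#' @export
gen_regular_train <- function(f_stim, start, stop) {
  stopifnot(f_stim > 0, stop >= start)
  pulse_train(seq(start, stop - 1e-9, by = 1000 / f_stim),
              meta = list(f_stim = f_stim))
}

# deepest dendritic compartment by path length from the soma
most_distal_dendrite <- function(model) {
  df <- model$morph$compartments
  pd <- morph_path_dist(model$morph)
  dend <- which(df$section == "dendrite")
  dend[which.max(pd[dend])]
}

# cumulative path distance (um) from the soma along the tree (to midpoints)
morph_path_dist <- function(morph) {
  df <- morph$compartments
  n <- nrow(df)
  d <- numeric(n)
  for (i in seq_len(n)) {
    p <- df$parent[i]
    d[i] <- if (p == 0) df$L[i] / 2 else d[p] + df$L[p] / 2 + df$L[i] / 2
  }
  soma <- which(df$section == "soma")[1]
  d - d[soma]
}

#' Drive configurations for the named experiments
#'
#' Builds the complete synaptic drive for one of the stock experiments:
#' \describe{
#' \item{`dcn_inhibition`}{450 GABAergic synapses on the DCN model (one per
#'   dendritic compartment plus 50 on the soma), `g = 1.89e-3` uS,
#'   `tau1 = 0.18`, `tau2 = 3.61` ms, `E = -90` mV, all driven by one common
#'   complex-spike-like train (`lambda = 2`, `t_r = 2` ms) starting at 300 ms
#'   and spanning 15 ms.}
#' \item{`grc_mf`}{one AMPA (2.88e-3 uS) plus one NMDA (4.51e-4 uS) synapse
#'   (`tau1 = 0.6`, `tau2 = 1.0` ms, `E = 0`) on the most distal compartment
#'   of the longest dendritic branch, driven by a regular train at `f_stim`.}
#' \item{`pc_scenario2`}{one glutamatergic synapse (6.014e-3 uS) at the most
#'   distal dendritic compartment, Poisson-like train with `lambda = 50` ms.}
#' \item{`pc_scenario3`}{1,000 glutamatergic (`lambda = 100` ms) and 100
#'   GABAergic (`lambda = 35.7` ms) synapses on randomly selected,
#'   non-overlapping dendritic compartments at baseline conductances
#'   2.5e-4 and 1e-3 uS, scaled by `delta_syn`.}
#' \item{`pc_cf`}{climbing-fibre drive: glutamatergic synapses
#'   (1.59e-3 uS, `tau1 = 0.3`, `tau2 = 3.0` ms) on every dendritic
#'   compartment with diameter >= 3.5 um, one common pulse.}
#' }
#'
#' @param kind experiment name (see Details)
#' @param model the target `ctdcs_neuron_model`
#' @param seed seed for the stochastic trains and placements
#' @param stop end of the drive window, ms (defaults per kind)
#' @param delta_syn gain offset stored in the returned config
#' @param f_stim regular-train frequency (Hz) for `grc_mf`
#' @param pulse_time common pulse time (ms) for `pc_cf`
#' @return a [drive_config()]
#' @export
gen_scenario_drives <- function(kind, model, seed = 1, stop = NULL,
                                delta_syn = 0, f_stim = 20, pulse_time = 500) {
  df <- model$morph$compartments
  dend <- which(df$section == "dendrite")
  soma <- soma_index(model)
  syn <- switch(kind,
    dcn_inhibition = {
      train <- gen_exp_train(lambda = 2, t_r = 2, start = 300, stop = 315,
                             seed = seed)
      targets <- c(dend, rep(soma, 50))
      if (length(dend) + 50 != 450)
        stop("dcn_inhibition expects 400 dendritic compartments (got ",
             length(dend), ")")
      lapply(targets, function(cp) list(
        spec = synapse_spec(1.89e-3, 0.18, 3.61, -90, cp, "GABA"),
        train = train))
    },
    grc_mf = {
      if (is.null(stop)) stop <- 2300
      cp <- most_distal_dendrite(model)
      train <- gen_regular_train(f_stim, start = 100, stop = stop)
      list(list(spec = synapse_spec(2.88e-3, 0.6, 1.0, 0, cp, "AMPA"),
                train = train),
           list(spec = synapse_spec(4.51e-4, 0.6, 1.0, 0, cp, "NMDA"),
                train = train))
    },
    pc_scenario2 = {
      if (is.null(stop)) stop <- 100000
      cp <- most_distal_dendrite(model)
      train <- gen_exp_train(lambda = 50, t_r = 0, start = 2000, stop = stop,
                             seed = seed)
      list(list(spec = synapse_spec(6.014e-3, 0.6, 1.0, 0, cp, "glut"),
                train = train))
    },
    pc_scenario3 = {
      if (is.null(stop)) stop <- 10000
      n_glut <- 1000; n_gaba <- 100
      if (length(dend) < n_glut + n_gaba)
        stop("fewer eligible dendritic compartments (", length(dend),
             ") than synapses (", n_glut + n_gaba, ")")
      with_seed(seed, {
        picks <- sample(dend, n_glut + n_gaba)
        gl <- lapply(seq_len(n_glut), function(j) list(
          spec = synapse_spec(2.5e-4, 0.6, 1.0, 0, picks[j], "glut"),
          train = gen_exp_train(100, 0, 0, stop, seed = sample.int(2^31 - 1, 1))))
        gb <- lapply(seq_len(n_gaba), function(k) list(
          spec = synapse_spec(1e-3, 1.0, 5.0, -80, picks[n_glut + k], "GABA"),
          train = gen_exp_train(35.7, 0, 0, stop, seed = sample.int(2^31 - 1, 1))))
        c(gl, gb)
      })
    },
    pc_cf = {
      thick <- dend[df$diam[dend] >= 3.5]
      if (!length(thick)) stop("no dendritic compartments with diameter >= 3.5 um")
      train <- pulse_train(pulse_time)
      lapply(thick, function(cp) list(
        spec = synapse_spec(1.59e-3, 0.3, 3.0, 0, cp, "glut"),
        train = train))
    },
    stop("unknown drive kind: ", kind)
  )
  drive_config(syn, delta_syn = delta_syn)
}

#' Export a drive configuration's pulse trains as two-column CSV
#'
#' One row per presynaptic event: synapse id and arrival time (ms).
#' @param drive a [drive_config()]
#' @param path output file
#' @export
write_drive_csv <- function(drive, path) {
  rows <- do.call(rbind, lapply(seq_along(drive$synapses), function(i) {
    tt <- drive$synapses[[i]]$train$times
    if (!length(tt)) return(NULL)
    data.frame(synapse = i, time_ms = tt)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
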