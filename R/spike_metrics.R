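# Spike-train statistics and response metrics.

#' Spike train
#'
#' @param times strictly increasing spike times, ms
#' @param t0,t1 recording window, ms (times must fall inside)
#' @export
spike_train <- function(times, t0, t1) {
  times <- as.numeric(times)
  stopifnot(t1 > t0)
  if (length(times)) {
    if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
    if (min(times) < t0 || max(times) > t1)
      stop("spike times outside the recording window")
  }
  structure(list(times = times, t0 = t0, t1 = t1), class = "ctdcs_spikes")
}

#' @export
print.ctdcs_spikes <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Spike train: %d spikes in [%.0f, %.0f] ms (%.2f Hz)\n",
              n, x$t0, x$t1, 1000 * n / (x$t1 - x$t0)))
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings on a uniform time grid, at most one spike per
#' refractory window; the spike time is the crossing sample.
#'
#' @param sim a `ctdcs_sim`, or a numeric voltage trace (then give `time`)
#' @param threshold detection threshold, mV (default 0)
#' @param refractory minimum separation between detections, ms (default 1)
#' @param comp column of the trace to use when `sim` is a `ctdcs_sim`
#' @param time time grid (ms) when `sim` is a plain vector
#' @return a [spike_train()]
#' @export
detect_spikes <- function(sim, threshold = 0, refractory = 1, comp = 1,
                          time = NULL) {
  if (inherits(sim, "ctdcs_sim")) {
    v <- sim$v[, comp]
    time <- sim$time
  } else {
    v <- as.numeric(sim)
    if (is.null(time)) stop("give a time grid for a plain voltage vector")
  }
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (length(up) > 1) {
    keep <- c(TRUE, diff(time[up]) > refractory)
    # enforce the refractory window sequentially
    last <- time[up[1]]
    for (i in seq_along(up)[-1]) {
      keep[i] <- (time[up[i]] - last) > refractory
      if (keep[i]) last <- time[up[i]]
    }
    up <- up[keep]
  }
  spike_train(time[up], t0 = time[1], t1 = time[length(time)])
}

#' Coefficient of variation of the inter-spike intervals
#'
#' S.D. over mean of the ISIs; undefined (NA) for fewer than 3 spikes.
#'
#' @param train a [spike_train()]
#' @export
isi_cov <- function(train) {
  if (length(train$times) < 3) return(NA_real_)
  isi <- diff(train$times)
  sd(isi) / mean(isi)
}

#' Classify a discharge pattern
#'
#' Four-way rule classification of the somatic firing pattern, evaluated in
#' priority order sparse, bursting, irregular, dense (anything else is
#' unclassified):
#' \itemize{
#' \item sparse: a silent period exceeding 3,000 ms (including the tail of
#'   the recording window) and ISI CoV, if defined, above 3;
#' \item bursting: maximum ISI above 200 ms and CoV above 2;
#' \item irregular: maximum ISI between 80 and 200 ms and CoV between
#'   0.5 and 2;
#' \item dense: all ISIs below 80 ms and CoV below 0.5.
#' }
#'
#' @param train a [spike_train()]
#' @return one of `"dense"`, `"irregular"`, `"bursting"`, `"sparse"`,
#'   `"unclassified"`
#' @export
classify_pattern <- function(train) {
  tt <- train$times
  cov <- isi_cov(train)
  if (length(tt) == 0)
    return(if (train$t1 - train$t0 > 3000) "sparse" else "unclassified")
  gaps <- c(diff(tt), train$t1 - tt[length(tt)])
  max_silence <- max(gaps)
  max_isi <- if (length(tt) >= 2) max(diff(tt)) else NA_real_
  if (max_silence > 3000 && (is.na(cov) || cov > 3)) return("sparse")
  if (!is.na(max_isi) && !is.na(cov)) {
    if (max_isi > 200 && cov > 2) return("bursting")
    if (max_isi > 80 && max_isi <= 200 && cov > 0.5 && cov <= 2)
      return("irregular")
    if (max_isi < 80 && cov < 0.5) return("dense")
  }
  "unclassified"
}

#' Instantaneous firing rate by adaptive Gaussian kernel convolution
#'
#' Each spike contributes a Gaussian kernel integrating to one spike, with a
#' spike-specific width `sigma_k = min(ISI_before, ISI_after) / divisor`
#' (edge spikes use their single neighbouring ISI). The default divisor is
#' `sqrt(2*pi)`, exposed as an argument.
#'
#' @param train a [spike_train()] with at least 3 spikes
#' @param divisor kernel-width divisor (default `sqrt(2*pi)`)
#' @return a function of time (ms) returning the rate in Hz
#' @export
ifr_trace <- function(train, divisor = sqrt(2 * pi)) {
  tt <- train$times
  if (length(tt) < 3) stop("IFR needs at least 3 spikes")
  isi <- diff(tt)
  before <- c(isi[1], isi)
  after <- c(isi, isi[length(isi)])
  sig <- pmin(before, after) / divisor
  function(t) {
    out <- numeric(length(t))
    for (k in seq_along(tt))
      out <- out + stats::dnorm(t, mean = tt[k], sd = sig[k])
    out * 1000  # spikes/ms -> Hz
  }
}

#' Transmission delay from a stimulus to the first somatic spike
#'
#' @param stim_time stimulus time, ms
#' @param train somatic [spike_train()]
#' @param window maximum latency considered, ms
#' @return delay in ms, or `NA` if no spike follows within the window
#' @export
transmission_delay <- function(stim_time, train, window = Inf) {
  post <- train$times[train$times > stim_time &
                      train$times <= stim_time + window]
  if (!length(post)) return(NA_real_)
  post[1] - stim_time
}

#' Silence period following a complex spike
#'
#' Interval from the complex-spike peak to the first simple spike after the
#' post-CS hyperpolarisation. Spikes within `min_gap` ms of the peak are
#' treated as CS spikelets and excluded.
#'
#' @param train somatic [spike_train()]
#' @param cs_peak_time time of the largest-amplitude peak of the complex
#'   spike, ms (see [cs_peak_time()])
#' @param min_gap spikelet exclusion window after the peak, ms (default 40,
#'   wide enough to cover the full spikelet envelope of the reduced model's
#'   complex spike)
#' @return silence period in ms, or `NA` if no simple spike follows within
#'   the recording
#' @export
silence_period <- function(train, cs_peak_time, min_gap = 40) {
  if (is.null(cs_peak_time) || is.na(cs_peak_time))
    stop("no complex-spike marker: cs_peak_time is required")
  post <- train$times[train$times > cs_peak_time + min_gap]
  if (!length(post)) return(NA_real_)
  post[1] - cs_peak_time
}

#' Time of the complex-spike peak
#'
#' The maximum-amplitude point of the voltage trace inside the complex-spike
#' window following the climbing-fibre pulse.
#'
#' @param sim a `ctdcs_sim` (somatic trace in column 1)
#' @param pulse_time climbing-fibre pulse time, ms
#' @param window CS window length after the pulse, ms (default 15, the
#'   typical duration of a complex spike)
#' @export
cs_peak_time <- function(sim, pulse_time, window = 15) {
  sel <- sim$time >= pulse_time & sim$time <= pulse_time + window
  if (!any(sel)) stop("pulse window outside the recording")
  sim$time[sel][which.max(sim$v[sel, 1])]
}

#' Burst decomposition of a spike train
#'
#' A burst is a maximal run of spikes with consecutive ISIs below `gap` ms
#' (runs shorter than `min_spikes` are not counted as bursts). For burst `k`
#' the burst period is `T_burst(k) = last(k+1) - last(k)`, the burst interval
#' `T_intv(k) = first(k+1) - last(k)` and the spiking period
#' `T_spike(k) = last(k) - first(k)`, so that
#' `T_burst(k) = T_intv(k) + T_spike(k+1)`.
#'
#' @param train a [spike_train()]
#' @param gap intra-burst ISI bound, ms (default 10)
#' @param min_spikes minimum spikes per burst (default 2)
#' @return list with `bursts` (data.frame: first, last, n), `t_burst`,
#'   `t_intv` (length `n_bursts - 1`) and `t_spike` (length `n_bursts`)
#' @export
burst_decompose <- function(train, gap = 10, min_spikes = 2) {
  tt <- train$times
  if (!length(tt))
    return(list(bursts = data.frame(first = numeric(0), last = numeric(0),
                                    n = integer(0)),
                t_burst = numeric(0), t_intv = numeric(0),
                t_spike = numeric(0)))
  brk <- c(0, which(diff(tt) >= gap), length(tt))
  first <- tt[brk[-length(brk)] + 1]
  last <- tt[brk[-1]]
  n <- diff(brk)
  keep <- n >= min_spikes
  first <- first[keep]; last <- last[keep]; n <- n[keep]
  k <- length(first)
  list(bursts = data.frame(first = first, last = last, n = as.integer(n)),
       t_burst = if (k >= 2) diff(last) else numeric(0),
       t_intv = if (k >= 2) first[-1] - last[-k] else numeric(0),
       t_spike = last - first)
}

#' Relay fidelity of a cell to a stimulus train
#'
#' Ratio between output spikes and stimulus pulses inside the analysis
#' window (the final `window` ms of the stimulus train's recording window).
#'
#' @param soma_train output [spike_train()]
#' @param stim_train stimulus [pulse_train()] or [spike_train()]
#' @param window analysis window length, ms (default 2000)
#' @export
relay_fidelity <- function(soma_train, stim_train, window = 2000) {
  stim <- if (inherits(stim_train, "ctdcs_pulse_train")) stim_train$times
          else stim_train$times
  if (!length(stim)) stop("empty stimulus train")
  t1 <- soma_train$t1
  t0 <- t1 - window
  np <- sum(stim >= t0 & stim <= t1)
  if (np == 0) stop("no stimulus pulses inside the analysis window")
  ns <- sum(soma_train$times >= t0 & soma_train$times <= t1)
  ns / np
}

#' Phase-response curve from perturbed oscillator spike times
#'
#' For every perturbation falling inside an inter-spike interval, the
#' stimulus phase is `phi = (t_stim - t_prev) / T` and the normalised phase
#' shift `(T - ISI_perturbed) / T`, with `T` the unperturbed oscillation
#' period. Shifts are averaged in `nbins` equal phase bins.
#'
#' @param spike_train a [spike_train()] of the oscillator
#' @param perturbation_train a [pulse_train()] of perturbation times
#' @param mean_period unperturbed period, ms; default: median ISI
#' @param nbins number of phase bins (default 20)
#' @return data.frame with `phase` (bin centre, 0..1), `shift` (mean
#'   normalised phase advance; positive = earlier next spike) and `n`;
#'   attribute `low_n = TRUE` flags fewer than 100 usable perturbations
#' @export
estimate_prc <- function(spike_train, perturbation_train, mean_period = NULL,
                         nbins = 20) {
  tt <- spike_train$times
  pp <- perturbation_train$times
  if (length(tt) < 3) stop("too few spikes for PRC estimation")
  if (is.null(mean_period)) mean_period <- median(diff(tt))
  idx <- findInterval(pp, tt)
  use <- idx >= 1 & idx < length(tt)
  phi <- (pp[use] - tt[idx[use]]) / mean_period
  isi_p <- tt[idx[use] + 1] - tt[idx[use]]
  shift <- (mean_period - isi_p) / mean_period
  ok <- phi >= 0 & phi < 1
  phi <- phi[ok]; shift <- shift[ok]
  bins <- cut(phi, breaks = seq(0, 1, length.out = nbins + 1),
              include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    phase = (seq_len(nbins) - 0.5) / nbins,
    shift = vapply(seq_len(nbins),
                   function(b) if (any(bins == b)) mean(shift[bins == b]) else NA_real_,
                   0),
    n = vapply(seq_len(nbins), function(b) sum(bins == b), 0L))
  attr(out, "low_n") <- length(phi) < 100
  out
}

#' Zero-phase low-pass filter for compound synaptic currents
#'
#' 5th-order Butterworth low-pass (default cutoff 30 Hz) applied
#' forward-backward for zero phase shift.
#'
#' @param i current trace on a uniform grid
#' @param dt sampling step, ms
#' @param cutoff cutoff frequency, Hz (default 30)
#' @param order filter order (default 5)
#' @export
filter_compound_current <- function(i, dt, cutoff = 30, order = 5) {
  fs <- 1000 / dt
  if (fs < 2 * cutoff) stop("sampling rate below twice the cutoff frequency")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, i))
}

# trapezoid integral of y(t) over [t_start, t_end]
trapz_window <- function(time, y, t_start, t_end) {
  sel <- time >= t_start & time <= t_end
  t <- time[sel]; yy <- y[sel]
  sum(diff(t) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Charge-density difference between two field conditions
#'
#' Absolute difference of the time integral of each ionic current density
#' between two conditions, over a common window (the interval from the end
#' of the complex spike to the end of the shortest silence period).
#'
#' @param time common time grid, ms
#' @param currents_a,currents_b current-density traces (mA/cm^2), matrices
#'   with one column per channel class, identical grids
#' @param t_start,t_end integration window, ms
#' @return named vector of `delta_c` per channel class (uC/cm^2 after
#'   ms * mA/cm^2 scaling by 1e-3)
#' @export
charge_density_delta <- function(time, currents_a, currents_b, t_start, t_end) {
  currents_a <- as.matrix(currents_a)
  currents_b <- as.matrix(currents_b)
  if (!identical(dim(currents_a), dim(currents_b)))
    stop("mismatched trace grids between the two conditions")
  out <- vapply(seq_len(ncol(currents_a)), function(j) {
    abs(trapz_window(time, currents_a[, j], t_start, t_end) -
        trapz_window(time, currents_b[, j], t_start, t_end))
  }, 0) * 1e-3
  names(out) <- colnames(currents_a)
  out
}

#' Mean firing rate over a window
#'
#' @param train a [spike_train()]
#' @param t0,t1 analysis window, ms (defaults to the recording window)
#' @return rate in Hz
#' @export
firing_rate <- function(train, t0 = train$t0, t1 = train$t1) {
  1000 * sum(train$times >= t0 & train$times <= t1) / (t1 - t0)
}

#' Export a spike train as single-column CSV
#' @param train a [spike_train()]
#' @param path output file
#' @export
write_spikes_csv <- function(train, path) {
  write.csv(data.frame(time_ms = train$times), path, row.names = FALSE)
  invisible(path)
}
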