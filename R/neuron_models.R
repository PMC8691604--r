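# Cerebellar neuron models: a 65-compartment granule cell built from the
# section/channel tables, and reduced Purkinje / deep-cerebellar-nucleus
# stand-ins calibrated against the printed single-cell baselines (tonic
# rate, somatic polarization, transmission delay, post-CS silence, transient
# bursting).

# ---------------------------------------------------------------------------
# Granule cell ---------------------------------------------------------------

#' Granule cell section table
#'
#' Per-section geometry and passive properties of the 65-compartment GrC
#' model: soma, 25 dendritic compartments (total tree length 158.6 um),
#' 5 hillock compartments, 30 identical axon-initial-segment compartments
#' (total 70.1 um) and 4 ascending-axon compartments (total 218.0 um), with
#' the axon perpendicular to the somato-dendritic plane. Diameters are
#' synthetic values consistent with the printed totals.
#'
#' @return data.frame with columns section, n_comp, total_length_um,
#'   diam_um, taper_to_um, cm_uF_cm2, ra_ohm_cm
#' @export
grc_section_table <- function() {
  data.frame(
    section = c("soma", "dendrite", "hillock", "AIS", "axon"),
    n_comp = c(1L, 25L, 5L, 30L, 4L),
    total_length_um = c(5.9, 158.6, 5.0, 70.1, 218.0),
    diam_um = c(5.9, 0.75, 2.3, 0.7, 1.0),
    taper_to_um = c(NA, NA, 0.7, NA, NA),
    cm_uF_cm2 = c(1, 1, 1, 1, 1),
    ra_ohm_cm = c(100, 100, 100, 100, 100),
    stringsAsFactors = FALSE)
}

#' Granule cell channel table
#'
#' Ionic mechanisms per location: maximum conductance densities (S/cm^2)
#' and reversal potentials (mV). Channel kinetics use standard
#' Hodgkin-Huxley formulations; densities are calibrated so the model is
#' silent at rest, has a current-density threshold near 8 uA/cm^2, and
#' relays low-frequency mossy-fibre input one-to-one while adapting above
#' 40 Hz.
#'
#' @return data.frame with columns channel, location, gmax_S_cm2, erev_mV
#' @export
grc_channel_table <- function() {
  data.frame(
    channel = c("GrC_NaF", "GrC_NaF", "GrC_NaF",
                "GrC_Kdr", "GrC_Kdr", "GrC_Kdr",
                "GrC_KA", "GrC_Kir", "GrC_KCa", "GrC_Ca"),
    location = c("soma", "hillock", "AIS",
                 "soma", "hillock", "AIS",
                 "soma", "soma", "soma", "soma"),
    gmax_S_cm2 = c(0.02, 0.08, 1.6,
                   0.012, 0.03, 0.15,
                   0.004, 1e-4, 0.004, 4e-4),
    erev_mV = c(60, 60, 60, -85, -85, -85, -85, -85, -85, 120),
    stringsAsFactors = FALSE)
}

grc_kinetics <- function(name, sections, gmax, erev) {
  switch(name,
    GrC_NaF = channel(name, sections, gmax, erev, gates = list(
      gate_v(3, vh = -46, k = 5.5, tau0 = 0.05, amp = 0.12, vd = -36, s1 = 12, s2 = 12),
      # fast inactivation accommodates slow depolarising ramps, setting the
      # current-density threshold while sparing brief mossy-fibre EPSPs
      gate_v(1, vh = -60, k = -4, tau0 = 5),
      # slow inactivation: recovery is slow at rest and accrual fast during
      # spikes, which produces the relay-fidelity adaptation above ~50 Hz
      gate_v(1, vh = -45, k = -4.5, tau0 = 25, amp = 600, vd = -85,
             s1 = 12, s2 = 200))),
    GrC_Kdr = channel(name, sections, gmax, erev, gates = list(
      gate_v(4, vh = -38, k = 8, tau0 = 0.5, amp = 3.5, vd = -45, s1 = 18, s2 = 18))),
    GrC_KA = channel(name, sections, gmax, erev, gates = list(
      gate_v(3, vh = -40, k = 10, tau0 = 0.5, amp = 2, vd = -45, s1 = 20, s2 = 20),
      gate_v(1, vh = -69, k = -7, tau0 = 15))),
    GrC_Kir = channel(name, sections, gmax, erev, gates = list(
      gate_v(1, vh = -85, k = -20, tau0 = 5))),
    GrC_KCa = channel(name, sections, gmax, erev,
      gates = list(gate_ca(1, kd = 0.8, hill = 4, tau = 5)),
      reads_pool = "ca"),
    GrC_Ca = channel(name, sections, gmax, erev, gates = list(
      gate_v(2, vh = -30, k = 6, tau0 = 1)),
      ca_pool = "ca"),
    stop("no kinetics defined for channel ", name))
}

#' Build the granule cell model
#'
#' Assembles the 65-compartment GrC from the section and channel tables
#' (defaults: [grc_section_table()], [grc_channel_table()]): a spherical
#' soma, five short dendrites, a tapered hillock, a 30-compartment axon
#' initial segment and a 4-compartment ascending axon perpendicular to the
#' somato-dendritic plane.
#'
#' @param section_table section geometry (see [grc_section_table()])
#' @param channel_table channel placement (see [grc_channel_table()])
#' @return a `ctdcs_neuron_model` with `cell_type = "GrC"`
#' @export
build_grc <- function(section_table = grc_section_table(),
                      channel_table = grc_channel_table()) {
  st <- section_table
  rownames(st) <- st$section
  for (s in c("soma", "dendrite", "hillock", "AIS", "axon"))
    if (!s %in% st$section) stop("section table is missing row: ", s)
  soma_d <- st["soma", "diam_um"]
  rows <- list(data.frame(
    id = 1L, parent = 0L, x0 = 0, y0 = 0, z0 = -soma_d / 2,
    x1 = 0, y1 = 0, z1 = soma_d / 2, diam = soma_d,
    section = "soma", region = "soma", stringsAsFactors = FALSE))
  # five dendrites in the lower hemisphere (somato-dendritic side, -z)
  nd <- st["dendrite", "n_comp"]
  if (nd %% 5 != 0) stop("dendrite compartment count must be divisible by 5")
  dirs <- rbind(c(0, 0, -1),
                c(0.5, 0, -0.87), c(-0.5, 0, -0.87),
                c(0, 0.5, -0.87), c(0, -0.5, -0.87))
  br_len <- st["dendrite", "total_length_um"] / 5
  for (b in 1:5) {
    ch <- morph_chain(rows, 1L, c(0, 0, -soma_d / 2), nd / 5, br_len,
                      st["dendrite", "diam_um"], dirs[b, ], "dendrite")
    rows <- ch$rows
  }
  hk <- morph_chain(rows, 1L, c(0, 0, soma_d / 2), st["hillock", "n_comp"],
                    st["hillock", "total_length_um"], st["hillock", "diam_um"],
                    c(0, 0, 1), "hillock",
                    taper_to = st["hillock", "taper_to_um"])
  ais <- morph_chain(hk$rows, hk$ids[length(hk$ids)], hk$end,
                     st["AIS", "n_comp"], st["AIS", "total_length_um"],
                     st["AIS", "diam_um"], c(0, 0, 1), "AIS")
  aa <- morph_chain(ais$rows, ais$ids[length(ais$ids)], ais$end,
                    st["axon", "n_comp"], st["axon", "total_length_um"],
                    st["axon", "diam_um"], c(0, 0, 1), "axon")
  df <- do.call(rbind, aa$rows)
  morph <- morphology(df, axis = c(0, 0, 1))
  if (nrow(df) != 65L)
    stop("GrC construction produced ", nrow(df), " compartments, expected 65")
  ct <- channel_table
  chans <- list()
  for (nm in unique(ct$channel)) {
    sub <- ct[ct$channel == nm, ]
    if (any(is.na(sub$gmax_S_cm2)))
      stop("channel table is missing gmax for row: ", nm)
    # one channel object per (channel, gmax) level; same gmax rows merge
    for (g in unique(sub$gmax_S_cm2)) {
      locs <- sub$location[sub$gmax_S_cm2 == g]
      tag <- if (length(unique(sub$gmax_S_cm2)) > 1)
        paste0(nm, "_", locs[1]) else nm
      chans[[tag]] <- grc_kinetics(nm, locs, g, sub$erev_mV[sub$gmax_S_cm2 == g][1])
      chans[[tag]]$name <- tag
    }
  }
  neuron_model(morph,
               passive = list(cm = st["soma", "cm_uF_cm2"],
                              ra = st["soma", "ra_ohm_cm"],
                              g_leak = 4.2e-4, e_leak = -78,
                              overrides = list(
                                axon = list(g_leak = 1e-3))),
               channels = unname(chans),
               pools = list(ca = ca_pool(tau = 30, k = 2, c0 = 0.05)),
               cell_type = "GrC")
}

# ---------------------------------------------------------------------------
# Reduced Purkinje cell ------------------------------------------------------

#' Default parameters of the reduced Purkinje cell
#'
#' Conductance densities (S/cm^2), passive properties and geometry knobs of
#' [build_reduced_pc()]. These values are the shipped calibration: one fixed
#' set satisfying the tonic-rate, polarization, transmission-delay,
#' silence-period, bursting and polysynaptic-drive baselines simultaneously.
#'
#' @return named list of parameters
#' @export
pc_default_params <- function() {
  list(
    # passive
    cm = 1.0, cm_dend = 0.7, ra = 120, g_leak = 3.5e-5, e_leak = -62,
    g_leak_dend = 2.0e-5, g_leak_axon = 2e-5,
    # geometry
    axon_L = 200, axon_diam = 0.8, axon_n = 8,
    dend_scale = 1.25,
    # soma/AIS spiking engine
    g_naf_soma = 0.045, g_kdr_soma = 0.060,
    g_naf_ais = 0.35, g_kdr_ais = 0.10, g_nap_ais = 5.1e-3,
    # adaptation and bursting
    g_cas_soma = 4e-4, g_sk_soma = 6e-3, g_km_soma = 6e-4,
    # dendritic calcium system (complex-spike machinery)
    g_cap_dend = 2.8e-3, g_skd_dend = 3e-3, cap_vh = -26, skd_kd = 2,
    sk_kd = 0.6, skd_tau = 15,
    # pause system: calcium-gated K on the level-4 dendrites, engaged by
    # outward dendritic calcium waves
    g_skp_dend = 5e-3, skp_kd = 1.5,
    # slow complex-spike calcium system on the thick dendrites: governs the
    # post-CS silence period and, under somatic step drive, the inter-burst
    # intervals of the transient bursting response
    g_cacs = 5e-4, cacs_vh = 8, g_skcs = 5e-3, skcs_kd = 1.5, skcs_hill = 4,
    skcs_tau = 20,
    # slow thick-dendrite calcium drive enabling wave re-ignition under
    # sustained somatic depolarisation
    g_cat = 1.3e-3,
    # pools
    ca_f_tau = 8, ca_f_k = 10, ca_d_tau = 25, ca_d_k = 2,
    ca_s_tau = 140, ca_s_k = 17)
}

pc_dend_levels <- function(scale = 1) {
  # binary tree, splits double per level; the distal (spiny) levels carry
  # most of the membrane area, which places the area centroid distally and
  # sets the cell's polarization length
  data.frame(
    L = scale * c(100, 120, 150, 180, 180, 120),
    nbranch = c(1, 2, 4, 8, 16, 32),
    diam = c(5.5, 4.0, 3.5, 1.5, 1.1, 0.9),
    ncomp = c(12, 15, 18, 22, 22, 15))
}

#' Build the reduced Purkinje cell model
#'
#' A branched stand-in for the full reconstructed Purkinje cell: spherical
#' soma, six-level binary dendritic tree with distally concentrated
#' membrane area (the two proximal levels are thick, diameter >= 3.5 um,
#' and carry the climbing-fibre synapses and the dendritic calcium
#' machinery), an axon initial segment hosting the spike-initiation and
#' pacemaker conductances, and a short axon stub. The distal-heavy tree
#' places the area centroid far from the soma, which sets the calibrated
#' polarization length. Fires tonically at rest; expresses complex-spike
#' bursts with a calcium-dependent silence period, and transient bursting
#' under somatic step depolarisation.
#'
#' @param par parameter list (see [pc_default_params()])
#' @return a `ctdcs_neuron_model` with `cell_type = "PC"`
#' @export
build_reduced_pc <- function(par = pc_default_params()) {
  soma_d <- 25
  rows <- list(data.frame(
    id = 1L, parent = 0L, x0 = 0, y0 = 0, z0 = -soma_d / 2,
    x1 = 0, y1 = 0, z1 = soma_d / 2, diam = soma_d,
    section = "soma", region = "soma", stringsAsFactors = FALSE))
  lv <- pc_dend_levels(par$dend_scale)
  # grow the binary tree level by level; branch directions fan out in -z
  grow <- function(rows, level, from_id, from_xyz, dirvec) {
    if (level > nrow(lv)) return(rows)
    region <- if (lv$diam[level] >= 3.5) "dend_thick"
              else if (level >= 5) "dend_distal" else "dendrite"
    ch <- morph_chain(rows, from_id, from_xyz, lv$ncomp[level], lv$L[level],
                      lv$diam[level], dirvec, "dendrite", region = region)
    rows <- ch$rows
    if (level < nrow(lv)) {
      # two daughters, tilted +-20 degrees around the parent direction
      for (sgn in c(-1, 1)) {
        d <- dirvec + sgn * 0.35 * orthogonal_unit(dirvec) +
          0.1 * sgn * rev(orthogonal_unit(dirvec)) * c(1, -1, 1)
        rows <- grow(rows, level + 1, ch$ids[length(ch$ids)], ch$end,
                     d / sqrt(sum(d^2)))
      }
    }
    rows
  }
  rows <- grow(rows, 1, 1L, c(0, 0, -soma_d / 2), c(0, 0, -1))
  ais <- morph_chain(rows, 1L, c(0, 0, soma_d / 2), 5, 50, 1.5,
                     c(0, 0, 1), "AIS")
  axn <- morph_chain(ais$rows, ais$ids[length(ais$ids)], ais$end,
                     par$axon_n, par$axon_L, par$axon_diam, c(0, 0, 1), "axon")
  morph <- morphology(do.call(rbind, axn$rows), axis = c(0, 0, 1))
  chans <- list(
    channel("NaF", "soma", par$g_naf_soma, 60, gates = list(
      gate_v(3, vh = -33, k = 5.5, tau0 = 0.04, amp = 0.12, vd = -33, s1 = 12, s2 = 12),
      gate_v(1, vh = -48, k = -6, tau0 = 0.4, amp = 5, vd = -52, s1 = 14, s2 = 14))),
    channel("NaV1.6_AIS", "AIS", par$g_naf_ais, 60, gates = list(
      gate_v(3, vh = -38, k = 5.5, tau0 = 0.04, amp = 0.10, vd = -38, s1 = 12, s2 = 12),
      gate_v(1, vh = -52, k = -6, tau0 = 0.4, amp = 5, vd = -56, s1 = 14, s2 = 14))),
    channel("NaP_AIS", "AIS", par$g_nap_ais, 60, gates = list(
      gate_v(1, vh = -54, k = 5, tau0 = 2))),
    channel("Kdr_soma", "soma", par$g_kdr_soma, -85, gates = list(
      gate_v(4, vh = -35, k = 8, tau0 = 0.35, amp = 25, vd = -50, s1 = 8, s2 = 18))),
    channel("Kdr_AIS", "AIS", par$g_kdr_ais, -85, gates = list(
      gate_v(4, vh = -35, k = 8, tau0 = 0.35, amp = 25, vd = -50, s1 = 8, s2 = 18))),
    channel("CaS_soma", "soma", par$g_cas_soma, 120, gates = list(
      gate_v(2, vh = -32, k = 5, tau0 = 1)),
      ca_pool = "ca_f"),
    channel("SK_soma", "soma", par$g_sk_soma, -85,
      gates = list(gate_ca(1, kd = par$sk_kd, hill = 4, tau = 8)),
      reads_pool = "ca_f"),
    channel("KM_soma", "soma", par$g_km_soma, -85, gates = list(
      gate_v(1, vh = -36, k = 6, tau0 = 2000))),
    channel("CaP_dend", c("dendrite", "dend_distal"),
      par$g_cap_dend, 120,
      gates = list(gate_v(2, vh = par$cap_vh, k = 6, tau0 = 0.5)),
      ca_pool = "ca_d"),
    channel("SK_dend", c("dendrite", "dend_distal"),
      par$g_skd_dend, -85,
      gates = list(gate_ca(1, kd = par$skd_kd, hill = 4, tau = par$skd_tau)),
      reads_pool = "ca_d"),
    channel("SKp_dend", "dendrite", par$g_skp_dend, -85,
      gates = list(gate_ca(1, kd = par$skp_kd, hill = 4, tau = 20)),
      reads_pool = "ca_d"),
    # slow, high-threshold calcium on the thick dendrites: loaded by the
    # complex-spike plateau and by step-evoked dendritic calcium events
    channel("CaCS_thick", "dend_thick", par$g_cacs, 120, gates = list(
      gate_v(2, vh = par$cacs_vh, k = 4, tau0 = 8)),
      ca_pool = "ca_s"),
    channel("SKcs_thick", "dend_thick", par$g_skcs, -85,
      gates = list(gate_ca(1, kd = par$skcs_kd, hill = par$skcs_hill,
                           tau = par$skcs_tau)),
      reads_pool = "ca_s"),
    # low-threshold slowly inactivating calcium: under sustained somatic
    # depolarisation it re-ignites dendritic calcium events, pacing the
    # transient bursting sequence
    channel("CaT_thick", "dend_thick", par$g_cat, 120, gates = list(
      gate_v(2, vh = -45, k = 5, tau0 = 10),
      gate_v(1, vh = -50, k = -5, tau0 = 30),
      # slow inactivation, fast to accrue during depolarised events and
      # slow to recover, terminates the transient bursting sequence
      gate_v(1, vh = -52, k = -4, tau0 = 120, amp = 2400, vd = -60,
             s1 = 6, s2 = 500))))
  neuron_model(morph,
               passive = list(cm = par$cm, ra = par$ra,
                              g_leak = par$g_leak, e_leak = par$e_leak,
                              overrides = list(
                                axon = list(g_leak = par$g_leak_axon),
                                dendrite = list(g_leak = par$g_leak_dend,
                                                cm = par$cm_dend),
                                dend_distal = list(g_leak = par$g_leak_dend,
                                                   cm = par$cm_dend),
                                dend_thick = list(g_leak = par$g_leak_dend,
                                                  cm = par$cm_dend))),
               channels = chans,
               pools = list(
                 ca_f = ca_pool(tau = par$ca_f_tau, k = par$ca_f_k),
                 ca_d = ca_pool(tau = par$ca_d_tau, k = par$ca_d_k),
                 ca_s = ca_pool(tau = par$ca_s_tau, k = par$ca_s_k, c0 = 0.02)),
               cell_type = "PC")
}

# ---------------------------------------------------------------------------
# Reduced deep-cerebellar-nucleus neuron ------------------------------------

#' Default parameters of the reduced DCN model
#' @return named list of parameters
#' @export
dcn_default_params <- function() {
  list(
    cm = 1.0, ra = 150, g_leak = 3e-5, e_leak = -60,
    g_leak_dend = 2.6e-5,
    dend_L = 2200, dend_diam = 3.0,
    axon_L = 150, axon_diam = 1.0, axon_n = 6,
    g_naf_soma = 0.2, g_kdr_soma = 0.3, g_nap_soma = 0,
    g_cat = 3e-4, g_hcn = 8e-5,
    g_sk_soma = 8e-3,
    ca_tau = 40, ca_k = 2)
}

#' Build the reduced deep-cerebellar-nucleus model
#'
#' Stand-in with exactly 400 dendritic compartments (four long dendritic
#' processes oriented into the lower hemisphere, whose electrotonic extent
#' sets the cell's polarization length), a soma carrying fast and
#' persistent sodium, delayed-rectifier and calcium-gated potassium
#' conductances, and low-threshold (T-type) calcium plus HCN conductances
#' supporting rebound firing after release from GABAergic
#' hyperpolarisation. Fires tonically at rest.
#'
#' @param par parameter list (see [dcn_default_params()])
#' @return a `ctdcs_neuron_model` with `cell_type = "DCN"`
#' @export
build_reduced_dcn <- function(par = dcn_default_params()) {
  soma_d <- 22
  rows <- list(data.frame(
    id = 1L, parent = 0L, x0 = 0, y0 = 0, z0 = -soma_d / 2,
    x1 = 0, y1 = 0, z1 = soma_d / 2, diam = soma_d,
    section = "soma", region = "soma", stringsAsFactors = FALSE))
  # four long dendritic processes, 100 compartments each, steeply oriented
  # into the -z hemisphere; their electrotonic extent sets the cell's
  # polarization length
  ang <- seq(0, 2 * pi, length.out = 5)[-5]
  for (b in 1:4) {
    d <- c(0.30 * cos(ang[b]), 0.30 * sin(ang[b]), -0.954)
    ch <- morph_chain(rows, 1L, c(0, 0, -soma_d / 2), 100, par$dend_L,
                      par$dend_diam, d, "dendrite")
    rows <- ch$rows
  }
  axn <- morph_chain(rows, 1L, c(0, 0, soma_d / 2), par$axon_n, par$axon_L,
                     par$axon_diam, c(0, 0, 1), "axon")
  morph <- morphology(do.call(rbind, axn$rows), axis = c(0, 0, 1))
  chans <- list(
    channel("NaF", "soma", par$g_naf_soma, 60, gates = list(
      gate_v(3, vh = -35, k = 5.5, tau0 = 0.04, amp = 0.12, vd = -35, s1 = 12, s2 = 12),
      gate_v(1, vh = -50, k = -6, tau0 = 0.4, amp = 5, vd = -54, s1 = 14, s2 = 14))),
    channel("NaP", "soma", par$g_nap_soma, 60, gates = list(
      gate_v(1, vh = -55, k = 5, tau0 = 2))),
    channel("Kdr", "soma", par$g_kdr_soma, -85, gates = list(
      gate_v(4, vh = -35, k = 8, tau0 = 0.35, amp = 25, vd = -50, s1 = 8, s2 = 18))),
    channel("CaT", c("soma", "dendrite"), par$g_cat, 120, gates = list(
      gate_v(2, vh = -55, k = 6, tau0 = 4),
      gate_v(1, vh = -78, k = -6, tau0 = 60)),
      ca_pool = "ca"),
    channel("HCN", c("soma", "dendrite"), par$g_hcn, -30, gates = list(
      gate_v(1, vh = -80, k = -8, tau0 = 250))),
    channel("SK", "soma", par$g_sk_soma, -85,
      gates = list(gate_ca(1, kd = 0.6, hill = 4, tau = 8)),
      reads_pool = "ca"))
  neuron_model(morph,
               passive = list(cm = par$cm, ra = par$ra,
                              g_leak = par$g_leak, e_leak = par$e_leak,
                              overrides = list(
                                dendrite = list(g_leak = par$g_leak_dend))),
               channels = chans,
               pools = list(ca = ca_pool(tau = par$ca_tau, k = par$ca_k)),
               cell_type = "DCN")
}

# ---------------------------------------------------------------------------
# f-I curve and calibration --------------------------------------------------

#' Frequency-current curve of a model
#'
#' Injects somatic current steps of increasing density and measures the
#' steady firing rate and first-spike latency. Current density is converted
#' to injected current through the total membrane surface area.
#'
#' @param model a `ctdcs_neuron_model`
#' @param current_density_steps step amplitudes, uA/cm^2 (sorted ascending)
#' @param onset step onset, ms
#' @param window analysis window after onset, ms (>= 2000)
#' @param dt integration step, ms
#' @return data.frame with columns current_density, rate_hz, latency_ms
#' @export
fi_curve <- function(model, current_density_steps, onset = 200,
                     window = 2000, dt = 0.025) {
  stopifnot(!is.unsorted(current_density_steps))
  area <- surface_area(model)
  soma <- soma_index(model)
  out <- lapply(current_density_steps, function(cd) {
    amp <- cd * 1e-3 * area * 1e6  # uA/cm^2 * cm^2 -> uA -> nA
    sim <- simulate_cell(model,
      injections = data.frame(comp = soma, t0 = onset, t1 = onset + window,
                              amp_nA = amp),
      duration = onset + window, dt = dt, v_init = model$passive$e_leak)
    tr <- detect_spikes(sim)
    post <- tr$times[tr$times > onset]
    data.frame(current_density = cd,
               rate_hz = 1000 * length(post) / window,
               latency_ms = if (length(post)) post[1] - onset else NA_real_)
  })
  do.call(rbind, out)
}

#' Calibration target set
#'
#' @param targets data.frame with columns name, value, unit, tol (absolute
#'   tolerances, > 0)
#' @export
calibration_targets <- function(targets) {
  stopifnot(all(c("name", "value", "unit", "tol") %in% names(targets)),
            nrow(targets) >= 1, all(targets$tol > 0))
  structure(targets, class = c("ctdcs_targets", "data.frame"))
}

#' Calibrate model parameters against a target set
#'
#' Bounded derivative-free (Nelder-Mead simplex on a logistic box
#' transform) minimisation of the summed squared normalised target error.
#' `metric_fn(model)` must return a named vector covering all target names.
#' If the starting model already satisfies every target the optimiser is
#' skipped (zero iterations) and the model is returned unchanged.
#'
#' @param model a `ctdcs_neuron_model`
#' @param targets a [calibration_targets()] set
#' @param metric_fn function(model) -> named numeric vector of achieved
#'   values
#' @param free_params named list: parameter name -> function(model, value)
#'   returning the updated model
#' @param start,lower,upper named numeric vectors over the free parameters
#' @param seed seed for the (deterministic) restart jitter
#' @param maxit simplex iteration cap
#' @return list with `model`, `report` (per-target residuals), `converged`,
#'   `iterations`, `failed` (TRUE when some residual exceeds its tolerance)
#' @export
calibrate <- function(model, targets, metric_fn, free_params,
                      start, lower, upper, seed = 1, maxit = 200) {
  stopifnot(inherits(targets, "ctdcs_targets"),
            identical(names(start), names(free_params)),
            all(start >= lower & start <= upper))
  apply_par <- function(m, v) {
    for (nm in names(free_params)) m <- free_params[[nm]](m, v[[nm]])
    m
  }
  residuals_of <- function(m) {
    got <- metric_fn(m)
    miss <- setdiff(targets$name, names(got))
    if (length(miss)) stop("metric_fn is missing targets: ",
                           paste(miss, collapse = ", "))
    (got[targets$name] - targets$value) / targets$tol
  }
  report_of <- function(m) {
    got <- metric_fn(m)
    data.frame(name = targets$name, target = targets$value,
               achieved = unname(got[targets$name]), unit = targets$unit,
               tol = targets$tol,
               residual = unname(got[targets$name] - targets$value),
               ok = abs(got[targets$name] - targets$value) <= targets$tol,
               row.names = NULL)
  }
  r0 <- residuals_of(model)
  if (all(abs(r0) <= 1)) {
    return(list(model = model, report = report_of(model), converged = TRUE,
                iterations = 0L, failed = FALSE))
  }
  # logistic box transform keeps the simplex inside the bounds
  to_unc <- function(v) stats::qlogis((v - lower) / (upper - lower))
  to_box <- function(u) lower + (upper - lower) * stats::plogis(u)
  obj <- function(u) {
    m <- apply_par(model, as.list(setNames(to_box(u), names(start))))
    sum(residuals_of(m)^2)
  }
  u0 <- to_unc(start)
  fit <- with_seed(seed, suppressWarnings(
    optim(u0, obj, method = "Nelder-Mead", control = list(maxit = maxit))))
  best <- as.list(setNames(to_box(fit$par), names(start)))
  model2 <- apply_par(model, best)
  rep2 <- report_of(model2)
  list(model = model2, report = rep2, converged = fit$convergence == 0,
       iterations = fit$counts[["function"]], failed = any(!rep2$ok),
       params = best)
}
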