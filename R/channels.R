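#' Voltage-dependent gating variable
#'
#' Hodgkin-Huxley-style gate with Boltzmann steady state
#' `x_inf(V) = 1 / (1 + exp(-(V - vh) / k))` (negative `k` gives an
#' inactivation/inwardly-rectifying gate) and either a constant time constant
#' or the usual bell-shaped form
#' `tau(V) = tau0 + amp / (exp((V - vd)/s1) + exp(-(V - vd)/s2))` (ms).
#'
#' @param p power with which the gate enters the conductance product
#' @param vh,k Boltzmann midpoint (mV) and slope (mV)
#' @param tau0 constant floor of the time constant (ms)
#' @param amp,vd,s1,s2 bell parameters; omit `amp` (or set 0) for constant tau
#' @return gate description list
#' @export
gate_v <- function(p, vh, k, tau0, amp = 0, vd = vh, s1 = 10, s2 = 10) {
  stopifnot(p >= 0, is.finite(vh), k != 0, tau0 > 0 || amp > 0)
  list(type = 0L, p = p, vh = vh, k = k,
       tauform = if (amp > 0) 1L else 0L,
       tau0 = tau0, amp = amp, vd = vd, s1 = s1, s2 = s2)
}

#' Calcium-dependent gating variable
#'
#' Hill activation by the compartment's calcium pool:
#' `x_inf = ca^h / (ca^h + kd^h)` with constant time constant.
#'
#' @param p power
#' @param kd half-activation concentration (pool units)
#' @param hill Hill coefficient
#' @param tau time constant (ms)
#' @export
gate_ca <- function(p, kd, hill, tau) {
  stopifnot(p >= 0, kd > 0, hill > 0, tau > 0)
  list(type = 1L, p = p, vh = kd, k = hill,
       tauform = 0L, tau0 = tau, amp = 0, vd = 0, s1 = 10, s2 = 10)
}

#' Ion channel specification
#'
#' A named conductance with maximum density `gmax` (S/cm^2), reversal
#' potential (mV), a list of gates ([gate_v()]/[gate_ca()]) and a section or
#' region assignment. Channels that carry calcium name the pool they feed
#' (`ca_pool`); channels with calcium-dependent gates name the pool they read
#' (`reads_pool`). `qt` is a temperature adjustment factor that divides all
#' gate time constants (kinetics are quoted at 37 C with `qt = 1`).
#'
#' @param name channel name (used by [block_channels()] and bias scoping)
#' @param sections character vector of region/section labels carrying the
#'   channel
#' @param gmax maximum conductance density, S/cm^2
#' @param erev reversal potential, mV
#' @param gates list of gates; empty list gives an ohmic conductance
#' @param ca_pool name of the calcium pool this channel feeds, or `NULL`
#' @param reads_pool name of the calcium pool read by `gate_ca` gates
#' @param qt temperature adjustment factor for the gate kinetics
#' @export
channel <- function(name, sections, gmax, erev, gates = list(),
                    ca_pool = NULL, reads_pool = NULL, qt = 1) {
  stopifnot(is.character(name), gmax >= 0, is.finite(erev), qt > 0)
  has_ca_gate <- any(vapply(gates, function(g) g$type == 1L, TRUE))
  if (has_ca_gate && is.null(reads_pool))
    stop("channel ", name, " has a calcium gate but no reads_pool")
  structure(list(name = name, sections = sections, gmax = gmax, erev = erev,
                 gates = gates, ca_pool = ca_pool, reads_pool = reads_pool,
                 qt = qt),
            class = "ctdcs_channel")
}

#' Calcium pool specification
#'
#' First-order intracellular calcium accumulator:
#' `dc/dt = -k * J_Ca - (c - c0) / tau` where `J_Ca` is the calcium current
#' density (mA/cm^2, inward negative, so influx raises `c`).
#'
#' @param tau decay time constant (ms)
#' @param k influx scaling (concentration units per mA/cm^2 per ms)
#' @param c0 resting concentration
#' @export
ca_pool <- function(tau, k, c0 = 0.05) {
  stopifnot(tau > 0, k > 0, c0 >= 0)
  list(tau = tau, k = k, c0 = c0)
}

#' Multicompartment neuron model
#'
#' Bundles a [morphology()], passive membrane properties, a channel list and
#' calcium pools into a simulatable cell. Passive properties are given
#' globally and optionally overridden per region:
#' `passive = list(cm = 1, ra = 150, g_leak = 3e-5, e_leak = -65, overrides =
#' list(axon = list(g_leak = ...)))` with cm in uF/cm^2, ra in Ohm cm, g_leak
#' in S/cm^2, e_leak in mV.
#'
#' @param morph a [morphology()]
#' @param passive passive property list (see Details)
#' @param channels list of [channel()] specifications
#' @param pools named list of [ca_pool()] specifications
#' @param cell_type one of "PC", "DCN", "GrC", or "generic"
#' @return object of class `ctdcs_neuron_model`
#' @export
neuron_model <- function(morph, passive, channels = list(), pools = list(),
                         cell_type = "generic") {
  stopifnot(inherits(morph, "ctdcs_morphology"))
  for (f in c("cm", "ra", "g_leak", "e_leak")) {
    if (is.null(passive[[f]])) stop("passive properties must include ", f)
    if (f != "e_leak" && passive[[f]] <= 0) stop("passive ", f, " must be positive")
  }
  nm <- vapply(channels, function(ch) ch$name, "")
  if (anyDuplicated(nm)) stop("duplicate channel names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  for (ch in channels) {
    for (pn in c(ch$ca_pool, ch$reads_pool))
      if (!is.null(pn) && is.null(pools[[pn]]))
        stop("channel ", ch$name, " references unknown calcium pool ", pn)
    hit <- morph$compartments$region %in% ch$sections
    if (!any(hit))
      stop("channel ", ch$name, " matches no compartments (sections: ",
           paste(ch$sections, collapse = ", "), ")")
  }
  structure(list(morph = morph, passive = passive, channels = channels,
                 pools = pools, cell_type = cell_type),
            class = "ctdcs_neuron_model")
}

#' @export
print.ctdcs_neuron_model <- function(x, ...) {
  cat(sprintf("%s neuron model: %d compartments, %d channel types\n",
              x$cell_type, nrow(x$morph$compartments), length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  %-10s gmax %.3g S/cm2, Erev %+.0f mV on [%s]\n",
                ch$name, ch$gmax, ch$erev, paste(ch$sections, collapse = ", ")))
  invisible(x)
}

#' Channel names of a model
#' @param model a `ctdcs_neuron_model`
#' @export
channel_names <- function(model) {
  vapply(model$channels, function(ch) ch$name, "")
}

#' Zero out named channels
#'
#' Returns a copy of the model with the maximum conductance of the listed
#' channels set to zero (pharmacological block); the input model is
#' unchanged. Blocking nothing returns an identical model.
#'
#' @param model a `ctdcs_neuron_model`
#' @param names channel names to block; `"all"` blocks every channel
#' @export
block_channels <- function(model, names) {
  avail <- channel_names(model)
  if (length(names) == 1 && identical(names, "all")) names <- avail
  unknown <- setdiff(names, avail)
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "))
  model$channels <- lapply(model$channels, function(ch) {
    if (ch$name %in% names) ch$gmax <- 0
    ch
  })
  model
}

# region -> passive property resolution
passive_of <- function(passive, region, field) {
  ov <- passive$overrides
  if (!is.null(ov) && !is.null(ov[[region]]) && !is.null(ov[[region]][[field]]))
    return(ov[[region]][[field]])
  passive[[field]]
}

# Compile a model into the flat arrays the C++ engine consumes.
compile_model <- function(model) {
  df <- model$morph$compartments
  n <- nrow(df)
  area <- morph_area_cm2(model$morph)
  cmv <- glv <- elv <- rav <- numeric(n)
  for (i in seq_len(n)) {
    r <- df$region[i]
    cmv[i] <- passive_of(model$passive, r, "cm") * area[i] * 1e3  # uF/cm2 * cm2 -> nF
    glv[i] <- passive_of(model$passive, r, "g_leak") * area[i] * 1e6
    elv[i] <- passive_of(model$passive, r, "e_leak")
    rav[i] <- passive_of(model$passive, r, "ra")
  }
  # axial conductance to parent (uS): series of the two half-resistances
  xsec <- pi * df$diam^2 / 4              # um^2
  rhalf <- rav * (df$L / 2) / xsec * 1e4  # Ohm
  gax <- numeric(n)
  for (i in seq_len(n)) {
    p <- df$parent[i]
    if (p > 0) gax[i] <- 1e6 / (rhalf[i] + rhalf[p])
  }
  pool_names <- names(model$pools)
  pools <- unname(model$pools)
  chans <- lapply(model$channels, function(ch) {
    hit <- which(df$region %in% ch$sections)
    list(comps = as.integer(hit - 1L),
         gbar = ch$gmax * area[hit] * 1e6,
         erev = ch$erev,
         ion = if (is.null(ch$ca_pool)) 0L else match(ch$ca_pool, pool_names),
         capool = if (is.null(ch$reads_pool)) 0L else match(ch$reads_pool, pool_names),
         gates = ch$gates,
         gate_bias = 0,
         qt = ch$qt)
  })
  list(n = n, parent = as.integer(df$parent - 1L), g_axial = gax,
       cm = cmv, g_leak = glv, e_leak = elv, area = area,
       ve = numeric(n), bias_comp = numeric(n),
       channels = chans,
       pools = if (length(pools)) pools else list())
}
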