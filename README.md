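# ctdcs

Cellular-level modelling of cerebellar transcranial direct current
stimulation (tDCS): what a weak, locally uniform electric field does to
Purkinje cells, deep-cerebellar-nucleus neurons and granule cells, and how
those single-cell sensitivities distribute over a folded cortical surface.
The package is aimed at computational neuroscientists and neurostimulation
modellers who want a self-contained, tested R implementation of this
analysis at desk scale — no MRI volumes, finite-element solvers or external
simulators required.

## What it computes

**Field coupling.** Under the quasi-uniform assumption the extracellular
potential along one neuron is linear in the distance along the field
direction,

    Ve_n = E · l_n        (soma as reference, l_n in µm, E in V/m → mV)

with the cell-centred sign convention: `E < 0` is *anodal* (field toward
the axonal terminal), `E > 0` *cathodal* (toward the dendrites). These
offsets drive the cable equation

    C_m dV_n/dt = −Σ I_ion(V_n) − I_syn + I_inj + Σ_m g_nm [(V_m + Ve_m) − (V_n + Ve_n)]

which is integrated with an implicit backward-Euler tree solve and
exponential gating updates at `dt = 0.025` ms.

**Cell models.** A 65-compartment granule cell built from its section and
channel tables, and reduced Purkinje / DCN models calibrated so that one
parameter set per cell reproduces the printed baselines simultaneously:
tonic rates (61.3 / 27.2 Hz), blocked-channel somatic polarization at
1.5 V/m (0.78 / 1.26 mV; granule cell 0.12 mV), the 8.5-ms
dendrite-to-soma transmission delay, the 440.6-ms post-complex-spike
silence period, and the transient bursting response to a 2-nA somatic step.

**Drives and metrics.** Difference-of-exponentials synapses
(`α(z) = A(e^{−z/τ₂} − e^{−z/τ₁})`, unit peak), the stock drive
configurations (inhibitory volley on the DCN, mossy-fibre trains on the
granule cell, parallel-fibre and 1,100-synapse polysynaptic drives and the
climbing-fibre volley on the PC), and the full metric set: pattern
classification (dense / irregular / bursting / sparse), ISI CoV, adaptive
Gaussian-kernel instantaneous firing rate, transmission delay T_d, silence
period T_sp, burst decomposition (T_burst, T_intv, T_spike), relay
fidelity r, phase-response curves, 30-Hz zero-phase Butterworth filtering
and charge-density differences.

**Spatial mapping.** Synthetic folded-cortex voxel grids with point-source
electric fields (median cortex intensity 0.45 V/m, ~1 % above 1 V/m),
marching-tetrahedra iso-surfaces whose outward normals stand for the
Purkinje somato-dendritic axes, signed projection `E_proj = −|E| cos θ`,
and per-vertex interpolation of sensitivity curves into response maps with
summary tables.

## Worked example

```r
library(ctdcs)

pc <- build_reduced_pc()

rest <- exp_tonic_rate(pc, duration = 5000, transient = 1000)
sprintf("tonic rate at rest: %.1f Hz (ISI CoV %.3f)", rest$rate_hz, rest$cov)

soma <- which(pc$morph$compartments$section == "soma")[1]
dv <- polarization_profile(pc, field_spec(1.5))[soma]
sprintf("somatic polarization at +1.5 V/m (channels blocked): %+.2f mV", dv)

for (E in c(-1.5, 0, 1.5))
  cat(sprintf("E = %+.1f V/m: silence period T_sp = %.1f ms\n",
              E, exp_pc_cs(pc, E = E)$t_sp))
```

prints

```
tonic rate at rest: 60.2 Hz (ISI CoV 0.009)
somatic polarization at +1.5 V/m (channels blocked): -0.78 mV
E = -1.5 V/m: silence period T_sp = 418.9 ms
E = +0.0 V/m: silence period T_sp = 432.4 ms
E = +1.5 V/m: silence period T_sp = 437.1 ms
```

Read: at rest the Purkinje model pacemakes regularly at ~60 Hz. A cathodal
1.5 V/m field hyperpolarizes the soma by 0.78 mV (anodal depolarizes by
the same amount — the passive response is antisymmetric). After a
climbing-fibre complex spike the cell stays silent for ~432 ms; anodal
fields shorten that pause and cathodal fields prolong it, monotonically
across the whole ±1.5 V/m range.

The spatial step runs on synthetic geometry:

```r
curve <- sensitivity_curve(seq(-1.5, 1.5, length.out = 13),
                           c(419, 421, 423, 425, 427, 430, 432,
                             433, 434, 435, 435, 436, 437), "T_sp")
mapres <- exp_spatial_map(list(T_sp = curve))
mapres$summaries$T_sp$anodal_fraction   # ~0.5 on near-spherical shells
```

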