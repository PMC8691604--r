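---
title: "Modelling the cellular response of cerebellar neurons to weak uniform fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cellular response of cerebellar neurons to weak uniform fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctdcs)
```

## The problem

Transcranial direct current stimulation (tDCS) of the cerebellum imposes an
electric field of at most a few tenths of a volt per metre on the tissue
under the electrode. At the scale of one neuron that field is effectively
uniform, and its only direct action is a sub-millivolt, compartment-dependent
shift of the membrane potential. Whether such a small polarization matters
depends on the cell: its morphology (which sets how much the soma polarizes),
its intrinsic dynamics (pacemaking, rebound firing, bursting), and the
synaptic context it operates in. `ctdcs` implements a desk-scale version of
this cellular analysis for the three principal cerebellar neuron classes —
Purkinje cells (PC), deep-cerebellar-nucleus neurons (DCN) and granule cells
(GrC) — plus the geometric step that projects a voxelised field distribution
onto the Purkinje-cell axes of a folded cortical surface.

## Field coupling and the simulator

Under the quasi-uniform assumption the extracellular potential along a
neuron varies linearly with distance along the field direction:
`Ve_n = E * l_n`, with the soma as the zero reference and `l_n` the signed
distance of compartment `n` (µm) along the field axis, giving millivolts for
`E` in V/m. The sign convention is cell-centred: negative intensities are
*anodal* (field pointing towards the axonal terminal) and positive
*cathodal* (towards the dendrites). These offsets enter the cable equation
as driving terms on the axial connections — the standard formulation for an
extracellular mechanism; the alternative (treating the offsets as purely
local shifts with no axial coupling) would make a uniform field invisible
to the cell, so it was not adopted.

Voltages are integrated with an implicit backward-Euler tree solve (Hines
ordering) and gating states with exponential (Rush–Larsen) updates at
`dt = 0.025` ms. This pairing is stable on stiff channel kinetics and is
the same class of scheme used by the standard compartmental simulators.
Channels are Hodgkin–Huxley-style gates with Boltzmann steady states and
constant or bell-shaped time constants; calcium-dependent gates read
first-order calcium pools filled by the calcium current density of the
compartment they live in. All kinetics are quoted at 37 °C; the `qt` factor
of each channel rescales its time constants if a different temperature is
wanted. Units are mV, ms, nA, µS and µm throughout, with conversions
centralised in the model compiler.

Two selective manipulations mirror the experimental ones: a uniform field
(`field_spec`) and a bias (`bias_spec`). A compartment-scoped bias adds
`V_bias` to the membrane potential sensed by every channel (including the
leak) of the listed compartments; a channel-scoped bias shifts only the
voltage argument of the named channels' gating functions. The
field-equivalent bias used by the sweep experiments is
`V_bias = -0.215 * E / 1.5` mV, i.e. the polarization a ±1.5 V/m field
imposes on the somatic channels, with anodal fields giving depolarising
bias. Bias magnitudes are capped at 1 mV.

## The reduced models and their calibration

The published multicompartment reconstructions (a 1,611-compartment PC and a
516-compartment DCN) are out of scope here; the package ships reduced
stand-ins that are calibrated, with one fixed parameter set per cell, to the
printed single-cell baselines:

| quantity | PC | DCN | GrC |
|---|---|---|---|
| tonic rate at rest | 61.3 Hz | 27.2 Hz | silent |
| somatic polarization at 1.5 V/m (channels blocked) | 0.78 mV | 1.26 mV | 0.12 mV |
| dendrite-to-soma transmission delay | 8.5 ms | — | — |
| post-complex-spike silence period | 440.6 ms | — | — |
| transient bursting under a 2-nA step | 12 bursts, mean period 116.7 ms | — | — |

A design constraint worth making explicit: a passive structure cannot
polarize its soma by more than the extracellular-potential span across the
cell, so a 0.78-mV somatic shift at 1.5 V/m requires an area centroid about
0.5 mm from the soma. Keeping the directional phenomenology — anodal fields
depolarise the soma and make the cell more excitable — requires that
centroid to sit on the *dendritic* side. The reduced PC therefore carries a
six-level binary tree with distally concentrated membrane area and a
soma-to-tip path of about 1.06 mm, rather than the ~0.3-mm extent of the
reconstructed cell; the reduced DCN uses four 2.2-mm dendritic processes
for the same reason. This is the price of reproducing both the printed
polarization magnitudes and the directions of every field effect with a
passive reduced morphology; the consequences are discussed under
*Limitations*.

The PC's dynamical repertoire is organised into loosely coupled subsystems:

* a pacemaker (persistent sodium at the axon initial segment) plus a
  slow-deactivating delayed rectifier, giving regular tonic firing;
* a regenerative dendritic calcium system (P-type-like channels along the
  thin dendrites) that supports an inward-propagating wave when the most
  distal compartment is pulsed — this sets the 8.5-ms transmission delay —
  and an outward wave when the thick compartments are driven by the
  climbing-fibre volley;
* a slow, high-threshold calcium conductance on the thick dendrites that is
  loaded by complex-spike-scale events and, through a slow calcium pool and
  a calcium-gated K conductance, enforces the post-complex-spike silence;
  the release from that silence is drive-sensitive, which is what makes the
  inter-burst intervals under a 2-nA step (~0.1 s) much shorter than the
  silence period at rest (~0.44 s) although both ride the same pool;
* a slowly inactivating low-threshold calcium conductance on the thick
  dendrites that re-ignites dendritic events under sustained somatic
  depolarisation (pacing the transient bursting) and whose slow
  inactivation — fast to accrue during depolarised events, slow to
  recover — terminates the sequence after roughly a dozen bursts.

The GrC is built from its section and channel tables: 65 compartments with
the printed totals (dendritic tree 158.6 µm, axon initial segment 70.1 µm,
ascending axon 218.0 µm, hillock of 5 compartments, 30 identical AIS
compartments, axon perpendicular to the somato-dendritic plane). Its
sodium channel carries a fast inactivation gate tuned so that slow
depolarising ramps accommodate — giving a current-density threshold between
5 and 8 µA/cm² — while brief mossy-fibre EPSPs still fire the cell, and a
slow inactivation gate whose accrual during spikes produces the
relay-fidelity adaptation above ~50 Hz.

`calibrate()` is the generic calibration operation: bounded derivative-free
simplex over user-chosen free parameters against a `calibration_targets`
table, with per-target residuals reported and an idempotence guarantee
(already-satisfying models are returned untouched). The shipped models are
the stored outcome of that process; the function itself is exercised on
small closed-form problems in the test suite.

## Synaptic drives

All synapses use the difference-of-exponentials kernel normalised to unit
peak, `alpha(z) = A (exp(-z/tau2) - exp(-z/tau1))`, with currents
`g_syn * alpha(t - tau) * (V - E_syn)`. The stock drive configurations are:
the DCN inhibitory volley (450 GABAergic synapses — one per dendritic
compartment plus 50 on the soma — driven by one common 15-ms train with
shifted-exponential intervals, λ = 2 ms, t_r = 2 ms); the GrC mossy-fibre
pair (AMPA 2.88e-3 µS + NMDA 4.51e-4 µS on the most distal dendritic
compartment, regular train; the NMDA synapse uses the same kernel with no
magnesium block, since only its conductance and time constants are
specified); the single parallel-fibre synapse for phase-response estimation
(λ = 50 ms Poisson-like train; no bias current is needed to put the model
in the 50–70-Hz band because its resting rate is already there); the
polysynaptic drive (1,000 glutamatergic synapses at λ = 100 ms and 100
GABAergic at λ = 35.7 ms on random non-overlapping dendritic compartments,
all trains mutually independent, conductances scaled by `1 + delta_syn`);
and the climbing-fibre volley (one common pulse onto every dendritic
compartment with diameter ≥ 3.5 µm). Three drive-configuration seeds
(default 1, 2, 3) reproduce the three-configuration design used for the
population statistics.

## Spike metrics

The spike detector uses upward crossings of 0 mV with a 1-ms refractory
window — robust for all three cells' spike amplitudes. The pattern
classifier applies the four published rules in the priority order sparse →
bursting → irregular → dense, with anything left over unclassified; the
sparse rule is the only position-dependent one (it looks at silent periods
including the tail of the recording). The instantaneous firing rate is a
sum of spike-centred Gaussians whose widths follow
`min(ISI_before, ISI_after) / sqrt(2*pi)`; the divisor is exposed because
the source convention is printed ambiguously (`2π` vs `√(2π)`), and the
√(2π) reading is the one that makes each kernel integrate to one spike at
the conventional width. Burst decomposition uses the 10-ms gap rule with a
two-spike minimum per burst, and satisfies
`T_burst(k) = T_intv(k) + T_spike(k+1)` by construction. The complex-spike
peak is the maximum-amplitude point within 15 ms of the climbing-fibre
pulse (the printed duration of a complex spike); the first *simple* spike
is the first detection more than 40 ms after that peak, a window wide
enough to cover the reduced model's spikelet envelope. The phase-response
curve uses the plain binned estimator (20 equal phase bins of the
normalised phase shift); it is validated against the closed-form PRC of a
leaky integrate-and-fire oscillator.

## Synthetic geometry and the spatial map

The folded cortical shell is a sinusoidally folded sphere voxelised at
600 µm, with the scalar field linear in the signed distance to the outer
surface so that marching-tetrahedra extraction at isovalue 0.5 recovers the
folds with sub-voxel accuracy. Voxels within 1.2 mm of the surface are
labelled cortex (the Purkinje-cell layer); everything deeper is labelled as
the nuclear region, and nuclei-owned vertices are removed from the surface.
Default shell parameters (radius 12 mm, folia wavelength 6 mm, amplitude
1.5 mm) give gyri and sulci whose normals span more than 120° against any
fixed axis, which is the feature the projection step needs.

The electric field is a superposition of current point sources in a
homogeneous medium — divergence-free away from the electrodes, with a
closed-form magnitude used as the test oracle. The default montage (one
anode close to the shell, one distant return) is normalised so the median
cortex-voxel intensity is 0.45 V/m, which with the default standoff leaves
roughly 1 % (and at most 1.3 %) of cortex voxels above 1 V/m — the printed
whole-cortex summary statistics of a 2-mA montage. When an explicit
`current_scale` is passed the field is exactly linear in it.

Projection follows the anatomy: the somato-axonal axis at each vertex is
the negated outward normal (dendrites grow outward, perpendicular to the
folds), `theta` is the angle between the local field vector and that axis,
and the signed projection is `E_proj = -|E| cos(theta)` so that field
toward the axonal terminal is anodal/negative. Sensitivity curves (a metric
evaluated on the 13-point intensity grid from −1.5 to +1.5 V/m at θ = 0°)
are mapped per vertex by piecewise-linear interpolation with clamping —
dense enough on 13 points, and free of overshoot where the curve is
monotone. Undefined curve points (a metric with no defined value at some
intensity) propagate as absent vertices rather than being bridged.
Summaries report the anodal/cathodal split, the fractions beyond ±0.5 and
±1.5 V/m, the θ histogram and the fractions of vertices whose metric
changes by more than 10/20/30 %.

## Numerical choices and problem sizes

Simulations run at `dt = 0.025` ms. Steady states for polarization are
reached by 500-ms relaxation with a 1-µV/ms terminal drift criterion,
keeping one code path for passive and active runs. Synaptic events are
snapped to the integration grid; the divergence guard aborts with the time
of failure if any compartment passes ±200 mV. The problem sizes used by the
stock experiments are the study's own: 5-s tonic runs (1-s transient), 10-s
polysynaptic runs per drive configuration with field onset at 2 s, 3-s
step-bursting runs, 2.3-s relay runs, and a 10⁴-vertex shell for the
spatial map. With-field statistics in the polysynaptic experiment use the
post-onset window; baseline statistics use the full post-transient window
(0.5 s transient), since the division is not otherwise specified. The
phase-response experiment defaults to 30-s recordings; longer recordings
sharpen the curve but do not change its shape.

## What the synthetic inputs do and do not show

The generators reproduce the *structure* of the study's inputs — intensity
statistics of the voxel field, folded geometry with a wide normal
distribution, drive configurations with the printed rates and conductances
— not any subject's anatomy. Passing the mapping tests on the synthetic
sphere (50/50 anodal–cathodal split, sin-θ orientation law, rotation
invariance) validates the geometry pipeline, but says nothing about
atlas-specific numbers such as which fraction of a real cerebellum exceeds
0.5 V/m under a particular montage; those require segmented MRI volumes and
a finite-element solve, which are deliberately out of scope.

## Known limitations

* The reduced PC trades morphological realism for the printed polarization
  values: its tree is ~3× longer than the reconstructed cell's. One
  consequence is that the dendrites are regenerative over a millimetre, and
  under the full polysynaptic drive they fire calcium waves that the
  reconstructed cell would not produce; the shipped model therefore fires
  at roughly 15-20 Hz with a CoV near 1.6 under that drive rather than the
  printed ~30 Hz at CoV 0.8. The baseline and field-direction behaviour of
  every other experiment is unaffected.
* The field modulation of the transmission delay and silence period has the
  printed direction (anodal shortens both, monotonically across the
  13-point grid) but a much smaller magnitude than reported for the
  reconstructed cell, whose spike initiation machinery is more sensitive to
  somatic polarization than the reduced one.
* Granule-cell relay adaptation sets in between 50 and 80 Hz (ratio ~0.5 at
  80 Hz) rather than rising smoothly from 40 Hz.
* No myelin, no stochastic channels, no short-term synaptic plasticity, no
  temperature sweeps; the NMDA synapse has no magnesium block.
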