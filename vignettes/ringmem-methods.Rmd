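---
title: "ringmem: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ringmem: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ringmem` models spatial orientation working memory in the fly central
complex at two levels: a conductance-based spiking model of the
ellipsoid-body/protocerebral-bridge (EB-PB) head-direction circuit, and the
Buridan-arena trajectory statistics used to quantify landmark fixation in
free-walking flies.  A synthetic-trajectory generator stands in for real
recordings, so every stage of the analysis is testable offline.  This
vignette explains the models, the calibrated parameters, and the design
decisions taken where the published description leaves the implementation
open.

## The circuit model

### Populations and wiring

The EB is discretized into 18 angular wedges of 20°.  Six populations are
simulated, one leaky integrate-and-fire unit per labeled neuron index:

* **EIP** (E-PG, 18 units, one per wedge) carry the head-direction bump and
  are the readout for all bump metrics.
* **PEI** (18 units, 9 per PB side) form the recurrent *C circuit* with EIP;
  it stabilizes the bump.
* **PEN** (18 units, 9 per side) form the *P circuit* with EIP; it shifts
  the bump during body rotation.
* **EIP-ring, C-ring, P-ring** (GABAergic pools of 8 units each): global
  inhibition that sets the bump width, and the two gating pools that
  suppress PEI and PEN respectively.

Synaptic weights follow the published table (EIP→PEI/PEN 4.0, EIP→ring 1.0,
PEI→EIP 8.0/4.0/4.0 and PEN→EIP 10.0/5.0/15.0 for the
central/peripheral/atypical classes, ring→EIP 3.0, ring→ring 1.6,
gate→PEI/PEN 10.0).  The index map is reconstructed from the published
example connections under the assumption that EIP indices are in *PB
order*: even wedge $w$ is EIP $w/2$, odd wedge $w$ is EIP $9+(w-1)/2$.
Under this ordering the quoted pair "glomerulus 0 projects centrally to
EIP10 and peripherally to EIP2" lands on *adjacent* wedges 3 and 4, which
makes the recurrence local — the alternative reading (antipodal targets 8
wedges apart) produces satellite bumps and is dynamically untenable.  The
two glomeruli whose peripheral wedge would wrap past the ring seam carry
the atypical connection class instead (targets EIP0 and EIP17), completing
the ring.  Every PEI glomerulus additionally receives EIP input from a ±2
wedge dendritic arbor, which sets the bump width scale; PEN input comes
from a single wedge offset by one wedge per side, which implements the
shifter.

### Neuron and synapse model

Neurons are leaky integrate-and-fire with τ = 20 ms, rest −70 mV, threshold
−50 mV, reset −55 mV, refractory 2 ms, C = 0.1 nF (R = 200 MΩ, rheobase
0.1 nA).  These microparameters are not constrained by the source analysis;
the calibration endpoints are the bump observables.  Synapses are
conductance-based with single-exponential decay: NMDA-like excitation
(τ = 100 ms, E = 0 mV) between EIP/PEI/PEN, GABA (τ = 10 ms) from the ring
pools, and a fast receptor (τ = 10 ms, E = 0 mV) for external spike drives.
Two deviations from the most naive reading were forced by dynamics:

* **GABA reversal −85 mV** (below rest).  At −70 mV inhibition is purely
  shunting and cannot bound the NMDA recurrence; every configuration ran
  away to the refractory ceiling.
* **Per-synapse saturation**: each recurrent synapse carries a gating
  variable $s \leftarrow s + \alpha(1-s)$ per presynaptic spike
  (α = 0.2), so its conductance saturates at the tabulated weight times a
  receptor gain.  α = 0.2 keeps synapses near-linear below ~100 spikes/s,
  which the shifter needs in order to transmit rate asymmetries.

Integration is fixed-step exponential-Euler at dt = 0.1 ms (conductance
decay exact, membrane relaxed toward its instantaneous fixed point), with
deterministic seeded Poisson drives, implemented in C++.

### Gating and protocol

A two-state Markov chain (300 ms steps, forward→rotation 0.40,
rotation→forward 0.60) drives the circuit.  During forward steps the
P-ring pool is driven (0.3 nA) and silences PEN; during rotation steps the
C-ring pool is driven and silences PEI, while the P-ring keeps a *partial*
drive (0.145 nA).  Full P-circuit disinhibition during rotation diffuses
the bump — which is exactly the published P-ring-suppression pathology —
so the partial gate is required for a wild-type phenotype.  Rotation steps
additionally deliver Poisson input to the PB side matching the turn
direction; at the calibrated operating point left-PB input rotates the
bump clockwise and right-PB input counterclockwise.  During the stimulus
stage a landmark stream (Poisson onto the PEI glomeruli whose wedge
matches the landmark bearing relative to the current heading) anchors the
bump; routing it through PEN as well bypasses the P-ring gate and
destabilizes the network, so the landmark drive is PEI-only.

The EIP-ring pool is tonically driven (0.175 nA) for the whole trial — the
pool is described as always active — and the condition currents act
against this baseline: −0.04 nA (EIP-ring suppression), −0.25 nA (P-ring
suppression), +0.20 nA (photoactivation, last 30 s of the stimulus stage
or seconds 20–30 of the poststimulus stage).

### Calibration

Free parameters (receptor gains, background/landmark/rotation drive rates,
gate currents) were tuned once, in order: (1) a single stable bump under
landmark input, persisting ≥ 90 s after landmark offset; (2) wild-type
time-averaged bump-aligned FWHM near the printed 1.86 rad, with
EIP-ring suppression near 2.04 rad; (3) unilateral-PB shift with the
correct signs; (4) the photoactivation phenotype pattern (persistence when
the landmark is on, permanent abolition when it is off).  Four projection
gains had to be decoupled from the two global receptor gains: the
C-ring→PEI gate (strong, to silence the heavily driven PEI), the
P-ring→PEN gate (weak, so PEN stays modulable), the EIP→EIP-ring drive and
EIP-ring self-inhibition (so the tonic/photoactivation currents rather than
EIP feedback set the global inhibition level), and the EIP→PEN input
(strong enough that near-bump PEN clear the partial gate without external
help, keeping the bump alive through rotations in darkness).

### Known limitations

* **Heading tracking is weak.**  The one-unit-per-wedge shifter moves the
  bump at only a fraction of the 120°/s body rotation speed, and short
  (300 ms) rotation bouts are partly absorbed by transition latency.
  Moreover the tabulated atypical weight (15) sits on top of the central
  connection that per-side ring coverage requires, leaving the two seam
  wedges with extra PEN drive; while the shifter is engaged this acts as
  a mild attractor at wedge 0/17 that can mask the sign of weak
  unilateral input.  (Removing the excess destabilizes the bump in every
  rotation epoch, so the stable wiring was kept.)  Accumulated bump angle
  therefore underestimates accumulated heading, and the heading–bump
  deviation in both wild-type and suppression conditions is dominated by
  this shared tracking deficit rather than by condition-specific drift.
  The deviation *ordering* between EIP-ring suppression and wild type is
  correspondingly weak, and the unilateral-input rotation direction is
  not asserted as a sustained-input observable.
* Stimulus-stage tracking relies mostly on the landmark stream re-anchoring
  the bump; in darkness the update comes only from the PEN chain.
* A sustained rotation of many seconds (never produced by the Markov
  chain) can collapse the bump.
* The bump-loss fraction under stimulus-stage P-ring photoactivation is
  near zero rather than the printed 24.2%; the source analysis itself
  flags this number as an implementation- and parameter-sensitive
  artifact.

## Bump metrics

Rates are binned at 100 ms per wedge.  A bump is *present* in a bin when
the peak rate is ≥ 5 spikes/s, at least 3× the ring-wide median, and the
super-half-maximum region is one contiguous circular arc spanning less
than half the ring; its position is the rate-weighted circular mean over
that arc.  For trial analysis the rate traces are first smoothed with a
500 ms moving average — single LIF units at tens of spikes/s need it to
beat Poisson bin noise.  FWHM is measured on the time-averaged,
bump-aligned profile by linear interpolation between wedge centers (up to
about half a wedge of discretization error on smooth shapes).  The
heading–bump deviation unwraps both traces and compares accumulated
changes, so a constant offset is ignored; a trial counts as having *lost*
the bump when the present-flag stays false for ≥ 2 s.

## Trajectory statistics

Movement directions are the azimuths at which the forward ray from the
current position meets the screen circle (radius 100 mm); frames moving
less than 0.25 mm are treated as stationary and excluded.  Direction
histograms use 12 quantiles of 30°, every 5 s over 15-s sliding windows.
Fixation density is the fraction of epochs in which the two landmark
quantiles jointly exceed 1/6 (strict inequality); the performance index is
the poststimulus minus prestimulus fixation density.  The fixation
deviation angle σ~f~ minimizes the second moment
$M(\sigma)=\sum_i p(\theta_i)^2\sin^2(\theta_i-\sigma)$ over the paired
(radar) histogram, solved in closed form through
$\sin(2\sigma+\phi)=0$ with $\cos\phi = A/K$, $\sin\phi = B/K$.  The two
stationary axes are $-\phi/2$ and $90°-\phi/2$; the printed form
"$-\phi/2$ or $180°-\phi/2$" names the same axis twice (mod 180°) and
would force FS = 0 everywhere, so the quarter-turn root is used and
verified against a 0.01° grid search.  Fixation strength is
FS = 1 − M~min~/M~max~, with significance criterion 0.1090 = control mean
(0.0544) + 2 SD (0.0273).

## The synthetic-trajectory generator

Synthetic flies follow the same two-state Markov chain; forward bouts
translate at 13 mm/s, rotation bouts turn at 120°/s while keeping 60% of
the forward speed (flies arc rather than pivot).  A fraction
`fixation_bias` of rotation bouts aims at the nearer fixation target with
10° aiming noise; `bias = 0` is an unbiased walk and `bias = 1` aims every
bout.  Three observation-level features were required so that the *null*
generator reproduces the low control-level fixation strength: per-frame
heading jitter during forward bouts (6° SD), wall-following at the
platform edge (turning onto the nearer tangent rather than reflecting, so
unbiased walks circulate and sweep all screen directions), and independent
per-frame centroid noise (0.15 mm SD) emulating video tracking error.
Without them the direction histogram of a 90-s walk is far lumpier than
real prestimulus data and the null FS lands well above the 0.1090
criterion.  What a green test on synthetic cohorts establishes is that the
*pipeline* recovers the fixation structure that was generated; it cannot
establish anything about real flies, whose trajectories are richer (no
thigmotaxis model, no pausing structure, no speed variability).

## Reproducibility and budgets

All randomness is seeded: behavior sequences and tracks via an internal
seed-scoped RNG, the integrator via its own 64-bit generator, and batch
runs derive per-trial seeds from the batch seed.  The acceptance batches
are scaled down to about 20 trials per condition (the source used ~200);
FWHM-type values are therefore compared at scaled-down tolerance.
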