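# ringmem

Spatial orientation working memory in *Drosophila*: a spiking
ring-attractor model of the ellipsoid-body/protocerebral-bridge (EB-PB)
circuit, driven by a Markov-chain locomotor model, together with the
Buridan-arena trajectory statistics used to quantify landmark fixation in
free-walking flies.

## The problem

A fly walking between two opposing visual landmarks keeps fixating their
directions for tens of seconds after the landmarks disappear — a working
memory of orientation.  The head direction is carried by a localized
"bump" of activity in the torus-shaped ellipsoid body.  Two EB-PB
subcircuits support it: a stabilizing **C circuit** (EIP–PEI, a ring
attractor) and a shifting **P circuit** (EIP–PEN), gated by GABAergic ring
neurons — EIP-ring neurons set the bump width by global inhibition, P-ring
neurons silence the shifter during straight walking, C-ring neurons
silence the stabilizer during body rotation.  Suppressing or
photoactivating the ring-neuron populations produces distinct memory
deficits; this package reproduces those circuit-level phenotypes and
implements the behavioral measures used to score the arena task.

For whom: computational neuroscientists working on head-direction/compass
circuits, and anyone analyzing Buridan-paradigm trajectory data who needs
the fixation statistics (performance index *PI*, fixation strength *FS*,
deviation angle σf) with a tested, scriptable implementation.

## The statistics at the core

For a 12-quantile movement-direction histogram p(θ) (paired so that
opposed quantiles share their mean):

* **Fixation density** FD = fraction of 5-s epochs with
  p(0°)+p(180°) > 1/6; **PI** = FD(poststimulus) − FD(prestimulus);
  estimated memory duration = PI × poststimulus duration.
* **Fixation strength** minimizes the second moment
  M(σ) = Σ p(θᵢ)² sin²(θᵢ−σ) in closed form
  (sin(2σ+φ)=0, cos φ = A/K, sin φ = B/K); σf is the minimizing axis and
  FS = 1 − M_min/M_max, with significance criterion
  0.1090 = control mean + 2 SD.
* **Bump metrics**: presence (contiguous super-half-max arc), circular-mean
  position, FWHM of the time-averaged bump-aligned profile, heading-bump
  deviation of unwrapped accumulated angles, and bump-loss fraction.

## Worked example

```r
library(ringmem)

## one wild-type trial: 60 s landmark on + 90 s landmark off
tr <- run_trial(protocol_spec("wildtype"), seed = 42)
trial_metrics(tr)
#>   condition seed present_stim present_post fwhm_rad mean_deviation_deg bump_lost
#> 1  wildtype   42        0.917        0.997     2.10                343     FALSE
```

The bump is detectable in ~92-100% of 100-ms bins through both stages, is
never absent for 2 s or longer (`bump_lost = FALSE`), and its
time-averaged, bump-aligned full width at half maximum is 2.10 rad for
this seed (the 20-trial batch average at seed 1 is 2.05 rad; the
reference value is 1.86 rad).  Suppressing the EIP-ring neurons
(−0.04 nA) widens the batch-average bump to 2.25 rad (reference
2.04 rad), while P-ring suppression (−0.25 nA) spreads activity over the
whole ring and no bump is detected at all.

```r
## synthetic Buridan cohort with landmark fixation and memory
coh <- synth_cohort(10, synthetic_fly_params(
  fixation_bias = c(pre = 0, stim = 0.6, post = 0.4), seed = 1))
pis <- sapply(coh, function(tk) analyze_track(tk)$PI)
round(mean(pis), 2)
#> [1] 0.21
```

A cohort that aims 60% of its turns at the landmarks while they are
visible and 40% afterwards shows a positive performance index — the
synthetic analogue of orientation memory; an unbiased cohort gives
PI ≈ 0.

## Command-line entry points

Thin wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --condition eip_suppress --n-trials 5 --seed 1 --out out/
Rscript inst/cli/synth.R --preset wildtype-like --n 10 --seed 1 --out tracks/
Rscript inst/cli/analyze.R --track tracks/track001.tsv --out analysis/
```

See `vignettes/ringmem-methods.Rmd` for the model equations, calibration
rationale, and known limitations (notably: the reduced-size shifter tracks
body rotation in the correct direction but below the real rotation speed,
so heading-bump deviations are dominated by that shared tracking deficit).
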