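# aldnp

Differential divisive-normalization models of odor information processing
in the *Drosophila* antennal lobe.

## What this is for

The insect antennal lobe receives a population code in which odorant
*identity* (the per-receptor affinity vector **b**⊘**d**) is multiplied by
the *concentration waveform* u(t), and appears to return the two factors
separately: projection-neuron (PN) responses decompose into a
concentration-invariant steady component plus ON/OFF transients marking
odor onset and offset. `aldnp` is for computational neuroscientists who
want to simulate, fit and stress-test circuit models of that computation.

At the core is the **differential Divisive Normalization Processor (DNP)**,

```
dx/dt = α·T[v]·(1 − x) − β·x − κ·N·x ,
```

a gating variable whose normalizer N is either the gate itself (feedback)
or a transform of the input (feedforward). Run across R channels with a
pooled normalizer (the *global* variant), its steady state in the strong
normalization regime κ ≫ α, β is

```
x_r(∞) ∝ a_r / Σ_q a_q        (a = affinity vector, independent of u),
```

a concentration-invariant recovery of odorant identity — which degenerates
to the constant 1 for a single channel. The package provides:

* **stimuli** — concentration staircases with optional white noise,
  binding/dissociation identities, synthetic affinity panels, the
  concentration contrast d/dt log(ε + u);
* **dnp** — feedback/feedforward and global DNP integrators plus their
  closed-form steady states;
* **neurons** — noisy Connor–Stevens spike generators, F–I curves and
  their monotone inverse, spike detection, limit-cycle extraction;
* **circuits** — the 23-parameter single- and multi-channel antennal-lobe
  circuits with five presynaptic-inhibition architectures, co-integrated
  in compiled code at dt = 0.1 ms;
* **signal** — PSTH estimation (200 ms windows, 100 ms overlap),
  steady/transient ON/OFF decomposition, angular distance, SNR,
  cross-correlation, step-amplitude CV;
* **optimize** — angular-distance pathway objectives with the
  axon-terminal saturation constraint, correlation-screened Latin
  Hypercube screening and Differential Evolution refinement;
* **pseudo_physiology** — a synthetic stand-in for the unavailable
  Or59b/DM4 recordings, with PSTH → current targets via F–I inversion;
* **experiments** — identity-recovery panels, five-architecture
  comparison, ON/OFF noise-robustness, all seeded and reproducible.

Functions take and return tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(aldnp)

stim  <- reference_staircase()                      # 0→100→0→500→0→1000→0 ppm
odor  <- odorant_identity("acetone-like", b = 0.005, d = 1)
osn   <- osn_frontend(stimulus_drive(odor, stim), seed = 1)
traces <- simulate_single_channel(default_circuit_params(), osn, seed = 1)
traces
#> <al_traces> single_channel: R = 1, duration = 5.85 s, dt = 1e-04 s
#>   PN spikes: 342 (58.5 Hz/channel)

psth  <- traces_psth(traces)
jumps <- detect_jump_times(stim)
dec   <- decompose_response(psth_interpolate(psth, stim$time_s)[1, ],
                            jumps$time_s, dt = 1e-4)
round(attr(dec, "segments"), 1)
#> [1]  34.1  97.5  21.5 123.0  15.6 128.5  25.0
```

The segment amplitudes alternate between spontaneous baseline (low values)
and the PN's steady firing level during the three odor plateaus. Across
the tenfold concentration range 100 to 1000 ppm the plateau rates move
only from 97.5 to 128.5 Hz (the 500 and 1000 ppm plateaus differ by under
5%) — the concentration invariance the presynaptic normalization provides;
the OSN input rates over the same segments run 86, 118.5 and 127.5 Hz on
top of a much stronger baseline.

Fitting a pathway against the synthetic reference recording:

```r
ref  <- generate_reference(waveform = stim, seed = 1)
spec <- objective_spec("preln", ref$target_I_OP, ref$osn_spikes,
                       stimulus = stim, mask = ref$valid)
fit  <- two_step_fit(spec, seed = 7)
fit
#> <al_fit> pathway: preln
#>   best objective (angular distance): 0.08642
#>   max axon-terminal gating: 1.063e-06 (constraint satisfied)
```

## Acceptance script

`scripts/acceptance.R` regenerates the headline quantity from scratch with
the installed package: it builds the pseudo-physiology reference on the
three-level staircase, runs the constrained two-step fit of the Pre-LN
pathway at the desk budget, re-simulates the returned parameters and
reports the maximum axon-terminal gating. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command-line interface

`inst/exec/al-experiments.R` wraps the experiment functions
(`simulate`, `fit`, `panel`, `compare-arch`, `noise-robustness`,
`make-fixtures`) with `--seed`, `--out` and `--full` flags, writing CSV
tables.

## Notes

The methods vignette (`vignettes/antennal-lobe-dnp.Rmd`) documents the
model equations, numerical scheme, the spike-train convention and its
rationale, the synthetic reference world, and the known limitations —
including two acceptance properties that are honestly not met in this
synthetic world and why.
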