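---
title: "Modelling glutamate spillover in a probabilistic synaptic environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glutamate spillover in a probabilistic synaptic environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the modelling strategy

Glutamate released by a synapse is rapidly bound by high-affinity
transporters (GLT-1/EAAT2) carried on perisynaptic astroglial processes.
Whether meaningful amounts nonetheless escape to activate high-affinity
receptors — NMDA receptors in particular — half a micron or more away depends
on two things that classical "average-medium" models wash out: the highly
variable geometry of the perisynaptic neuropil, and the fact that a bound
glutamate molecule is not necessarily taken up — a substantial fraction is
released back into the extracellular space before translocation.

`gluspill` models both. The neuropil around one synapse is generated *anew
for every run* as a random packing of overlapping spheroids, each labelled a
neuronal or an astroglial element; glutamate molecules are independent
Brownian walkers that reflect off all surfaces, can bind while dwelling near
astroglial surfaces, and can unbind again a few milliseconds later.
Averaging readouts over many such stochastic environments preserves the
contribution of rare transporter-free escape routes instead of chiselling
them away into a homogeneous effective medium.

## Environment generation

The arena is a cube (default 4 µm edge) centred on the release site. The
synaptic apposition is a 250 nm diameter structure: two solid hemispheric
obstacles (pre- and postsynaptic elements) separated by a 20 nm high
extracellular cleft; release is confined to the central 120 nm wide, 20 nm
high cylinder. Geometrically, obstacles plus cleft form a spherocylinder
(capsule) whose central slab is void.

Spheroids with radii uniform on [50, 300] nm (the size range of cellular
elements in 3D electron-microscopic reconstructions) are placed with uniform
random centres, rejecting any whose surface would come within 10 nm of the
cleft volume. Placement stops when a running Monte Carlo estimate of the
extracellular volume fraction α — the fraction of fixed internal test points
(default 2 × 10⁵) not covered by any solid — first reaches its target. The
per-sphere increment of the covered fraction is a few 10⁻⁴, so the overshoot
past the target is well inside the ±0.01 acceptance tolerance.

Roles are then assigned. Each spheroid is first labelled astroglial by an
independent Bernoulli draw at probability VF~astro~/(1 − α) (the ratio of the
target astroglial volume to the total occupied volume); because spheroids
overlap and vary in size, the realised astroglial share is then corrected by
greedy label flips — each test point is owned by the spheroid containing it
most deeply, and labels are flipped until the owned astroglial point share is
within a fifth of the tolerance of VF~astro~. The deepest-containment
ownership rule (ties to the lowest spheroid index) is used identically for
test points, shell volumes and classification queries, so all volume
estimates are mutually consistent.

Defaults follow the hippocampal (CA1) parameter set: α = 0.2, VF~astro~ =
0.1; the explored ranges are α ∈ [0.1, 0.3] and VF~astro~ ∈ [0.05, 0.3]
(0.3 being the cerebellar value).

## Brownian dynamics and collisions

Free molecules take isotropic Gaussian steps with per-axis variance 2 D dt,
with D = 0.5 µm²/ms (time-resolved fluorescence anisotropy measurements of
extracellular diffusivity in brain tissue). Every step segment is tested
against all reachable surfaces; the earliest crossing is mirror-reflected
about the tangent plane at the hit point, iterating up to eight reflections
per step. Astroglial spheroids reflect exactly like neuronal ones — binding
is a bookkeeping event, not an absorbing boundary. Arena walls are
reflective by default; an "open" mode instead flags leavers as escaped.
Tortuosity is therefore an *emergent* property of the obstacle packing, not
an imposed factor.

Numerical choices:

* **Time step.** Default dt = 2 × 10⁻⁵ ms, giving an rms 3D step of
  ~7.7 nm, comparable to the 5 nm transporter-contact shell; a guard refuses
  steps whose rms displacement exceeds twice the contact cutoff whenever
  binding is active. In obstacle-free settings (calibration of the free
  diffusion coefficient, point-source validation) the increments are exact
  for any dt, and coarser steps are used for speed.
* **Step-length clamp.** Individual 3D steps are rescaled to at most
  3.5 × rms (exceedance probability ≈ 5 × 10⁻⁸ per draw), which lets a
  uniform spatial hash guarantee that no surface can ever be jumped past
  undetected.
* **Degenerate reflections.** If a reflection cascade has not settled after
  eight iterations (a grazing hit on an edge, roughly one step in 10⁶ at
  baseline), the particle reverts to its pre-step position and the event is
  counted on the run object (`n_rejected_moves`) rather than aborting a long
  simulation. The stand-alone `resolve_collisions()` surface, intended for
  interactive use, does raise an error in that case, since there it signals
  a time step too coarse for the geometry.
* **Reproducibility.** Every particle owns a counter-derived sub-stream of a
  fast deterministic generator (xoshiro256++ seeded via splitmix64), so runs
  are bit-identical for a given seed on any platform, and paired conditions
  (unbinding on/off under one seed) give each particle identical diffusion
  noise until its own binding fate diverges.

## Transporter binding and unbinding

While a molecule stays within 5 nm of an astroglial surface, binding follows
the classical first-order lifetime expression P(t) = 1 − exp(−t/Ψ) in
continuous contact time t; the contact clock resets once the molecule departs
beyond 5 nm. Sampling uses the per-step incremental hazard
1 − exp(−dt/Ψ), which reproduces the cumulative expression exactly and makes
the binding statistics independent of the step size. Ψ (default 1 ms, the
value obtained by calibrating the simulated bound-glutamate spatial profile
against an imaged reference profile, over a 0.1–10 ms grid) lumps transporter
affinity, surface density and surface proximity into one time constant.

Each binding event draws a fate once: with probability P~unbind~ = 0.35 the
molecule will be released back into the extracellular space; otherwise it is
retained for the rest of the run (translocation into the astrocyte takes tens
of milliseconds, far beyond the ≤10 ms simulated window, and is not
modelled). Release times follow the S-shaped cumulative-Gaussian schedule
with median 4 ms and spread 2 ms after binding. The delay is drawn as
max(0, N(4, 2²)) — *left-censoring* rather than resampling the ~2.3% negative
mass — because censoring preserves the stated schedule exactly for every
positive time: the CDF still crosses 0.5 at 4 ms and equals Φ(−1) at 2 ms.
Released molecules reappear at their binding position (the transporter does
not move them sideways), with a reset clock, free to bind again.

A consequence of using the exact hazard deserves emphasis. Sampling with the
incremental hazard makes binding statistics step-size independent and equal
to 1 − exp(−t/Ψ) in accumulated contact time — but accumulated 5 nm contact
is scarce for a Brownian walker in this geometry (on the order of 0.1 ms
over a 9 ms run at baseline), so with Ψ = 1 ms only a modest fraction of
molecules ever bind. The paired unbinding-on/off contrast therefore has a
robust *sign* — the test suite finds distal free glutamate and NMDAR
activation greater-or-equal in the unbinding arm in every paired comparison
— while its *magnitude* at 0.5–1 µm is a few percent at these defaults. A
formulation that instead re-tests the cumulative P against a fresh uniform
draw at every step (a reading the phrase "computed at every time step"
also admits) approaches absorption-on-contact at small dt and would push the
model into a strong-binding regime with a much larger unbinding effect; it
is, however, step-size dependent, and this package deliberately implements
the exact hazard instead.

Two readout conventions follow from this model. "Bound" concentration counts
both release-scheduled and retained molecules, since both remain physically
transporter-bound throughout a run. And the unbinding-off condition
(P~unbind~ = 0) leaves every bound molecule bound forever, which is the
contrast arm used throughout.

## Concentration profiles

Molecule counts are tallied in 20 nm concentric shells around the release
site at the recorded times. Each shell's extracellular volume is estimated
per realisation by stratified Monte Carlo: points uniform within the analytic
shell are classified against that realisation's geometry, so near-cleft
heterogeneity is captured rather than assumed away; shells are clipped to the
arena automatically. Absolute molarity is
`scale_factor × count / (N_A × V_EC)`; the default scale factor 3 maps 1000
simulated walkers onto the ~3000 glutamate molecules of an average synaptic
vesicle, valid because the ~12 000 transporters per µm³ of hippocampal
neuropil make the supply effectively non-saturating, so concentrations scale
linearly in molecule count. Profiles are averaged across runs (each with its
own fresh environment) with the across-run SEM; shells with zero estimated
extracellular volume but non-zero counts are flagged rather than dropped.

For Ψ calibration, both the simulated bound-glutamate profile at 4 ms (near
the binding peak) and the reference profile are normalised to unit peak
before least squares, because only the *shape* of a fluorescence profile is
comparable to a concentration profile; the fit uses the overlapping distance
range with uniform weights. The package ships no experimental curve: the
reference generator (`synthetic_reference_profile()`) produces
simulation-derived stand-ins at a known Ψ, which is what the calibration
tests recover. Passing those tests demonstrates parameter recoverability,
not agreement with any real imaging data.

## NMDA receptor kinetics

The receptor model is the standard five-state scheme — unbound, single-bound,
double-bound, desensitised, open — with both binding steps driven by
kon × [glu]. Rate constants ship in a plain-text parameter file
(`inst/extdata/nmdar_5state.csv`, the published set of the cited kinetic
model: kon = 5 /mM/ms, koff = 0.0129 /ms, kd = 0.0084 /ms, kr = 0.0068 /ms,
ko = 0.0465 /ms, kc = 0.0738 /ms) and can be swapped without touching code.
No Mg²⁺ block or voltage dependence is modelled: the activation readout is
by construction the no-block limit, and "double occupancy" (C2 + D + O, all
doubly-liganded states) is emitted alongside open probability since a doubly
occupied ("tagged") receptor opens on depolarisation without further
glutamate.

The linear ODE system is integrated with `deSolve::lsoda` at rtol = atol =
10⁻⁸, driven by the simulated free-glutamate transient at a given shell
(linearly interpolated; held at zero — or optionally its last value — beyond
the simulated window) over a 300 ms window so that slow post-transient
dynamics are visible from a ~10 ms transient. Probability conservation along
the trajectory is monitored and stays below 10⁻⁷.

One caveat discovered while characterising the metric: with these published
rate constants the doubly-liganded pool has a slow decay tail (the
desensitised state exchanges with C2 at 0.0068–0.0084 /ms while the pool
drains only via koff), so a *5%-of-peak* tag-duration threshold lands in the
several-hundred-millisecond range for any brief transient, saturating the
300 ms window. The 150–250 ms tagging window commonly associated with this
scheme corresponds to roughly the *half*-of-peak duration, which the test
suite checks separately. The threshold is a user parameter
(`threshold_fraction`).

## Experiment orchestration and scales

`run_experiment()` runs conditions × runs with seeds derived from one master
seed via iterated Lehmer mixing (`derive_seed(master, condition, run,
module)`), writes per-run and aggregated CSVs plus a YAML manifest, and is
byte-reproducible for a given config and seed. `paired_conditions()`
duplicates each (α, VF~astro~) condition into unbinding-on/off arms whose
seeds deliberately exclude the unbinding flag, giving shared environments
and per-particle noise — the variance-reduced contrast behind the
activation-ratio analyses.

Default problem sizes are the package's desk-scale choices: 1000 particles,
5–10 runs per condition, 9–10 ms of system time at dt = 2 × 10⁻⁵ ms, 2 × 10⁵
internal generation points, 10⁵–10⁶ volume test points. The test suite runs
reduced versions of everything except the paired baseline contrast, which it
runs at 1000 particles × 5 paired runs.

## What the synthetic world does and does not capture

The generator emulates measured bulk statistics — extracellular and
astroglial volume fractions, element size range, cleft dimensions — and the
probabilistic variability of the perisynaptic space. It does not emulate
real cell morphologies (dendritic spines, astroglial leaflets, sheets and
dead ends), spatial correlations between astroglial processes and synapses,
transporter surface density variation, or any optical readout physics
(sensor kinetics, point-spread function). Green tests therefore certify the
algorithmic properties of the model — exact binding statistics, emergent
tortuosity, conservation, reproducibility, parameter recoverability — not
fidelity to any particular tissue. Known limitations worth keeping in mind:
spheroids are a coarse stand-in for cellular shapes; transporter supply is
non-saturating by assumption; unbinding probability 0.35 is an estimate with
an uncertain upper range; and the ≤10 ms window excludes slower uptake
dynamics entirely.
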