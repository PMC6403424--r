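---
title: "Modelling heat-fuelled helical polymerization of supramolecular toroids"
author: "toroidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat-fuelled helical polymerization of supramolecular toroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toroidyn)
```

## The system and the model

`toroidyn` models a dissipative supramolecular polymer: ring-shaped
(toroidal) assemblies of a chiral aromatic macrocycle that are inert at
equilibrium, are *activated* by a brief heat pulse into a kinetically
trapped packing, and then transiently polymerize into micrometre-scale
helical chains before collapsing back to intact toroids as the stored
energy dissipates. The same cycle, run inside lipid vesicles, converts
chemical-conformational energy into mechanical shape change
(sphere-to-tubule elongation and back), in analogy with microtubule
dynamic instability.

The kinetic model is a continuous-time Markov jump process over four
kinds of matter, with all times in days, concentrations in µM and
lengths in nm:

* **inactive** free toroids (eclipsed packing, the equilibrium state),
* **active closed** free toroids (slipped packing, kinetically trapped),
* **active open** free toroids (one-turn open spirals with two reactive
  ends),
* **helical chains**, represented by their integer lengths in toroid
  units (every in-chain subunit is active by construction).

Seven reaction channels act on this state; they group into the three
dynamic processes the cycle is built from:

1. **Activation and relaxation.** A heat pulse instantaneously converts
   a fraction `activation_efficiency` (default 1) of the inactive pool
   to active closed toroids; it is modelled as an event because the
   20-minute treatment is three orders of magnitude shorter than the
   day-scale dynamics. Active closed toroids relax back to inactive
   with first-order rate `k_relax_free`. Active closed and open
   interconvert with rates `k_open`/`k_close`; their ratio is the
   single-toroid open/closed equilibrium constant, fixed at
   `5.5e-3`. Free open toroids do not relax directly — the open spiral
   is a high-energy conformation whose relaxation pathway runs through
   closing first; a direct channel would in any case be unidentifiable
   from the observables.
2. **Cooperative growth.** Two open spirals nucleate a dimer chain
   (`k_nuc`, slow); chain ends add open toroids (`k_el`, fast —
   `k_el/k_nuc` is the cooperativity that produces the lag phase) and
   chains join end-to-end (`k_join`). Chain ends are treated as
   equivalent and saturating, so elongation propensity scales with
   (number of chains × open count) and joining with distinct chain
   pairs: the simplest laws consistent with end-to-end connection.
3. **Collapse.** Each in-chain subunit relaxes independently at rate
   `k_relax_chain`, much smaller than `k_relax_free` because helical
   neighbour-turn contacts stabilize the trapped packing. A relaxed
   subunit leaves immediately as one inactive toroid and severs the
   chain at its (uniformly random) position — there is no latent-defect
   bookkeeping, which keeps chains representable as bare lengths.
   Length-1 fragments re-enter as open monomers; length-0 fragments
   vanish. UV irradiation lowers the barrier between the packings, so a
   UV pulse is a finite window (default 5 minutes) in which both
   relaxation rates are multiplied by `uv_factor`.

Total toroid units are conserved by every channel; this is asserted
exactly, at every snapshot, in the stochastic engine's tests.

## Two engines, one network

The **stochastic engine** (`ssa_simulate()`) is an exact
direct-method Gillespie simulation: exponential waiting times,
propensity-proportional channel choice, with the per-chain channels
aggregated by class and a second draw selecting the chain and site —
this avoids a per-chain channel explosion. The inner loop is compiled;
a pure-R engine implementing the identical channel semantics
(`engine = "R"`) is kept as the reference implementation, and the two
are cross-checked exactly on propensities and statistically on
trajectories. All randomness flows from R's seeded generator, so
identical inputs and seed reproduce bit-identical trajectories.

The **mean-field twin** (`ode_simulate()`) integrates the
length-resolved master equation for chain concentrations
`c_n, n = 2..n_max`, with the scission term producing the uniform
fragment kernel (each fragment length `0..n-1` at rate
`2 k_relax_chain c_n`) and joining as a self-convolution, evaluated by
padded FFT. It serves as the smooth backend for fitting and as an
independent oracle for the stochastic engine: on the default
calibration, the 20-replicate ensemble mean stays within statistical
error of the deterministic solution across the full 15-day horizon.

Numerical choices that matter:

* **Integrator.** The default is the Jacobian-free Adams method. The
  system's stiffest scales (`k_close`, early per-chain elongation)
  force step sizes near 10^-2^–10^-3^ days for any non-implicit method,
  but the right-hand side is cheap; stiff solvers with dense
  finite-difference Jacobians over thousands of length bins cost far
  more than the step-count they save. Integration failures (including
  early returns on excessive work) are hard errors, never silently
  truncated output.
* **Truncation.** `n_max` defaults to 3000 units; flux past the
  boundary drains into an absorbing *leak* bin that is reported and
  bounded (default 10^-3^ of total units; exceeding it is an error
  telling you to raise `n_max`). For the fitting objective a
  *reflecting* truncation is used instead (boundary chains stop
  elongating, over-long pair joins are rejected): it conserves units
  exactly and, at `n_max = 1000`, reproduces the open system's
  observables to better than 1% while integrating a third of the
  state.
* **Quasi-stationary open pool.** In the fitting objective only, the
  open-spiral concentration is taken as
  `O* = k_open A / (k_close + k_el C)` and its sub-percent mass folded
  into the closed pool. This removes the fastest modes and makes each
  objective evaluation ~7× cheaper; the approximation is validated
  against the full dynamics in the tests (mean observables agree to
  ~1%).

## Calibrated default parameters

The absolute rate constants of the laboratory system are not published;
the shipped defaults are calibration products of this package, produced
by sweeping stochastic ensembles against the reference behaviours of
the 30 µM single-fuel experiment and then frozen:

| parameter | default | units | anchored by |
|---|---|---|---|
| `k_open/k_close` | 5.5×10⁻³ | — | single-toroid open/closed equilibrium constant |
| `k_open` | 0.8 | 1/day | growth-flux magnitude: mean length peaks near day 4 |
| `k_relax_free` | ln(20)/20 ≈ 0.15 | 1/day | first-order CD recovery to 5% of the post-pulse value in 20 days (exact by construction) |
| `k_relax_chain` | 0.07 | 1/day/subunit | ~7-day depolymerization phase; sustained CD under 4-day refuelling |
| `k_nuc` | 0.7 | 1/(µM day) | short (~1 day) lag before rapid growth |
| `k_el` | 6000 | 1/(µM day) | monomer capture fast against closing; cooperativity `k_el/k_nuc` ≈ 8600 |
| `k_join` | 220 | 1/(µM day) | scission/joining balance sets the day-4 chain-length scale (longest chains ~1 µm; DLS proxy ~250 nm) |
| `uv_factor` | 2×10⁴ | — | complete (≥95%) depolymerization within the 5-minute UV window |
| `activation_efficiency` | 1 | — | repeated cycles without loss of response |

Joining turned out to be essential, which settles an open modelling
question: with per-subunit scission active during growth, an
elongation-only model fragments chains faster than nucleation-limited
growth can extend them, and the day-4 population never reaches the
several-hundred-unit lengths the light-scattering signal implies. A
scission/joining balance (`C* ≈ sqrt(k_relax_chain · M / k_join)` in
concentration units) sustains long chains while energy lasts and lets
them collapse once the free active pool is spent.

The desk scale maps 30 µM onto 10⁴ toroid units (so one unit is
3×10⁻³ µM in an effective volume of ~5.5×10⁻¹⁶ L); this keeps exact
stochastic simulation fast while keeping sampling error quantifiable.
Ensembles of 20 replicates are used for headline quantities.

## Observable proxies

* **Mean assembly length** is reported in two conventions:
  `all_assemblies` (every object counts, free toroids as length 1 — the
  package's default trajectory observable, matching micrographs in
  which toroids and chains are both visible) and `chains_only` (the
  average measured chain length, the convention of the cryo-TEM
  averages; calibration uses this one).
* **CD proxy**: affine in the fraction of subunits in the chirally
  slipped (active) packing. It is intensive — invariant to system size
  at fixed composition — which is exactly why the relaxation decay it
  reports is concentration independent while polymerization is not.
* **DLS proxy**: intensity-weighted mean hydrodynamic diameter; spheres
  (12 nm) for free toroids and the standard short-rod approximation
  `D_h = L/(ln(L/d) + 0.32)` for chains (`L = n × pitch`, `d = 12` nm),
  spliced below its minimum (`L < d e^{0.68}`) to `max(d, L)` so the
  proxy stays continuous and monotone for stubby helices. Weights are
  proportional to squared assembly mass — the simplest DLS-like
  weighting. Both rules are documented approximations; only the
  12 nm → few-hundred-nm trend is meaningful, and the day-4 check is
  accordingly read with a generous (±30%) band.
* **Cryo-TEM sampler**: draws objects with probability proportional to
  their number, applies multiplicative log-normal measurement noise
  (default sd 0.1 on the log scale — lengths are positive and relative
  error is the realistic model), and reports lengths via the geometry
  map (monomer = 12 nm diameter; chain = `n × pitch`).

## Geometry

A toroid is a closed circle of centerline radius
`(external_diameter − tube_diameter)/2`; the helix built from `n` units
concatenates `n` one-turn spirals of that radius along the z axis with
rise `pitch` per turn. Only the 12 nm external diameter is an observed
quantity; tube diameter (3 nm) and pitch (= tube diameter, close-packed
turns) are exposed assumptions. The helix diameter is therefore
invariant in `n` — the quantitative image of the observation that the
helix retains the toroidal curvature — and handedness follows the
enantiomer: S builds right-handed (+ torsion), R left-handed, and the
racemic mixture (chirality 0) refuses to build, mirroring the racemic
control that cannot polymerize.

A vesicle of resting diameter 500 nm (the extrusion pore size)
containing a growing chain is modelled as a spherocylinder whose total
length equals the encapsulated rod length, under conserved membrane
area (lipid area is nearly inextensible on these timescales; water
permeates, so volume is free). That constraint has the closed form
`r = A₀/(2πL)` — a 1000 nm rod in a 500 nm vesicle gives cap radius
125 nm and aspect ratio 4 — and recovery after depolymerization returns
the area-equivalent sphere. A fixed-volume mode is provided as an
alternative; both report infeasibility (with the maximum supportable
rod length) if the required cap radius falls below a bilayer-scale
minimum.

## Calibration and identifiability

`calibrate()` fits free rates (log₁₀ scale, L-BFGS-B, deterministic
multi-start) by weighted least squares between a dataset (mean chain
length in nm, optional CD trace) and the mean-field solution, with
`k_open/k_close` pinned to the equilibrium ratio throughout — only the
ratio is constrained by the data, so `k_close` is never estimated. The
CD trace enters through its best affine map onto the model active
fraction (baseline and amplitude profiled out in closed form), making
the fit invariant to CD units. Two robustness choices matter for small
samples: per-time standard errors are floored at 5% of the signal
range (a 100-object sample that happened to miss every rare long chain
otherwise reports a misleadingly tiny error around the monomer length
and can drag the fit to a no-polymer corner), and trial rates whose
fastest time scale the integrator cannot resolve are rejected with a
flat penalty rather than integrated.

`parameter_recovery_report()` closes the loop end-to-end: simulate
noisy synthetic datasets from known rates, refit from deliberately
displaced starting values (×3 / ÷3 alternating), and demand that each
estimated parameter's median lands within a factor of 2 of the truth.
The default free pair is the identifiable core: `k_join` sets the
chain-length scale of the scission/joining balance and
`k_relax_chain` the collapse kinetics. `k_el` is deliberately not in
the default recovery set: above the threshold where monomer capture
saturates (`k_el · C ≫ k_close`), the observables respond only weakly
to it — a genuine, structural non-identifiability, reported rather than
hidden.

## What the synthetic data do and do not emulate

`generate_dataset()` reproduces the *statistical structure* the
analysis assumes: per-time cryo-TEM length samples (n = 100) with
multiplicative noise, an affine CD trace with additive noise, a DLS
trace with relative noise, and stored ground truth with bit-identical
regeneration from metadata. It does not emulate micrograph images,
spectra, autocorrelation functions, aggregation beyond the model's
species, or any instrument drift; passing the recovery tests therefore
demonstrates internal consistency of model + estimator under the
assumed noise, not that the model is correct for real data.

## Known limitations

* Absolute rates are calibration products; only their anchored
  combinations (equilibrium ratio, relaxation time, cycle timings) are
  meaningful.
* The mean-field twin slightly overestimates early growth at desk
  scale (it factorizes pair correlations; the `C(C−1)/2` vs `C²/2`
  difference is visible as a ~2σ systematic at 10⁴ units).
* The DLS and hydrodynamic rules are textbook short-rod approximations,
  not instrument models.
* Chains are unbranched and sequence-free; there is no spatial or
  diffusive structure, no temperature-continuous kinetics (pulses are
  events), and vesicle mechanics is a dimensional response, not a
  bending-energy minimization.
* The second cycle of a repeated-fuel experiment starts from whatever
  short helices survived the first collapse; they act as seeds, so the
  *all-objects* mean length overshoots cycle 1 by ~30% while the mean
  *chain* length — the quantity the imaging averages track — repeats
  within 10%. The cycle-invariance checks use the latter.

## Reproducing the headline numbers

`scripts/acceptance.R --seed N --out results/acceptance.json`
recomputes, from a fresh installation: the stationary open/closed ratio
of the isolated two-state subsystem (10⁵ toroids), the helix diameter
invariance (1/10/100 units), the peak time and depolymerization
duration of the calibrated 20-replicate ensemble (10⁴ units, daily
recording, 15 days), the analytic-plus-ODE CD recovery time, and the
day-4 intensity-weighted hydrodynamic diameter. The test suite runs the
same checks plus the full property battery at the same problem sizes.
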