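# toroidyn

Kinetic modelling of **heat-fuelled, out-of-equilibrium helical
polymerization of supramolecular toroids** — a synthetic counterpart of
microtubule dynamic instability.

The system: ring-shaped (toroidal) assemblies of a chiral aromatic
macrocycle are inert at thermodynamic equilibrium. A short heat pulse
traps their stacking in an activated (slipped) packing; activated
toroids transiently open into one-turn spirals, nucleate slowly,
elongate and join rapidly into helical chains up to a micrometre long,
and then — as each in-chain subunit relaxes and severs its chain — the
polymers collapse back to intact toroids. Refuelling every few days
sustains the active state; UV light quenches the chains in minutes.
Inside a lipid vesicle the growing chain stretches the sphere into a
tubule and depolymerization restores it.

`toroidyn` is for modellers of dissipative supramolecular assembly who
want a tested, reproducible implementation of this cycle: an exact
stochastic simulator, its deterministic master-equation twin,
observable proxies (CD, DLS, cryo-TEM statistics), helix/vesicle
geometry, parameter calibration, and a synthetic-data generator.

## The model

State: counts of inactive `I`, active closed `A`, active open `O` free
toroids plus the multiset of chain lengths (toroid units). Channels
(times in days, concentrations in µM):

| process | channels | rates |
|---|---|---|
| activation | heat pulse: `I -> A` (fraction `activation_efficiency`) | event |
| conformer exchange | `A <-> O` | `k_open`, `k_close` (ratio fixed at 5.5e-3) |
| relaxation | `A -> I` | `k_relax_free = ln(20)/20` /day |
| nucleation | `O + O -> chain(2)` | `k_nuc` |
| elongation | `chain(n) + O -> chain(n+1)` | `k_el` (`k_el/k_nuc >> 100`: cooperative) |
| joining | `chain(n) + chain(m) -> chain(n+m)` | `k_join` |
| scission | per in-chain subunit: sever at the relaxed toroid | `k_relax_chain` /day/subunit |
| UV window | both relaxation rates × `uv_factor` | event window |

Exact SSA (`ssa_simulate`, compiled, with a pure-R reference engine)
and a length-resolved mean-field ODE (`ode_simulate`, deSolve, FFT
joining convolution) implement the same network and are cross-validated
against each other. Total toroid units are conserved exactly.

## Worked example

Simulate the reference experiment — 30 µM toroids (desk scale: 10,000
units), one heat pulse, 15 days — and look at the cycle:

```r
library(toroidyn)

ens <- run_ensemble(20, seed_base = 1, initial_state(1e4, 30),
                    default_params(), single_fuel(), t_end = 15,
                    record_times = 0:15)
ens
#> toroid_ensemble: 20 replicates, seeds 1..20
#>   peak ensemble-mean assembly length 2.47 units at t = 4 d

s <- ens$summary
round(s[s$time %in% c(0, 1, 4, 8, 15),
        c("time", "mean_length_units", "mean_length_chains",
          "active_fraction", "dls_nm")], 3)
#>    time mean_length_units mean_length_chains active_fraction  dls_nm
#> 1     0             1.000              1.000           1.000  12.000
#> 2     1             1.355            122.678           0.869 180.895
#> 5     4             2.467            174.208           0.656 273.550
#> 9     8             1.937            154.959           0.489 247.217
#> 16   15             1.427            117.876           0.302 195.966
```

Reading the numbers: the mean assembly length (all objects, toroid
units) rises from 1 (all monomers) to its peak at **day 4** and decays
back over the following week; the mean *chain* length jumps to ~150
units (~450 nm) as soon as chains exist and the intensity-weighted DLS
proxy grows from 12 nm to ~250–280 nm at the peak — the chains carry
most of the mass. The active fraction (the CD proxy) decays first-order
on the 20-day relaxation scale, reaching ~0.65 at day 4.

Geometry and the vesicle response:

```r
h <- build_helix(toroid_geometry(chirality = 1), 100)
h
#> helix_model: 100 turn(s), right-handed, external diameter 12 nm,
#>              axial length 300 nm

vesicle_shape(1000, sphere_diameter = 500)
#> vesicle_shape (fixed_area): cap radius 125 nm, cylinder 750 nm,
#>                             total 1000 nm, aspect 4
```

Calibration against a time series (here the shipped model-generated
calibration curve):

```r
ds <- read.csv(system.file("extdata", "default_calibration_synthetic.csv",
                           package = "toroidyn"))
fit <- calibrate(ds, free = c("k_nuc", "k_el", "k_relax_chain"),
                 n_max = 400, maxit = 10)
fit
#> Calibrated toroid polymerization model
#>   loss 1.12502e-08, converged, 15 data points
#>   k_nuc          0.7
#>   k_el           6000
#>   k_relax_chain  0.07
#>   fixed: k_open, k_join, k_relax_free (k_close pinned to k_open / 0.0055)
```

A thin command-line wrapper ships in `inst/cli/toroidyn`
(`simulate | fit | synth | geometry | vesicle | crosscheck`) for
config-file-driven runs with reproducibility manifests.

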