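---
title: "Metabolic bottlenecks, bursty expression, and the distribution of cell generation times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic bottlenecks, bursty expression, and the distribution of cell generation times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`stogrow` simulates single bacterial cells whose division is limited by the
production of `p` biomass precursor metabolites.  The premise is that cell
size increase corresponds to a stoichiometric amount of precursor
metabolites, so the empirical Adder and Sizer size-homeostasis laws can be
restated in metabolite units: under the metabolic **Adder** a cell must
*produce* a fixed amount of each limiting metabolite before dividing,
irrespective of what it inherited; under the metabolic **Sizer** each final
metabolite pool must *reach* an absolute threshold.  Division fires at the
first time all `p` pools meet their targets, making the generation time the
maximum of `p` first-passage times — the structural reason the simulated
generation times are right-skewed and their logarithms are well fitted by a
generalized extreme value distribution of type III (negative shape,
bounded upper tail).

Three layers feed that first-passage problem:

1. **Bursty expression.** Each pathway's `n` enzymes form one operon with a
   common transcription-burst schedule: alternating OFF/ON intervals with
   iid exponential durations (defaults `t_OFF` 144 s, `t_ON` 240 s).
   Transcripts initiate at a constant rate while ON and are discarded if
   elongation does not finish before the burst ends.  Each mRNA carries a
   single ribosome producing one copy of *each* of the `n` enzyme species
   per translation round (polycistronic reading); the protein in progress
   when the mRNA decays is lost.  All molecule lifetimes are exponential.
2. **Pathway kinetics.** Substrate flows in at `S_in` molecules/s per
   pathway (total `p·S_in`) and is consumed by the first step of each
   cascade; each step is Michaelis–Menten with shared `kcat` and `Km`,
   with the live enzyme count as a piecewise-constant time-varying
   parameter.  Secretion multiplies the final production term by
   `(1 − σ)`; import adds a constant rate `f` to the final pool.
3. **Division and inheritance.** At division every pool — substrate,
   intermediates, final metabolites, mRNA and enzyme counts — is halved
   exactly; cumulative secreted/imported counters reset; daughters draw
   fresh, independent burst schedules.  Inherited molecules get fresh
   exponential lifetimes, which is distributionally exact by
   memorylessness.

## Parameters and calibration

| parameter | default | units | role |
|---|---|---|---|
| `p` | 3 | – | bottleneck pathways |
| `n` | 3 | – | enzyme steps per pathway |
| `S_in` | 9000 | molecules/s/pathway | substrate supply (media richness) |
| `kcat` | 300 | 1/s | catalytic constant |
| `Km` | 6e4 | molecules | half-saturation (≈100 µM at 1 µm³) |
| `mean_t_on` / `mean_t_off` | 240 / 144 | s | burst durations |
| `mrna_rate_on` | 1/240 | 1/s | initiation rate while ON |
| `mean_mrna_lifetime` | 120 | s | mRNA decay |
| `mean_protein_lifetime` | 1800 | s | enzyme decay |
| threshold | 2e7 (Sizer), 1e7 (Adder) | molecules | division requirement |
| burn-in / tree / replicates | 100 / 13 / 3 | generations | simulation plan |

The burst durations and the 1e7/2e7 thresholds are fixed model constants.
The expression and kinetic values are calibration surrogates chosen once by
the same procedure a wet calibration would use: among parameter
combinations, keep the one whose mean generation time and CV at
`p = 3`, `S_in = 9000/s` are closest to physiological values for a
minimal-medium bacterium (mean ≈ 35 min, CV ≈ 0.2).  Two structural
considerations pin the regime: the model's noise story requires bottleneck
enzymes that are *variable and few* (the defaults give ≈10–20 copies per
step, with single bursts delivering ≈5 proteins per species), and enzyme
memory must not span many generations or the Sizer's inheritance feedback
(daughters of an over-producing cell start closer to target) cancels the
pathway-to-pathway variability that drives every `p`-dependent effect.
With ~1e5-copy enzymes (as cruder per-reaction rate constants would
require) generation times become essentially deterministic and the model's
phenomenology disappears.

## Numerical choices

* **Integration.** Classic RK4 over the exact enzyme-count breakpoints:
  the integrator never steps across a jump, so the zero-order-hold enzyme
  signal is honoured exactly.  Within a segment the step is
  `min(1 s, 0.5·Km/(kcat·E_max))`, well inside the stability and accuracy
  range for dynamics whose fastest linearised rate is `kcat·E/Km`.  The
  mass balance `d(S + ΣP + ΣQ − ΣF)/dt = p·S_in` is a linear invariant and
  is preserved to round-off.
* **Event location.** Division (all final pools at target) is detected per
  step and refined by bisection to a relative tolerance of 1e-8; final
  pools are non-decreasing, so the event condition is monotone and
  bisection is exact.  The triggering pathway is the last to cross; exact
  ties break to the lowest index.
* **Degenerate inputs.** Pools are clamped at zero (Michaelis–Menten rates
  vanish there anyway); a configuration in which some pathway has neither
  substrate supply nor feed is rejected at construction, since such a cell
  can never divide; a cell that has not divided by `max_cycle_time`
  (50× the deterministic-limit cycle time by default) is flagged
  non-dividing and its subtree truncated with a warning.
* **Expression horizons.** Expression is generated per cycle out to 2.5×
  the best-case cycle time and *continued* — never regenerated — if
  division has not fired, so a longer horizon extends the same
  realisation.
* **Inheritance rounding.** Halved molecule counts are kept as reals and
  rounded only where molecules are enumerated; a dedicated test shows
  generation-time statistics are insensitive to half-count rounding at the
  default copy numbers.
* **Reproducibility.** Every cell cycle runs on its own RNG stream keyed by
  `(master seed, replicate, cell id)` through an exact Lehmer mix, so
  results are independent of traversal order and bit-identical on replay;
  the config echo in `run_meta.json` is written with 17 significant digits
  so a replay is exact.

## Design decisions on open points

* The printed chain equations are implemented as the within-pathway
  cascade (step `j` consumes the product of step `j − 1`, step 1 consumes
  the substrate): the literal subscripts would make a final pool its own
  substrate, which contradicts the linear-cascade schematic.
* Secreted molecules do **not** count toward the division target (secretion
  acts as an effective increase of the threshold); imported molecules do.
* Knockouts keep total inflow at `p·S_in`, redistributing the lost
  pathway's share over the `p − 1` survivors (+50 % per pathway at
  `p = 3`); the knocked-out metabolite must be fed, or the configuration is
  rejected under the Sizer.
* The growth-rate estimator fits `ln N(t)` over the first 40 % of sorted
  birth events.  The literal "100 permutations of the cell order" leaves
  the sorted curve unchanged, so the estimator instead averages 100
  bootstrap resamples of the cells, which uses the whole data set and
  yields a dispersion estimate.
* Burn-in follows daughter A; under perfect halving daughters are
  exchangeable, so the choice is immaterial.
* Cross-feeding is a single-cell proxy (auxotroph + 2× `kcat`
  overexpression + secretion + feed), not a coupled two-strain co-culture;
  feasibility requires secretion ≥ feed (non-strict) and growth strictly
  above the matched prototroph.

## What the tests show — and what they do not

The test suite runs on reduced problem sizes: lineage trees of 5–9
generations (31–511 cells) with burn-ins of 20–100 generations and 1–3
replicates, against the full plan's 100 + 13 × 3; the acceptance script
uses 10-generation trees over 3 seed streams (3069 cells).  Properties
checked include exact conservation and halving identities, closed-form
division times, independent-oracle ODE agreement (explicit Euler and
`deSolve`), GEV and Monod parameter recovery on synthetic data, Yule-rate
recovery of the growth estimator, monotone uptake/secretion effects under
matched seeds, and the `p`-dependence of mean generation times.

The synthetic lineages emulate bursty expression propagating through
metabolism into division timing.  They do not emulate: ribosome or
polymerase competition, DNA replication timing, asymmetric division,
stochastic chemical kinetics of metabolism, metabolite feedback on uptake,
or physical space and shared media — so passing tests support the model's
internal logic, not quantitative agreement with any particular organism.

## Known limitations

* The growth-rate-versus-supply curve is a noise-smoothed crossover from a
  substrate-limited linear branch to an enzyme-capacity plateau.  It is
  monotone and saturating, and a Monod hyperbola describes it only
  approximately (R² ≈ 0.96 over the default sweep grid): the knee is
  sharper than a true hyperbola, and the Monod acceptance check at
  R² ≥ 0.98 fails at this calibration.
* With the default calibration the CV of generation times is nearly flat
  in `p`, while skewness decreases with `p`; the mean's increase with `p`
  is robust.
* The Sizer's inheritance feedback makes non-trigger pathways start ahead,
  so `p`-effects are weaker than an iid extreme-value picture suggests;
  calibrations with long-lived enzymes weaken them further.
* `E_ij` enters the ODEs as molecule counts, not concentrations; volume
  growth within a cycle is not modelled.
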