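# stogrow

Stochastic single-cell growth simulation with bursty gene expression and
metabolic division rules.

## The problem

Steady-state models of microbial growth (flux balance, growth laws,
resource allocation) predict mean behaviour but are silent about why
genetically identical cells divide at different times — and therefore about
the growth consequences of anything that acts through cell-to-cell
variability, such as metabolite exchange between cells.  `stogrow`
implements an abstract single-cell growth model for exactly that question:
it is aimed at systems and microbial ecology modellers who want to ask how
uptake, secretion, pathway loss (auxotrophy) and reciprocal cross-feeding
change the distribution of generation times and the population growth rate.

## The model

A cell carries `p` parallel biosynthetic pathways, one per *bottleneck*
biomass precursor metabolite, each a linear cascade of `n` equivalent
Michaelis–Menten enzymes fed by a common substrate supplied at a constant
rate `S_in` per pathway (total inflow `p·S_in`; all quantities are absolute
molecule numbers for a 1 µm³ cell).  The `n` enzymes of a pathway sit on
one operon and share a stochastic transcription-burst profile: ON and OFF
durations are exponential with means `t_ON = 4 min` and `t_OFF = 2.4 min`;
transcripts initiate at a constant rate while ON, each completed mRNA is
translated by a single ribosome into one copy of each enzyme per round, and
mRNAs and proteins decay with exponential lifetimes.  The enzyme copy
numbers enter the pathway ODEs as piecewise-constant, time-varying
parameters: with `v_ij(x) = kcat · E_ij(t) · x/(x + Km)`,

    dS/dt      = p·S_in − Σ_i v_i1(S)
    dP_ij/dt   = v_ij(P_i,j−1) − v_i,j+1(P_ij)          (j < n)
    dP_in/dt   = (1 − σ_i)·v_in(P_i,n−1) + f_i

where `σ_i` is a secretion ratio (the secreted amount accumulates as
`dQ_i/dt = σ_i v_in`) and `f_i` a constant metabolite import rate.

Division is gated by a **metabolic Adder/Sizer** rule: producing each
limiting metabolite is a proxy for cell-size increase, so the cell divides
when every final pool `P_in` reaches its target — a fixed increment over
the inherited pool (Adder, threshold 1e7 molecules) or an absolute level
(Sizer, threshold 2e7, the default).  At division all content is split
exactly in half and the daughters draw fresh burst profiles.  Generation
time is the first time all `p` pools meet their targets — the maximum of
`p` first-passage times — which is why generation times are right-skewed
and their logs are well described by a generalized extreme value (GEV)
distribution with negative (type III, bounded-tail) shape.

The analysis stack mirrors the model's outputs: population growth rate from
the semilog slope of sorted birth events (first 40 %, averaged over 100
bootstrap resamples), maximum-likelihood GEV fits to log generation times,
distribution moments, Monod-curve fits `μ = μ_max·S/(K_s + S)` to growth
rate versus supply, and the exchange scenarios: uptake, secretion,
auxotrophy with flux redistribution (`p·S_in` over `p − 1` pathways), and a
single-cell cross-feeder proxy (knockout + feed + 2× overexpression +
secretion) with feasibility classification (secretion ≥ feed and growth
above the prototroph baseline).

## Worked example

```r
library(stogrow)

cfg <- growth_config(
  plan = simulation_plan(burn_in_generations = 50, tree_generations = 7,
                         replicates = 1),
  seed = 7)
lin <- simulate_lineage(cfg)   # burn-in, then a 127-cell lineage tree

summary(lin)
#> Lineage of 127 cells (1 replicates, 0 non-dividing)
#> Generation times: mean 2079.4 s, CV 0.217, skewness 0.439, excess kurtosis -0.069

fit_log_gev(lin)
#> GEV fit to log-transformed data (n = 127)
#>   location 7.5451, scale 0.2245, shape -0.3351  [shape < 0 = type III (bounded upper tail)]
#>   log-likelihood 13.98

growth_rate(lin)
#> Population growth rate: 0.0003437 /s (1.237 /h)
#>   point estimate 0.000337 /s, bootstrap sd 4.9e-05, R^2 0.9921, 127 births
```

The default calibration gives an E. coli-like mean generation time of
~35 min with CV ~0.2 at `p = 3`, `S_in = 9000/s`; the negative GEV shape
says the log-generation-time tail is bounded (type III), and the growth
rate of ~1.2/h is the slope of `ln N(t)` over the early expansion of the
tree.

Scenario sweeps run through `run_scenario()` /
`classify_feasibility()`, or from a shell via the installed CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "stogrow", package = "stogrow"))')
Rscript "$CLI" simulate --generations 8 --seed 1 --out out/
Rscript "$CLI" sweep --scenario uptake --s-in 2000,9000 --feed-rate 0,2000,8000 --out out/
```

## Package layout

- `R/expression.R` — burst schedules, transcription, translation, enzyme
  copy-number trajectories
- `src/cycle_integrate.cpp` — RK4 integration of the pathway ODEs over
  piecewise-constant enzyme segments with bisected division-event location
- `R/cycle.R`, `R/population.R` — division rules, perfect halving, burn-in
  and lineage trees
- `R/analysis.R` — growth rate, GEV and Monod fits, moments
- `R/scenarios.R` — uptake/secretion/auxotroph/cross-feeder sweeps
- `R/config.R`, `exec/stogrow` — configuration schema, file I/O, CLI
- `vignettes/metabolic-bottleneck-growth.Rmd` — the methods vignette
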