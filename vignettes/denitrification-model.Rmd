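---
title: "Modelling cell diversification and denitrification kinetics in batch culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell diversification and denitrification kinetics in batch culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Paracoccus denitrificans* raised aerobically and then confronted with
anoxia must synthesise its denitrification proteome *de novo*. Batch
incubations in gas-tight, He-washed vials show a characteristic sequence:
O~2~ is scavenged to exhaustion, practically all NO~3~^−^ is reduced to
NO~2~^−^ before any appreciable N-gas appears, and N~2~O stays at trace
level but **rises steadily** through the whole anoxic phase until NO~2~^−^
is gone. A homogeneous population cannot reproduce these curves. `denitpop`
implements the alternative: transcription of the *nar* and *nirS* genes
initiates stochastically in each cell, with low specific probabilities, and
autocatalytic expression then commits the cell. At the population scale
this divides the culture into four pools:

* `zMinus` — naive cells (no Nar, NirS or cNor),
* `zNa` — cells with Nar,
* `zNaNi` — cells with Nar, NirS and cNor,
* `zNi` — cells with NirS and cNor (recruited directly from the naive pool),

all of which carry NosZ, because *nosZ* is readily induced by the
O~2~-sensing regulator FnrP in every cell. The model tracks these pools
together with the per-vial amounts of O~2~ (headspace and aqueous),
NO~3~^−^, NO~2~^−^, and aqueous-plus-headspace NO, N~2~O and N~2~.

## Model structure

### Respiration and electron competition

Each acceptor is reduced at a per-cell electron-flow velocity. O~2~,
NO~3~^−^, NO~2~^−^ and N~2~O follow Michaelis–Menten kinetics
(`mm_velocity()`); NO follows a cooperative two-substrate form
(`no_reduction_velocity()`), reflecting binding of two NO molecules to
cNor — this keeps the NO flux negligible at the 10^−25^ mol initialisation
floor. Electron supply from the TCA cycle is capped at `veMaxTCA`; when
O~2~, NO~3~^−^ and NO~2~^−^ are respired simultaneously, O~2~ is served
first, then NO~3~^−^, then NO~2~^−^ (`restrict_electron_flows()`). NO and
N~2~O reduction are exempt from the cap because their onset never coincides
with supply saturation. Stoichiometries are 4 e^−^ per O~2~, 2 per
NO~3~^−^, and 1 per NO~2~^−^, NO-N and N~2~O-N reduced.

NO~3~^−^ is reduced by `zNa + zNaNi`; NO~2~^−^ and NO by `zNaNi + zNi`;
O~2~ and N~2~O by **all four pools** — the population-wide N~2~O sink is
the model's key structural assumption.

### Recruitment and the closed-form recruited fractions

Recruitment is a deterministic expected-value flux (pool size × specific
probability), not an agent-level Bernoulli draw — this matches the
continuous system-dynamics formulation the model family comes from; a
stochastic mode is out of scope. Two gates must hold:

* an O~2~ threshold: `[O2]aq < 5.95e-5` mol L^−1^ for *nar*,
  `< 9.75e-6` mol L^−1^ for *nirS* (the parameter-table values; the
  corresponding empirical outsets of NO~2~^−^ and NO accumulation are
  slightly different in the source's body text and both remain
  configurable), and
* an energy gate: the source pool's usable electron flow must exceed
  `veMin`, the minimum respiration needed to fuel synthesis of the first
  reductase molecules. Electrons to N-oxides are weighted 0.5 relative to
  O~2~ because their ATP yield per electron is about half. Nar-positive
  source cells may count their (TCA-restricted) NO~3~^−^ flow; naive cells
  may not, since they have no Nar. We use the restricted rather than the
  potential NO~3~^−^ flow in this gate: energy cannot come from electrons
  the TCA cycle cannot deliver.

Because the gates are shared by all cells of a pool, the fraction recruited
over a window of length `t` has the closed form `1 − exp(−r·t)`
(`fraction_nar()`), and the NirS fraction combines the two source branches
weighted by the Nar fraction (`fraction_nir()`). The *functional* Nar
fraction counts only the O~2~-energised window (it alone shapes the
NO~2~^−^ curve, because NO~3~^−^ is exhausted before N~2~O appears); the
*theoretical* fraction also counts N~2~O-sustained recruitment after
NO~3~^−^ exhaustion.

### Gas physics and the sampling events

Headspace–liquid exchange is first-order in the departure from Henry
equilibrium, `kt · (kH·p − c_aq)`, with solubilities at 20 °C of 0.0014
(O~2~), 0.0021 (NO), 0.056 (N~2~O-N) and 0.00035 (N~2~-N)
mol L^−1^ atm^−1^. The robotised incubation system samples the headspace
on a schedule; each sampling removes a fraction `D = 0.015` of every
monitored gas (replaced by He) and leaks 2.92 nmol O~2~ into the vial. We
apply this as an instantaneous state update at the sampling time — exactly
equal to the printed removal rate acting over the 0.017 h sampling
duration, and far kinder to the integrator. N~2~ is not diluted in the
model because the production data the model is meant to be compared with
are already sampling-corrected. The N removed from the NO and N~2~O
headspace pools is banked in a `sampledN` state so that total N remains an
exact invariant. The sampling schedule itself is not printed in the source
material; the package default is one sampling every 3 h from t = 0,
configurable as an explicit time list. The summary fractions depend only
mildly on this choice (the O~2~ tail, and hence the recruitment windows,
shift by a fraction of the 3 h interval).

### Integration

`run_simulation()` integrates the coupled ODEs with `deSolve::lsoda`
(stiff-capable, adaptive) between consecutive sampling times, applying the
sampling perturbation as a state reset at each boundary. Defaults:
`rtol = 1e-8`, absolute tolerance 10^−16^ on chemical pools (whose scale is
10^−4^ mol down to 10^−12^), 10^−2^ on cell pools (scale 10^8^–10^10^).
The recruitment gates are sharp conditionals inside the right-hand side; we
deliberately do not smooth them, because the window durations they define
feed the closed-form fractions. Window durations are accumulated as
indicator states integrated alongside the ODEs, so they are independent of
the output grid. Concentrations are clipped at zero inside the right-hand
side (aqueous NO at its 10^−25^ mol floor), which protects the kinetics
from the integrator's harmless sub-tolerance negative excursions. A run
over 150 h (long enough for complete N~2~ recovery in every default
treatment) takes about a second.

## Parameters

Velocities are mol e^−^ cell^−1^ h^−1^, yields cells (mol e^−^)^−1^,
concentrations mol L^−1^, time h. The carbon-source-specific defaults:

| symbol | butyrate | succinate | meaning |
|---|---|---|---|
| `veMaxTCA` | 1e-14 | 9.34e-15 | TCA-cycle electron-supply cap |
| `veMaxO2` | 4.22e-15 | 4.42e-15 | max electron flow to O~2~ |
| `veMaxNO3` | 1e-14 | 9.34e-15 | max electron flow to NO~3~^−^ |
| `veMaxNO2` | 2.65e-15 | 2.01e-15 | max electron flow to NO~2~^−^ |
| `veMin` | 1.87e-17 | 1.95e-17 | minimum flow for enzyme synthesis |
| `yieldO2` | 2.74e13 | 4.97e13 | growth yield on O~2~ |
| `yieldNOx` | 1.12e13 | 1.52e13 | growth yield on N-oxides |

The butyrate `veMaxTCA` is printed as 10^14^ in the source parameter
table — a sign slip (it would exceed the sibling velocities by 28 orders of
magnitude); the package uses 10^−14^, consistent with the butyrate
`veMaxNO3`. `veMin` is *defined* as the O~2~ electron flow at 1 nM aqueous
O~2~, which evaluates to 0.44 % of `veMaxO2` for both carbon sources
(1.96×10^−17^ succinate, 1.87×10^−17^ butyrate); the succinate table value
1.95×10^−17^ differs from the derived 1.96×10^−17^ in the last digit, and
the table value is kept as the default. `veMaxO2` itself comes from the
yield relation μ = `veMaxO2 · yieldO2` (0.22 h^−1^ succinate, 0.12 h^−1^
butyrate); the empirically reported butyrate μ of 0.067 h^−1^ would give
2.45×10^−15^, which grossly under-predicts O~2~ depletion and was rejected
in the source's own parameterisation.

Shared constants: `rNa = 0.035` h^−1^ and `rNi = 0.004` h^−1^ (the
treatment-averaged optimised initiation probabilities), `kmO2 = 2.25e-7`,
`kmNO3 = 5e-6`, `kmNO2 = 4.13e-6`, `kmN2O = 5.93e-7` (mol N~2~O-N L^−1^;
the optimised value — *in vitro* NosZ affinities of ~5 μM over-predict
N~2~O tenfold), NO-binding constants `k1NO = 8e-14`, `k2NO = 3.4e-8`,
`kt = 3.6` L h^−1^, dilution `D = 0.015` (mid-point of the printed
0.013–0.016 range), O~2~ leak 2.92 nmol per sampling, 20 °C.

The four canonical treatments (`canonical_treatments()`) cross butyrate and
succinate with nominally 0 and 7 vol% initial headspace O~2~, 2 mM
NO~3~^−^, 50 mL medium, 70 mL headspace, 2.2×10^8^ cells. The "~0"
treatments retained unquantified trace O~2~ after He washing; their
`initialO2VolPct` is `NA` and `run_simulation()` refuses to guess — tests
and examples that need such a run state their trace explicitly (we use
0.3 vol% as a plausible residue). All summary targets quoted below use the
fully specified 7 % treatments.

## What a default run produces

For the butyrate, 7 % O~2~ treatment with the defaults:

```r
sim <- run_simulation(treatment_config("butyrate", 7),
                      kinetic_params("butyrate"))
sim
#> Batch denitrification simulation (butyrate, 7 vol% O2)
#>   NO2- peak: 99.9 umol vial-1 at 39.2 h
#>   F_Na functional 0.362 (window 12.8 h), theoretical 0.673
#>   F_Ni 0.089 (windows 23.2 / 23.2 h)
#>   N2O headspace max: 2.54 nmol N; final N2: 100 umol N
```

The published summaries for this treatment are a functional Nar fraction of
0.343, a theoretical one of 0.656, and a NirS fraction of 0.088; the
residual differences are consistent with the unprinted sampling schedule.
The counterfactuals (`run_counterfactual()`) reproduce the source's
structural arguments: `narAlwaysOn` (`rNa = 4` h^−1^, 98 % Nar-positive
within an hour) floods the medium with NO~2~^−^ far faster than observed;
`nosZOnlyDenitrifiers` removes the population-wide N~2~O sink and turns the
steadily rising N~2~O trace into a plateau; `veMinZero` with mildly
re-optimised probabilities (`rNa = 0.033`, `rNi = 0.0033`) still completes
denitrification, showing the energy gate is plausible but not necessary.

## Synthetic observations and calibration

`generate_observations()` emulates the measurement structure: headspace
amounts of O~2~, NO, N~2~O and N~2~ plus the liquid NO~2~^−^ amount at each
sampling time, with additive Gaussian noise truncated at zero. The noise sd
is a fraction (default 2 %, motivated by the replicate spread of such
incubations) of each species' range, with an optional detection-limit
floor; no error model is published, so this is the package's own choice.
The 0.1 mL liquid withdrawals for NO~2~^−^ analysis (taken from parallel
vials in the experiment) are not modelled. What passing calibration tests
on these data do **not** show: robustness to structured errors (drift,
peak-integration bias), to replicate-correlated noise, or to model
misspecification — the synthetic truth is the model itself.

`fit_parameters()` minimises a range-scaled sum of squares: per species,
residuals between the simulated observables (linearly interpolated to the
observation times) and the data, divided by the squared observed range so
that a 100 μmol NO~2~^−^ curve and a 3 nmol N~2~O curve weigh comparably.
The objective form and optimiser are not specified in the source (which
used a proprietary system-dynamics tool); we use bounded derivative-free
search — each free parameter is mapped to the real line by a logistic
transform of its log-scale position inside its bounds, then optimised by
golden-section (one parameter) or multi-start Nelder–Mead (several), with
extra starts drawn under a fixed seed. Gradients are deliberately avoided:
the event-laden, gated model makes them unreliable. A failed simulation
returns a 10^6^ penalty so the search can step around non-physical
corners. Two presets mirror the published recipes: `"rNa-from-NO2"` (the
NO~2~^−^ curve identifies `rNa`) and `"rNi-from-N2"` (NO~2~^−^ depletion
plus N~2~ accumulation identify `rNi`). On synthetic data at 2 % noise,
joint recovery of both probabilities lands within a few percent of the
generating values (the acceptance suite requires ±25 % across five seeds).
Replicates are accepted in the observation table; the objective simply sums
over all rows, which weights replicate means implicitly.

Calibration runs use a shortened horizon (80 h, past complete N~2~ recovery
for the oxic treatments) and relaxed tolerances (`rtol = 1e-6`,
`atol = 1e-13`) — the objective is dominated by measurement noise long
before integrator error matters.

## Known limitations

* **The ~3× growth-rate claim.** The source states that full denitrifiers
  (`zNaNi`, `zNi`) grow "approximately three times faster" than the
  N~2~O-only respirers during anoxia. Under the model's own equations this
  ratio is `1 + (veNO2res + veNO)/veN2O`, and because the N~2~O pool is
  strongly quasi-steady (population consumption capacity far exceeds
  production), `veN2O ≈ veNO × denitrifier fraction`. The ratio is
  therefore ≈ `1 + 2/denitFraction` — about 13 at peak denitrification in
  the oxic butyrate run, falling as the minority expands, but reaching 3
  only if the denitrifying fraction approached unity, which would
  contradict the model's central claim that it is small. The package
  reproduces the *directional* phenomenon (a large, declining growth
  advantage, which is what makes the N~2~O trace rise) but not the
  published factor; the corresponding acceptance check is expected to fail
  and is retained as documentation of the discrepancy.
* Electron competition is evaluated globally (one restriction shared by all
  pools), as in the source equations; a per-pool restriction would differ
  only while NO~3~^−^ and NirS-positive cells coexist, which is brief.
* Molecular regulator dynamics (FnrP/NNR/NarR activation, NO inhibition of
  FnrP/NosZ) are abstracted into the two O~2~ thresholds and the two
  initiation probabilities; cell death and maintenance energy are absent,
  so total cell number never decreases.
* The O~2~ leak is applied only at sampling events, never continuously, and
  total pressure is fixed at 1 atm for partial-pressure bookkeeping.
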