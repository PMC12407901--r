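---
title: "Estimating ion selectivity from transepithelial dilution potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ion selectivity from transepithelial dilution potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghkselect)
```

## The measurement and the model

A channel-forming small molecule added to an epithelial monolayer opens a
second conductive pathway in parallel with the epithelium's own
(paracellular) one. Its ion selectivity is encoded in the *dilution
potential*: reduce the apical NaCl from 140 to 70 mM and a Na⁺-selective
pathway drives the transepithelial voltage positive, a Cl⁻-selective one
negative. `ghkselect` converts the four quantities an Ussing-chamber
experiment yields per monolayer — conductance and dilution potential before
and after compound addition — into the relative permeability
$P = P_{Cl}/P_{Na}$ of the drug-formed pathway.

Three model layers stack up:

**Activities.** Single-ion activity coefficients come from the extended
Debye-Hückel equation,
$\log_{10}\gamma = -A z^2 \sqrt{\mu} / (1 + B \alpha \sqrt{\mu})$,
with the 37 °C constants $A = 0.522$ and $B = 3.31\ \mathrm{nm}^{-1}$ and
Kielland-style hydrated diameters ($\alpha_{Na} = 0.4$ nm,
$\alpha_{Cl} = 0.3$ nm, overridable per recipe). This form is valid at
physiological ionic strengths; it is not a Pitzer model and is not meant
for brines. Each bath gets coefficients at its *own* ionic strength — the
70 mM apical bath has larger $\gamma$ than the 140 mM basolateral one — with
a `shared_gamma` compatibility switch for analyses that reused the
concentrated bath's coefficients, and a `mu_override` for pinning the ionic
strength externally. With the packaged recipes ($\mu = 0.1469$ M from NaCl
plus the two gluconate salts; buffer speciation excluded), the computed
$\gamma_{Na} = 0.7367$ and $\gamma_{Cl} = 0.7163$ sit within 0.13 % of the
published nine-digit values for this bath; the residual discrepancy
back-solves to $\mu \approx 0.148$ M, i.e. a slightly different
ionic-strength bookkeeping (likely partial buffer ionisation) that the
recipe format can express explicitly if desired.

**Circuit decomposition.** The treated monolayer is two conductances in
parallel, each behind its own electromotive force:
$\Delta V_t = w\,\Delta V_{FRT} + (1-w)\,\Delta V_{drug}$ with
$w = G_{FRT}/(G_{FRT}+G_{drug})$. The decomposition assumes the
epithelium's own pathway is unchanged by the compound (same $G_{FRT}$,
same $\Delta V_{FRT}$), which is the standard assumption behind
before/after designs. $G_{drug} = G_{total} - G_{FRT}$; a non-positive
difference means the compound added nothing measurable and the replicate
carries no selectivity information — it is flagged invalid with that
reason, never clamped or dropped silently.

**GHK inversion.** The drug pathway's potential obeys the
Goldman-Hodgkin-Katz voltage equation restricted to Na⁺ and Cl⁻. The
default slope is the conventional 61.5 mV (the printed 37 °C
approximation); `slope = "exact"` evaluates $RT\ln 10/F$ at the bath
temperature (61.54 mV at 310.15 K) for users who prefer rigour over
convention — the choice moves $P$ by well under 1 %. The inversion is
closed-form and exact; it is valid only strictly between the Nernstian
limits (the potentials of perfectly single-ion-selective pathways).
Potentials within `guard_mV` (default 0.1 mV) of a limit are rejected as
numerically unstable rather than returning enormous or negative ratios:
in practice such values mean the circuit decomposition amplified
measurement error beyond what the replicate can support.

Aggregation is per-monolayer-then-average: each replicate yields its own
$P$, and the compound is summarized as mean ± s.e.m. over valid replicates
(s.e.m. = sample SD/√n). Pooled estimators are deliberately out of scope.

### Voltage sign convention

Which side is "positive" is a perennial source of confusion and the
literature rarely states it. The package fixes the convention by
self-consistency of the GHK form used: basolateral activities in the
numerator's Na⁺ term, so that an apical dilution through a
cation-selective pathway ($P<1$) produces a *positive* potential and
compound addition then drives the voltage *negative* exactly when the drug
pathway is more anion-selective than the epithelium's own. The simulators
use the identical convention, so forward/inverse consistency is testable
end to end.

## Raw-trace reduction

Recordings are open-circuit voltage with intermittent bipolar ±0.5 nA
current injections. `detect_pulses()` finds non-zero-current runs and pairs
adjacent opposite-polarity pulses; `compute_gt()` measures the deflection
between the stable tails of the paired plateaus, so slow baseline drift
cancels to first order (a lone pulse falls back to tail-minus-baseline at
half the current step). Ohm's law then gives $R_t$ in MΩ (mV/nA) and
$G_t = 10^{-3}/(R_t \cdot \text{area})$ in mS/cm²; the default area is
0.33 cm² (6.5 mm Transwell insert). Note the scale this implies: a 2 mV
deflection from a 1 nA step is a 2 MΩ monolayer, i.e. $G_t$ of order
10⁻³ mS/cm². Pulses that straddle a protocol event are excluded and
flagged; zero-deflection pulses (infinite conductance) likewise.

`step_plateaus()` splits the recording at its protocol events ("dilution",
"compound_added") and takes the *median* of the last 60 s (configurable)
of pulse-free voltage, and of accepted conductances, in each segment.
Medians are robust to residual pulse edges and make plateau values
invariant to pulse placement; segments shorter than the window use the
whole segment with a warning. Irregular sampling is supported throughout —
nothing is resampled.

## The supporting assays

All four scalar quantifications are ratios of plateau or control levels
and therefore invariant to instrument gain and offset:

* **Chloride efflux**: baseline = median of the first 2 min; compound
  level = median of the last minute before Triton; 100 % = median of the
  last minute of the run. Values outside [0, 100] are reported with a flag.
  An equal Triton and baseline level leaves the scale undefined and errors.
* **Viability**: blank wells define 100 %, Triton wells 0 %.
* **Yeast rescue**: mutant OD₆₀₀ as a percentage of wild type, per dose,
  with a max-over-dose summary. "Percent of WT" is ambiguous between
  vehicle-treated WT and compound-matched WT; both modes are implemented
  (`vehicle_wt` default, documented as a package choice, with no claim
  about which any particular study used).
* **Phosphorus curve**: ordinary least squares (`stats::lm`) of A₈₂₀
  against nmol phosphorus; quantification inverts the line and reports R²
  and an extrapolation flag.

## What the simulators emulate — and what they do not

Every generator takes a seed and emits a ground-truth sidecar; recovery
tests compare analysis output against the sidecar only. Identical seeds
give identical bytes.

`simulate_dilution_trace()` is the forward model of the analysis chain: a
two-pathway GHK epithelium whose drug conductance rises logistically
(time constant 10 s — the protocol literature says only "allowed to
equilibrate", so the kinetics are a documented invention) after the
compound event, a junction offset while the baths are asymmetric, bipolar
pulse deflections by Ohm's law, optional linear drift, and white Gaussian
voltage noise. Scenario defaults are the study conditions the analysis
targets: 140/70 mM Ringer's pair, 61.5 mV slope, 0.33 cm² insert,
±0.5 nA pulses (2 s each polarity every 15 s, 5 Hz sampling),
$G_{FRT} = 10^{-3}$ mS/cm² and $G_{drug,max} = 4\times10^{-3}$ mS/cm²
(the MΩ scale that ±0.5 nA pulses resolve), junction 1.2 mV, noise SD
0.02 mV (a low-noise epithelial amplifier after filtering), drift 0,
neutral paracellular selectivity $p_{frt} = 1$ (never reported
numerically, hence a free parameter), and segment durations
120/240/360 s. What the simulator does *not* capture: capacitive pulse
transients, electrode polarisation, slow $G_{FRT}$ rundown, correlated
(1/f) noise, temperature excursions, or any pore-level mechanism. Passing
recovery tests therefore demonstrates that the analysis chain is
self-consistent and noise-robust under these idealisations — not that any
laboratory instrument meets them.

The other generators follow the same pattern: `simulate_ise_trace()`
(2 min baseline, exponential approach with τ = 1.5 min to the programmed
fraction of the Triton level, Triton step, 3 min tail, 0.3 ppm noise),
`simulate_growth_table()` (Hill rescue × high-dose rolloff, rescaled so
the programmed maximum is attained exactly on the dose grid),
`simulate_plate()` (affine viability-to-fluorescence map with noise on the
viability scale, which is what makes the derived percentages exactly
gain/offset-invariant at a fixed seed).

## Numerical choices and degenerate inputs

* Closed-form GHK inversion, not iterative: exact, fast, and testable
  against an independent bracketing root-solve (they agree to 10⁻⁹
  relative over 1000 random tuples in the suite).
* Plateau statistic: median everywhere; no tie-breaking subtleties arise
  because windows always contain many samples.
* Guard band `guard_mV = 0.1` on the Nernstian limits: inside it the
  derivative $dP/dV$ diverges and replicate-level error dominates.
* Degenerate inputs error loudly with the quantity that failed: negative
  concentrations, non-increasing time axes, missing controls, equal
  control means, zero-deflection pulses, rank-deficient standard curves,
  zero vehicle means.
* Charge imbalance in a recipe warns (buffers are often intentionally
  incomplete) rather than errors.

## Problem sizes

The shipped tests run the full chain at modest sizes chosen as
representative: recordings of 720 s at 5 Hz (3600 samples), six replicates
per scenario across the selectivity regime $P \in \{0.06, 0.16, 1.12, 3\}$,
1000-tuple oracle sweeps for the inversion and circuit round-trips. The
generators scale to longer protocols by changing the segment durations.

## Limitations

Only Na⁺ and Cl⁻ enter the GHK relation; bi-ionic protocols and
multi-ion permeation are out of scope, as are liquid-junction-potential
*prediction* (the protocol measures it), voltage-clamp short-circuit
analysis, and capacitance estimation. The activity model excludes
buffer speciation equilibria by default. The s.e.m. reported for $P$ is
across monolayers; error propagation from voltage uncertainty within a
replicate is not attempted.
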