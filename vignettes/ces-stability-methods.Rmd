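---
title: "Methods: quantifying stability in closed microbial ecosystems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying stability in closed microbial ecosystems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesdyn)
```

## The system and the three data streams

A closed microbial ecosystem (CES) is a materially sealed, light-energized
vial holding an alga and a bacterial consortium. Because the vial exchanges
no matter with the outside, its headspace pressure integrates the community's
gas metabolism: net O~2~ production during the light phase raises pressure,
net respiration during the dark phase lowers it. cesdyn analyzes the three
complementary data streams such an experiment yields —

1. **headspace pressure/temperature time series** per vial, the real-time
   functional proxy;
2. **FT-ICR-MS peak lists** of the dissolved organic matter (DOM), the
   chemical state of the system;
3. **ASV count tables** from 16S amplicon sequencing, the community state —

and the statistics that couple them. A seeded synthetic-data generator
produces all three streams with known ground truth, so every analysis stage
is testable end to end without any external download.

## Pressure dynamics

### Temperature calibration

Sealed headspace pressure responds to bath-temperature fluctuation for
purely physical reasons. A sterile control vial monitored alongside the
biological units isolates that abiotic response: `fit_temperature_calibration()`
fits pressure on temperature by ordinary least squares, and
`apply_calibration()` subtracts the fitted slope, referencing every trace to
a constant 30 °C:

$$P' = P - b\,(T - 30).$$

One calibration (from the single control) is applied to all units,
mirroring the single-control experimental design. A constant-temperature
control is rejected — the slope is unidentifiable.

### Diel cycles and the two metrics

Traces are cut at light-on into 24-h cycles (half-open windows, with the
closing boundary sample carried so a cycle spans a full day). Two metrics
are computed per cycle on a running-median-smoothed copy (default window
600 s):

- **Diel amplitude**, the proxy for carbon-cycling intensity. Two
  definitions are exposed. The default, `light_rise`, is the smoothed
  pressure at light-off minus at light-on — the net photosynthetic gain
  over the light phase. The alternative, `max_min`, is the cycle maximum
  minus minimum. For the idealized symmetric diel path the two coincide,
  but their error behaviour differs sharply: the extremes of `max_min` are
  biased *high* by residual noise (the max of many noisy points) and
  *low* by smoothing (any running median clips the light-off cusp by about
  `slope × window/4`). Measured on the default synthetic scenario, no
  smoothing window brings `max_min` within 5% at every phase — small
  windows overshoot the 5 hPa late phase by up to 6%, large windows clip
  the 18.7 hPa early phase by 4%. `light_rise` anchors on two points that
  sit on *linear* segments of the diel path, where a running median is
  unbiased, and recovers all phase means within ~2.5%. That is why it is
  the default.
- **ΔP~net~**, the net 24-h change (last minus first smoothed value of the
  boundary-inclusive cycle). Zero means photosynthesis and respiration are
  balanced over the day.

With `smoothing_window = 0` the raw series is used; this is the exact
estimator for noise-free data (any median smoother distorts the sawtooth
cusp), and it is what the generator-closure tests use.

Interior data gaps up to `max_gap` (default 300 s, never less than 1.5
sampling intervals) are linearly interpolated when the cycle is resampled
onto its regular grid; longer gaps invalidate the cycle with a recorded
reason rather than silently biasing the metrics.

### Phase summaries

`phase_summary()` pools the per-cycle metrics of all vials inside a day
window and reports the amplitude mean, sample SD (n − 1) and coefficient of
variation (percent), plus a two-sided one-sample t-test of ΔP~net~ against
zero. The degenerate all-zero case is reported as t = 0, p = 1 by
convention. Pooling across vials matches the study design's "mean ± SD
across all units".

## DOM molecular characterization

### Formula assignment

Negative-mode FT-ICR-MS resolves masses finely enough that a peak's
elemental formula can be assigned from its exact mass alone.
`candidate_formulas()` enumerates every CHNOS formula whose theoretical
[M−H]^−^ m/z (neutral monoisotopic mass minus the proton mass,
1.00727646688 Da) lies within the ppm tolerance, solving the hydrogen count
from the residual mass over a (C, N, O, S) grid — exact, because H steps
are ~1.008 Da apart, vastly wider than any ppm window. Candidates must pass
all validity rules:

| rule | default | why |
|---|---|---|
| element counts | C 4–50, H 4–100, N 0–4, O 1–40, S 0–2 | conservative CHNOS space for solid-phase-extracted DOM |
| H/C | [0.3, 2.5] | stoichiometrically plausible organic matter |
| O/C | (0, 1.2] | ditto; O ≥ 1 makes the lower bound automatic |
| DBE | integer in [0, 25] | even-electron neutral molecules; `C − H/2 + N/2 + 1` |
| NOSC | [−4, +4] | the chemical limits of carbon oxidation state |

The NOSC bound is stated explicitly because the other rules do not imply
it: a formula such as C5H4N4O6S2 satisfies every element and ratio bound
yet would have NOSC 4.8, which no real molecule can reach. Ties between
candidates are broken deterministically: smallest |ppm error|, then fewest
N+S atoms, then lowest DBE, then lexicographic element counts. Duplicate
assignments within a sample merge by summing intensity.

Mass constants are a single table (C 12 exactly, H 1.0078250319,
N 14.0030740052, O 15.9949146221, S 31.97207069 Da).

### Classification and summaries

Formulas are placed in H/C–O/C (van Krevelen) space and classified into the
seven conventional compound classes (lipids; aliphatic/peptides;
carbohydrates; unsaturated hydrocarbons; lignin/CRAM-like; tannins;
aromatic structures), first matching rule wins, no match →
`"unclassified"`. The default boxes are the standard convention and fully
replaceable via `class_scheme()` — studies that publish their own
supplementary boundaries can drop them in.

Class relative abundance is intensity-weighted by default (the van Krevelen
representation scales points by intensity); count weighting is a flag, and
both are reported by the pipeline. Chemodiversity is the Shannon index (in
nats — the base is a convention choice) over assigned-formula intensity
shares. Between-sample formula sets are compared by exact element-count
keys into shared/unique partitions with per-class tallies.

## Community profile

ASVs with fewer than 2 reads *in total across samples* are removed
(dataset-wide singleton removal — the usual artifact filter; a per-sample
interpretation is available by flag). Genus is the sixth semicolon-delimited
rank of the lineage string; unparseable lineages group as
`unclassified_genus`. No rarefaction is performed.

Bray–Curtis dissimilarities, PCoA (classical scaling; negative eigenvalues
reported, not embedded), PERMANOVA (Anderson's pseudo-F, free label
permutation matching the single-factor design) and the dispersion
homogeneity test (distances to group centroids with the standard
imaginary-axis correction) are delegated to vegan behind the package's
interfaces. All permutation p-values use the (count + 1)/(n~perm~ + 1)
convention, and all permutation tests accept a seed and reproduce exactly.
Groups of one sample carry no dispersion information; they are flagged and
excluded from the homogeneity test rather than crashing it. With two
samples per group — the study's actual replication — within-group distances
are pairwise equal and the dispersion F becomes degenerate; results at that
replication deserve the same caution the original analysis attached to
them.

## Coupling statistics

- **Mantel test**: Spearman rank correlation of the strictly-upper-triangle
  entries, null built by jointly permuting rows and columns of the second
  matrix. The p-value is two-sided on |ρ| by default (a negative
  community–chemistry association would be just as noteworthy as a positive
  one); one-sided is a flag, and `exact = TRUE` enumerates all n!
  permutations for n ≤ 7. This test is implemented in-package because the
  two-sided convention and exhaustive option are not available in the
  reference implementations; vegan's Mantel serves as an independent
  cross-check in the test suite.
- **Series × mass-bin grid**: assigned intensities are summed into
  half-open 50-Da bins of neutral mass over 200–600 Da per heteroatom
  series, and each (genus, series-bin) pair is given a Spearman ρ across
  the shared samples. Cells with |ρ| < 0.3 are masked for display, as are
  cells undefined because a vector is constant (masked with a reason, not
  an error). With only six samples the |ρ| ≥ 0.3 mask admits nearly any
  nonzero rank correlation — a display convention, not an inference
  threshold.
- **KS comparison of NOSC distributions**: the two-sample
  Kolmogorov–Smirnov D with the asymptotic p by default (appropriate for
  the thousands of formulas per time point) and an exact small-sample
  option.
- **Diversity coupling**: both `chem ~ a + b·micro` and
  `chem ~ a + b·ln(micro)` are fitted by OLS; each reports R² and the slope
  p, and the form with higher R² is preferred. A winning logarithmic form
  means chemodiversity falls ever faster per unit of microbial-diversity
  loss at the low-diversity end. A constant response reports R² = 0 for
  both forms rather than NaN.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults encode the biphasic
study conditions; every number below is a scenario parameter.

**Pressure** (`pressure_scenario()`): 12 vials plus one sterile control
sharing a single bath-temperature series (30 °C mean, 0.5 °C diel swing),
54 days at dt = 60 s (native hardware records at 10 s; 60 s keeps
full-study objects small and is equivalent at diel scale, and dt is
configurable down to 10 s). The diel signal is a piecewise-linear sawtooth
— linear rise over the 12-h light phase to the day's amplitude, linear fall
over the dark phase — which makes amplitude an exact generative parameter.
Phase windows: days 1–8 at 18.7 hPa, days 31–45 at 7.2 hPa, days 46–54 at
5.0 hPa; days 9–25 are a collapse window (amplitude 0, baseline declining
1 hPa/day) and undeclared days interpolate linearly, giving the
collapse-and-recovery trajectory. Each vial-day's realized amplitude is
scattered around the target by a per-phase relative SD (0.15 / 0.05 /
0.08). Without this term the generator cannot express the study's
variability contrast at all — with a constant target, measured CVs are
noise-only and *inversely* proportional to amplitude, ordering the phases
backwards. The defaults deliberately use smaller dispersion than the
study's printed amplitude SDs, because a 38.7% amplitude CV would make the
±5% phase-mean recovery property unattainable at 96 cycles (the sampling
error alone is ~4%); the chosen values preserve the qualitative contrast
(measured CV ≈ 13–17% in phase 1 versus 7–9% in phase 2a) while mean
recovery holds. Sensor noise is i.i.d. Gaussian (0.5 hPa); the abiotic
temperature coupling is 0.5 hPa/°C; sampling covers t = 0 to 54 × 86400 s
inclusive so every cycle owns its closing boundary sample and the
noise-free ΔP~net~ equals the generative baseline change exactly.

**DOM** (`dom_scenario()`): three time points with two replicates sharing a
time point's formula set (masses and intensities re-drawn per replicate).
Series counts follow the study trajectory — CHOS 682 → 518 → 452, CHNO
3046 → 3182 → 3448 — while the CHO counts (4375 → 3000 → 2200) are free
parameters of the emulation, chosen so total richness declines. Formulas
are rejection-sampled from the compound-class H/C–O/C boxes with the class
mixture drifting toward lignin/CRAM-like and aliphatic/peptide material
(mixtures track the reported class percentages); every truth formula
passes the assignment validity rules, so assignment closure is exact at
zero ppm noise. Observed m/z adds Gaussian ppm error (default 0.2 ppm);
intensities are lognormal with sdlog growing 1.0 → 1.10 → 1.45 across time
points — an evenness loss representing the growing dominance of a few
recalcitrant compounds, calibrated so that together with the richness loss
the expected chemodiversity declines along a logarithmic curve in the
expected microbial diversity (the log-shaped coupling the analysis is meant
to detect). No replicate-to-replicate formula variability is simulated
(the study does not report it), no isotopologues, no adducts other than
deprotonation, no multiply charged ions.

**Community** (`community_scenario()`): ten genera with target relative
abundances per time point emulating the observed succession — an even
early community led by *Pseudomonas* (genus Shannon 2.14), a shift to
*Brevundimonas* dominance with *Pseudomonas* and *Duganella* vanishing
(1.41), then further dominance with rising *Porphyrobacter* and the loss
of *Terrimonas* and *Ensifer* (0.86). Each genus carries 3 ASVs split by a
fixed 0.8/0.1/0.1 profile shared across genera, so ASV-level diversity is
a stable offset of genus-level diversity — a deliberate choice: drawing
the split at random per seed was found to jitter the diversity anchor
points enough to obscure the log-shaped coupling the DOM side is
calibrated to. Counts are Dirichlet-multinomial (concentration 1000,
50 000 reads/sample), emulating tight replicates.

All generators are exactly reproducible from their seed, restore the
caller's RNG state, and write/read losslessly through the interchange
formats (pressure CSV, per-sample peak-list CSV + manifest, ASV TSV, truth
JSON).

### What passing tests do and do not show

The generator draws from the same model families the analyses assume —
Gaussian sensor noise, lognormal intensities, Dirichlet-multinomial counts,
linear temperature coupling. Passing the closure and recovery tests
therefore demonstrates the *implementation* is correct and the estimators
are calibrated under those assumptions; it does not validate the
assumptions against real instruments. Real FT-ICR-MS spectra carry
isotopologues, adducts, charge states and mass-dependent calibration drift
that the assignment module deliberately does not model; real pressure
sensors drift nonlinearly; real communities are not ten genera. Results on
real data inherit those caveats.

## Numerical conventions and problem sizes

- All randomized procedures take explicit seeds; no hidden global state.
- Permutation p-values can never be zero ((count + 1)/(n + 1)).
- The test suite exercises the full 54-day, 12-vial pressure scenario at
  dt = 60 s, assignment on ~2 000-peak samples against a full-grid
  brute-force oracle, 1 000-replicate null calibrations of PERMANOVA and
  the Mantel test at 199 permutations, exhaustive-permutation oracles at
  n = 5–6, and 100-seed stability loops for the diversity-coupling
  preference — sizes chosen to give stable Monte-Carlo margins on a single
  CPU in minutes.
- `scripts/acceptance.R` regenerates the default study from a command-line
  seed and recomputes every headline quantity from scratch.

## Known limitations

- Assignment treats peaks as monoisotopic, singly charged [M−H]^−^ ions;
  no isotope-pattern scoring or spectral recalibration.
- The amplitude estimators assume the diel path rises over the light phase
  and falls over the dark phase; exotic schedules (photoperiod near 0 or
  24 h) are rejected at construction.
- PERMANOVA and dispersion inference at two samples per group is fragile
  for any implementation; the package computes the statistics but their
  small-sample behaviour is the user's responsibility.
- The compound-class boxes are stoichiometric proxies, not structural
  identifications.
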