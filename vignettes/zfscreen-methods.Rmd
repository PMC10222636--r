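---
title: "Methods: benchmark concentrations, phenotype specificity and cross-laboratory harmonization in zebrafish embryo screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark concentrations, phenotype specificity and cross-laboratory harmonization in zebrafish embryo screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfscreen)
```

## The data model

A screen places one embryo per well of a 96-well plate: a dilution series
of one test substance (7 concentrations × 11 embryos, or 11 × 7 in the
narrow-spacing design), 12 vehicle-control (VC) wells, and a 7-well
positive-control (PC) series with one embryo per PC concentration. The two
built-in layouts both satisfy the plate arithmetic
`conc × embryos + VC + PC = 96`, which `plate_design()` enforces.
Mortality is recorded at 24 and 120 hours post-fertilization (hpf) and is
treated as absorbing: an embryo dead at 24 hpf stays dead at 120 hpf. This
is the only reading under which scoring mortality at both timepoints is
coherent, and `validate_dataset()` reports any record violating it.
Phenotypes are scored only in embryos alive at 120 hpf; flags on dead
embryos are validation findings, not data.

Concentrations are stored in µM as dosed and converted to log10(molar)
only at analysis boundaries (`log10_molar()`), because dosing is naturally
expressed in µM while potency comparisons across substances and
laboratories live on the log10-molar scale. VC wells (0 µM) have no molar
value and never enter a concentration-response curve; they provide the
baseline instead.

## Endpoints

Every recorded phenotype *X* yields the combined endpoint `X+Mort@120`:
the numerator at each concentration counts embryos that are dead at
120 hpf plus survivors with the phenotype, the denominator counts all
embryos dosed there. Combining with mortality makes the expected response
monotone in concentration even when a phenotype is superseded by death at
high doses — the phenotype "disappears" from survivors, but the combined
incidence keeps rising. Two dataset endpoints are always added:
`Mortality@120` and `MalformedAny+Mort@120` (dead or malformed in any
*binary* recording). Binarized quantitative image traits are excluded from
the any-malformation endpoint: thresholded continuous readouts fluctuate
around their cutoff at baseline, and their union produces erratic,
non-monotone incidence. They keep their own combined endpoints.
`Mortality@24` is built separately and used only for QC baselines.

PC wells carry one embryo per concentration per plate — too few for a
curve — so PC data are pooled across the plates run within the same ISO
calendar week (`pool_pc_weekly()`). The ISO-week rule is a deterministic,
reproducible reading of "plates run within a week"; a sliding 7-day window
would couple pool membership to arbitrary anchor dates. Single-plate pools
are flagged `low_n` rather than dropped. Concentrations with no surviving
denominator are dropped with a warning, never imputed.

## Noise correction and BMC

Responses are first baseline-anchored by subtracting the same-plate VC
response for the endpoint, floored at 0 (`anchor = TRUE`, configurable).
The candidate BMR thresholds are interpreted as levels of baseline noise,
so the curves they are applied to should start from the plate's own
baseline; anchoring also keeps a lab with an elevated malformation
baseline from appearing active everywhere.

The noise-correction stage is a weighted least-squares isotonic
regression (`pava()`), pool-adjacent-violators with embryo counts as
weights, clipped to [0, 100]. It is a deterministic monotone projection
with the same intent as sweep-based monotone curve filters used elsewhere
in this field: report the monotone curve closest to the data and let a
response threshold define the point of departure. Fidelity to any
particular filter implementation is an explicit non-goal; the projection
is instead verified against an exhaustive level-set oracle in the tests.

`bmc_at()` reports a curve as active when its maximum corrected response
reaches the BMR; the BMC is the log10-molar concentration of the first
crossing, linearly interpolated between the bracketing tested
concentrations. Conventions at the edges:

* lowest tested concentration already at or above the BMR → BMC is that
  concentration, flagged `censored_low`;
* inactive curve → the highest tested concentration is substituted and
  flagged `censored_at_max`, so replicate variance summaries are defined
  for inactive runs (an all-inactive triplicate has variance 0, not NA);
* a flat corrected segment lying exactly at the BMR → the lowest
  concentration of the segment.

## Dataset-adaptive BMR

For each endpoint, `scan_thresholds()` evaluates every substance ×
replicate curve over a grid of candidate thresholds (default 5–95% in
steps of 5, spanning the plausible range for embryo screens) and pools the
replicate-to-replicate potency variance over substances with at least two
replicates, weighting by degrees of freedom. Censored values stand in for
inactive replicates here too; whether the original analysis pooled over
active replicates only is not documented, and substitution is the choice
consistent with how triplicate SDs are summarized downstream.

`select_bmr()` makes "the lowest threshold that stabilizes potency
estimation" concrete: fit `v(t) = a·exp(−k·t) + c` and take the smallest
grid threshold where the decay term has fallen to `tol = 0.05` of its
amplitude. Three numerical safeguards matter in practice, all visible on
simulated data:

* **Censoring tail.** Pooled-variance profiles are typically U-shaped: at
  high thresholds partially-active substances split into active and
  censored replicates and the variance re-inflates. The fit therefore uses
  the profile only up to its minimum; the rise beyond it is a censoring
  artifact, not stabilization.
* **Constrained asymptote.** The asymptote `c` is bounded near the
  smallest observed pooled variance. Unconstrained, the optimizer can
  prefer a degenerate shallow-decay solution whose plateau lies below
  every observed value, pushing the stabilization point past the grid.
* **Degenerate profiles.** A flat profile is already stable (BMR = lowest
  threshold). A decay spanning fewer than four grid points cannot support
  a three-parameter fit and takes the profile minimum. A profile rising
  from the first threshold, or one on which the fit fails, returns the
  highest threshold with `converged = FALSE` and a warning — degraded,
  never an error.

## Specificity of altered phenotypes

Per plate, `score = BMC(Mortality@120) − BMC(endpoint)` in log10 units:
positive when the phenotype appears below lethal concentrations. When
mortality is inactive its censored top-concentration value is used, so a
clearly phenotype-active but non-lethal substance earns a large positive
score; the convention is undocumented in the field and chosen here because
the alternative (dropping the score) would hide exactly the most specific
substances. When the phenotype endpoint is inactive there is no score and
the plate is non-toxic.

In theory scores are non-negative; in practice dose spacing and BMR
differences produce negative ones, and these are taken as draws from the
noise of the BMC calculation. `derive_cutoff()` mirrors that tail: the
cutoff is −Q₀.₀₅ of the negative scores, a positive number by
construction. Quantiles use linear interpolation with `h = (n − 1)p`
(R type 7); no convention is documented for the original analysis, and
type 7 is R's default and reproducible everywhere. With no negative scores
the cutoff is 0 with a warning.

Classification is strict at the boundary — specific requires
`score > cutoff`, a score exactly at the cutoff is non-specific — and
substance calls take the majority class (> 50% of plates, usually 2 of 3);
with no majority the call is inconclusive and the BMC and score of the
specific plates are reported, because the specific observations are the
ones a reader of an inconclusive call needs to judge. Blinded duplicates
are aggregated per blinded code, never merged across a pair: the pair
exists to measure reproducibility, and merging would destroy the
measurement.

## Ontology harmonization

The mapping table (recording → ontology term(s) → granular group → general
group) is a static CSV; no live ontology service is queried. Recordings
may map to several terms; terms belong to at most one granular group,
granular groups nest uniquely in general groups, and terms that do not
describe a structural change carry no group. The bundled
`ontology_map_synthetic.csv` is a *partial, synthetic* illustration
(its term labels follow field conventions but most identifiers are
placeholders); real studies supply their own table in the same layout.

`collapse_calls()` reduces substance × endpoint calls to substance ×
defect-group calls: the representative class is the highest-precedence
class present (specific > non-specific > inconclusive > non-toxic), and
ties within the winning class are broken by the most potent — numerically
smallest — log10 BMC. The collapse is idempotent, and a coarse recording
mapped to several groups propagates its call into each of them; that is a
property of the vocabulary being harmonized, not of the algorithm.

## QC gates

Three checks, all flag-only — QC never mutates or deletes data, and
exclusion is a separate opt-in (`strict_qc`), matching the practice of
keeping marginal plates with a note rather than silently discarding them:

* VC baselines for `Mortality@24`, `Mortality@120` and
  `MalformedAny+Mort@120` flagged strictly above 20% (exactly 20% passes);
* PC reproducibility: sample SD of weekly-pool BMCs per endpoint, its
  median across endpoints, and fold equivalents `10^SD`;
* blinded duplicates: per endpoint, the absolute difference of member
  median BMCs over triplicates, flagged above 0.5 log10 (~3.2-fold);
  pairs with identical medians are omitted from the plot table since they
  sit exactly on the identity line.

Sample (n − 1) SDs are used throughout. Triplicate BMC variability keeps
only substances with SD > 0 — all-inactive triplicates are identical by
censoring and would swamp the distribution with zeros.

## The synthetic study generator

`simulate_study()` exists so every stage of the pipeline is testable
against known ground truth. It reproduces the *structure* of a blinded
three-laboratory study: 35 screening substances plus 3 blinded duplicate
pairs (41 codes, 38 compounds) and one positive control; triplicate plates
per substance per lab in three consecutive weeks; 7 × 11 wide-spacing
(0.5 log10) and 11 × 7 narrow-spacing (0.2 log10) designs with a 100 µM
top concentration; 21, 9 and 21 recordings per lab, the third lab
recording 9 of its 21 as binarized quantitative traits and carrying an
elevated VC malformation baseline (15% versus 8%), which visibly trips
the any-malformation VC gate at the binomial-tail rate expected for
12-well blocks.

Mechanism: mortality follows a Hill curve in probability
(`p0 + (pmax − p0)·cˢ/(AC50ˢ + cˢ)`); death by 120 hpf is drawn per
embryo, with half the deaths occurring by 24 hpf; phenotype flags are
drawn only for survivors (the conditional model implied by the recording
protocol), with three designated recordings per substance responding
through their own Hill curve and the rest at baseline. Lethal AC50s are
drawn log-uniformly between about 3 and 50 µM — inside the tested window,
as a dose range-finding design intends — so that "specific" substances,
whose phenotype AC50 is tenfold lower, also remain resolvable above the
0.1 µM range floor; inactive compounds sit far above the top
concentration. Duplicate pairs share truth parameters exactly under
different blinded codes. Reproducibility is two-level: one global seed,
plus per-plate sub-seeds derived from a 31-bit hash of the plate id, so
any plate can be regenerated alone and full studies are byte-identical
across runs.

What the generator does **not** emulate: real vocabularies and their
many-to-one term mappings (simulated recordings map 1:1 via
`sim_ontology_map()`), correlated phenotypes within an embryo,
plate-position or edge effects, dose-preparation error, inter-lab
potency shifts from protocol differences (dosing scenario and chorion
status are carried as metadata but have no effect on the simulated
biology), and non-monotone concentration-responses. Tests passing on
simulated data therefore demonstrate the pipeline's internal correctness
and statistical behavior under idealized noise — not that any particular
laboratory's data will meet the QC gates or produce stable BMRs.

## Problem sizes and verification

The test-suite checks run at sizes chosen to make their statistics
decisive while staying quick: the isotonic projection is compared with an
exhaustive level-set oracle on hundreds of random curves of length ≤ 6
(the oracle enumerates all 2ⁿ⁻¹ block partitions); BMC parameter recovery
uses 100 simulated full-top Hill curves with 11 embryos per concentration
and requires a median absolute error below 0.25 log10 units at BMR 50; the
false-specific rate under phenotype ≡ mortality noise is measured on 200
substances × 3 plates; the noise-floor behavior of the BMR compares 12
versus 3 embryos per concentration across 10 seeded datasets; and the full
synthetic interlaboratory study (3 labs × 41 blinded substances ×
triplicates, ~35,000 wells) runs end to end, where mortality BMCs are
required to track the simulated AC50 truth (Spearman ρ > 0.9), duplicate
medians to agree within 0.5 log10 for ≥ 90% of endpoint pairs, and
substances constructed tenfold more phenotype-potent to be called specific
on their responding endpoints ≥ 90% of the time.

## Known limitations

* The stabilization rule is one concrete instantiation of "lowest stable
  threshold"; other readings (e.g., slope-based change-point detection)
  would select somewhat different BMRs on slowly-decaying profiles.
* No bootstrap confidence intervals on BMC values; replicate spread is
  summarized by SDs only.
* The relational-schema export targets generic ANSI SQL and omits
  engine-specific details (sequences, indexes, partitions).
* Ontology handling is table-driven; there is no reasoning over the
  ontology graph beyond the supplied rows.
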