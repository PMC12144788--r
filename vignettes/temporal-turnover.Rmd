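---
title: "Temporal turnover of CF lung microbiota across a pulmonary exacerbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal turnover of CF lung microbiota across a pulmonary exacerbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfturnover)
```

## The problem

Airway infections in cystic fibrosis (CF) are polymicrobial and dynamic:
taxa immigrate, go locally extinct, and recolonize over weeks to months.
Pulmonary exacerbations (PEx) — acute worsenings severe enough to warrant
antibiotics — are typically treated only after symptoms appear. An
ecological view of the lung as an island habitat suggests a different
handle: if the *rate of species turnover* in a patient's sputum microbiota
rises ahead of clinical presentation, turnover itself becomes an early
warning signal. This package implements that analysis end to end for
longitudinal taxon tables with clinical metadata: per-patient turnover
exponents, colonization classification, lung-function change models,
fine-scale turnover profiles, and threshold-based dating of PEx onset.

## Species–time relationships and the turnover exponent

The species–time relationship (STR) describes how observed richness grows
with observation time and is modelled with the power law

$$S = c\,T^{w},$$

where $S$ is cumulative observed richness over time $T$, $c$ the intercept,
and $w$ the temporal scaling exponent — larger $w$, faster turnover. Across
many taxa, habitats and time scales, reported $w$ values rarely exceed 0.5,
which makes departures from that norm interpretable.

STR curves are built with the **moving-window** method
(`accumulate_moving_window()`): for each window length $L = 1,\dots,N$, the
mean over all $N-L+1$ contiguous sample windows of the number of distinct
taxa present at least once in the window. Unlike one-direction
accumulation, this treats immigration, local extinction and recolonization
symmetrically, and every curve is non-decreasing in $L$ by construction.
The power model is fitted by ordinary least squares on the natural-log
scale (`fit_power()`); the slope is base-invariant and $c$ is the
back-transformed intercept. If every mean richness value is identical the
community shows no turnover and the fit is bypassed with the convention
$w = 0$, $R^2 = 1$, p reported as `NA` — an exact ecological reading of a
degenerate input, not an error.

Two time axes are available for whole-series fits (`str_time_unit`):

* `"sample_count"` (default): $T$ is the ordinal window length. One curve
  per patient despite uneven visit spacing, a dimensionless $w$ robust to
  sampling jitter.
* `"days"`: $T(L)$ is the mean duration spanned by windows of length $L$
  plus one mean inter-sample interval (so $T(1)$ is one mean interval, not
  zero).

## Chronic and intermittent colonization

Each taxon detected at least once is classified by **temporal
persistence** (fraction of samples in which it is present) using a
modified Leeds rule: chronic if persistence strictly exceeds 0.5,
intermittent otherwise (`compute_persistence()`). The tie at exactly 50%
is intermittent — the rule is "more than half", and this keeps the
boundary deterministic. Persistence is always computed over the whole
series; fine-scale windows reuse the whole-series labels, so a taxon's
membership never flickers between windows. Presence means relative
abundance strictly above `presence_threshold`, default 0: processed taxon
tables are assumed already denoised upstream, so any non-zero proportion
counts as a detection.

The persistence–abundance relationship (PAR, `fit_par()`) regresses log10
mean relative abundance when present on persistence. Abundance spans
orders of magnitude while persistence is a bounded fraction, hence the
one-sided log transform; regressing on log10 persistence instead is
available via `par_log_persistence` for sensitivity analysis.

## Lung function

Clinical course is summarized by cumulative absolute change in %FEV1
(percent of predicted forced expiratory volume in one second):
`cumulative_abs_change()` accumulates $|\Delta\%FEV_1|$ between
consecutive non-missing visits, and `fit_lft()` fits

$$\Delta\%FEV_1 = a\,T^{b}$$

with $T$ in days from the first usable visit. Missing values are skipped,
never imputed, with differences bridged across gaps: microbiota and
lung-function streams are fitted separately, so dropping a visit from one
does not disturb the other. Points with zero elapsed time or zero
cumulative change are excluded from the log–log fit (their log is
undefined); a constant series takes $b = 0$ by convention.

## Fine-scale profiles: the sliding quadrat

`sliding_quadrat()` moves a five-timepoint temporal quadrat one sample at
a time along the series. Within each quadrat the whole-microbiota presence
matrix is accumulated by the same moving-window method (sub-window lengths
1–5) and fitted for a local exponent `w_local`; the quadrat's %FEV1 values
give a local `b_local` when at least three strictly positive
cumulative-change points exist, and are recorded as absent otherwise.
Values are indexed at the quadrat midpoint — the third of five samples —
and its disease state, giving $N-4$ entries per patient.

**Why the quadrat fit uses elapsed days by default.** Under ordinal time
the moving-window curve obeys $S(L) \le L\,S(1)$ (a window's union richness
cannot exceed the summed richness of its samples), so the local log–log
slope is bounded near 1 no matter how violent the turnover. A conservative
alarm threshold of $w > 1$ would then be unreachable by construction, and
the very large local exponents that perturbed series produce would be
invisible. With $T(L)$ = mean sub-window span plus one whole-series mean
inter-sample interval, densely sampled clinical episodes — exacerbation
and treatment periods draw extra visits — compress the time axis relative
to the patient's usual visit rhythm exactly where richness surges, and
local exponents well above 1 emerge. This does mean `w_local` conflates
accumulation rate with local sampling density; we consider that a feature
for alarm purposes (both reflect the clinical episode) but it should be
kept in mind when comparing patients with very different visit schedules.
`quadrat_time_unit = "sample_count"` restores the ordinal variant.

Note that the whole-series $w$ is *not* the mean of the `w_local` values;
the two live on different scales and no identity links them. Note also
that `w_local` can never be negative here: mean window richness is
non-decreasing in window length and the time axis increases, so the OLS
slope is non-negative; the fitted value is reported unclipped regardless.

## Dating PEx onset

`detect_onset()` scans quadrat midpoints in date order up to the treatment
start (the whole series if the patient was never treated) and dates onset
at the first midpoint whose `w_local` strictly exceeds the threshold.
Default thresholds are 0.5 — the typical upper bound of reported STR
exponents — and the conservative 1.0, which ignores mild departures from
the norm. The lead time is the whole-day difference between treatment
start and the crossing. Design choices:

* **First exceedance**, not sustained exceedance, is the default (a single
  departure point per patient); `sustained_k` requires $k$ consecutive
  exceedances for noise-averse use.
* Crossings are dated at the **quadrat midpoint** where `w_local` is
  indexed, not at the window end.
* Crossings after treatment start never contribute a lead but are kept as
  a late-crossing diagnostic; a crossing in an untreated patient is
  flagged censored.
* Lead time is monotone non-increasing in the threshold, patient by
  patient — a structural property of the scan that the tests assert.

`cohort_onset_summary()` reports the sample mean and SD (with the $n-1$
denominator) of available lead times per threshold, plus censoring and
non-crossing counts.

## Cohort-level inference

Turnover exponents are compared between the whole-microbiota, chronic and
intermittent groups with the tie-corrected Kruskal–Wallis test (through
`stats::kruskal.test`) and Dunn's post-hoc pairwise $z$ tests computed from
pooled ranks with tie correction. The multiplicity adjustment for the Dunn
p-values defaults to Bonferroni — the most conservative of the available
choices (`none`, `bonferroni`, `holm`) — because the source analyses report
only pairwise P values without naming an adjustment. All p-values are
two-sided. The lung-function rate $b$ is regressed on $w$ across patients
with ordinary least squares and standard F diagnostics
(`regress_b_on_w()`).

## The synthetic cohort generator

`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes, plus a ground-truth table that analysis code never
reads. It emulates a processed longitudinal sputum 16S deposit, not raw
sequence data. Defaults (all overridable in `generator_params()`):

| Parameter | Default | Why |
|---|---|---|
| patients | 12, of which 2 never exacerbate | cohort sizes typical of granular longitudinal CF studies |
| series length | 221–368 days | observed range of year-scale PEx studies |
| samples (PEx) | 16–35 | routine plus emergency visits |
| samples (stable) | 6–9 | routine-only visit schedules |
| chronic core | 12 taxa, presence prob 0.9 per sample | high-persistence core incl. a dominant pathogen (lognormal abundances, one taxon ~6x the rest) |
| intermittent pool | 90 taxa | long tail of rare colonizers |
| baseline immigration | Poisson, 1.2 detections/visit; 70% recur from a 20-taxon resident subset | baseline detections are mostly recurrences, true immigration is rare |
| burst | rate x 8 from onset to treatment end; 85% drawn from the full pool | exacerbation as an immigration burst of novel taxa |
| onset | 21 days before treatment start | the latency the onset module should recover |
| visit density | 8x inside [treatment start - 30 d, treatment end + 7 d] | emergency and on-treatment monitoring visits cluster |
| %FEV1 | baseline U(25, 81), noise SD 2.5, -10 across E, +10 across T | clinically plausible spirometry course |
| coupling | 0.5 x newly detected taxa per visit, random sign | each visit-to-visit |change| grows with realized immigration — the simplest mechanism producing a positive b–w association; a modelling choice, not a claim about biology |

All randomness flows from one cohort seed through per-patient derived
seeds tied to the patient index, so a patient's series is invariant to
cohort reordering and fixed seeds reproduce byte-identical files.

**What the generator does not emulate.** Sequencing noise, compositional
count noise beyond per-sample normalization, primer/PCR bias, taxonomic
misassignment, co-occurrence structure between taxa, seasonal forcing, and
multi-PEx series. Passing tests on synthetic cohorts therefore demonstrate
that the estimators recover the generative structure they assume — they do
not certify performance on real sputum data, where the deposit's column
layout must first be mapped onto the reader formats
(`read_taxon_table()`, `read_sample_metadata()`).

## Numerical choices

* Degenerate all-equal-richness curves: $w = 0$, $R^2 = 1$, p `NA`
  (convention, both whole-series and quadrat fits).
* All-zero sample columns are rejected at load; columns are normalized to
  sum to 1 within 1e-9.
* Persistence ties at exactly the cutoff are intermittent (strict
  inequality).
* Power fits require at least 3 strictly positive points; degenerate
  equality is declared when the y-range is below 1e-12 relative.
* Dates, not sample indices, are authoritative for elapsed time; day 0 is
  each patient's first sample (first usable %FEV1 sample for lung-function
  curves), so fits are invariant to calendar shifts.
* Derived per-patient seeds stay below 2^31.

## Problem sizes in the test suite

The simulation-backed checks run at sizes chosen to finish comfortably on
one CPU while leaving the conclusions stable under the fixed seeds used:
oracle equivalence on 200 random matrices up to 25 taxa by 12 samples;
onset recovery over 100 simulated PEx patients; dose–response of $w$ over
50 seeds per immigration level; subset-ordering, lung-function-ordering
and specificity properties over 100 cohorts of 12 patients.

## Known limitations

* Per-patient $b$ is estimated from few, unevenly spaced visits with
  visit-level spirometry noise; its sampling error is comparable to the
  PEx effect size under the default generator conditions. Cohort contrasts
  on $b$ (PEx vs stable, $b$-on-$w$ slope) are therefore directional
  rather than sharply separated at $n = 12$, and the corresponding checks
  are stated as such. Tighter separation would require either calmer
  spirometry noise or more visits per patient.
* The elapsed-days quadrat exponent deliberately responds to visit
  density as well as to richness accumulation (see above).
* Onset dating resolves at the visit rhythm: the crossing is assigned to a
  quadrat midpoint, so lead times are quantized by the local inter-visit
  interval.
* Detection is retrospective: quadrats use complete five-visit windows, so
  the profile ends two visits before the series does — prospective
  streaming detection is out of scope.

## A minimal session

```{r example, eval = FALSE}
library(cfturnover)

cohort <- generate_cohort(generator_params(), seed = 101,
                          output_dir = "cohort")
series <- cohort$series$P01

profiles <- compute_persistence(series)
count_by_label(profiles)

compute_str(series, "whole", profiles)          # S = c T^w, whole microbiota
compute_lft(series)                              # dFEV1 = a T^b
fine <- sliding_quadrat(series)
detect_onset(fine, series$treatment_start, threshold = 1.0)

analysis <- analyze_cohort(cohort$series)        # the whole cohort at once
analysis$summary
```
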