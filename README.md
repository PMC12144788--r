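# cfturnover

Temporal turnover analysis of cystic fibrosis (CF) lung microbiota across
pulmonary exacerbations (PEx).

People with CF carry diverse, dynamic airway infection communities, and
exacerbations are usually treated only once symptoms worsen. Treating the
lung as an island habitat, this package measures how fast bacterial taxa
turn over within each patient's longitudinal sputum series and asks whether
a surge in turnover anticipates the clinical start of PEx treatment — an
early-warning signal for timely intervention. It is written for microbial
ecologists and respiratory-microbiome researchers working with
per-patient taxon-by-sample tables plus clinical metadata (%FEV1, BETR
disease states, treatment dates).

## What it computes

* **Species–time relationships (STR).** Moving-window species accumulation:
  for every window length *L*, the mean richness over all contiguous
  *L*-sample windows; fitted with the power law *S = cT^w*, where *w* is the
  temporal scaling exponent (higher *w* = faster turnover; values above the
  ~0.5 norm reported across ecosystems flag perturbation).
* **Colonization status.** A modified Leeds criterion labels each detected
  taxon chronic (temporal persistence > 50%) or intermittent (≤ 50%), plus
  persistence–abundance regressions (log10 mean abundance when present vs
  persistence).
* **Lung function.** Cumulative absolute change in %FEV1 fitted with
  *Δ%FEV1 = aT^b*; *b* is the patient's rate of lung-function change.
* **Fine-scale profiles.** A sliding five-timepoint quadrat yields local
  *w* and *b* at each quadrat midpoint, aligned with BETR disease states
  (B0 baseline, E exacerbation, T treatment, R recovery, B1 post-PEx).
* **Onset lead time.** The first quadrat midpoint whose local *w* exceeds a
  threshold (0.5, or conservatively 1.0) before treatment start dates PEx
  onset; the lead is reported in days.
* **Cohort statistics.** Tie-corrected Kruskal–Wallis with Dunn post-hoc
  tests comparing *w* between whole/chronic/intermittent groups, and OLS of
  *b* on *w* across patients.
* **Synthetic cohorts.** A seeded generator emulating a processed
  longitudinal sputum deposit (chronic core + rare intermittent pool,
  immigration bursts before treatment, %FEV1 trajectories, denser visits
  around exacerbation), with ground truth for validation.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → colonization → STR → lung function → fine scale/onset → cohort
report), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_colonization.R
Rscript analysis/03_turnover_str.R
Rscript analysis/05_fine_scale_onset.R
```

which prints, for the default simulated cohort (12 patients, 10 PEx with an
immigration burst starting 21 days before treatment, 2 stable):

```
Chronic taxa per patient: 12.0 +/- 0.0 (min 12, max 12)
Intermittent taxa per patient: 49.3 +/- 20.4 (min 8, max 69)
PAR slopes all positive: TRUE (range 1.19 to 1.42)

w(chronic): mean 0.018 +/- 0.011 (min 0.011, max 0.049)
w(intermittent): mean 0.853 +/- 0.071 (min 0.741, max 0.965)
w(whole): mean 0.477 +/- 0.098 (min 0.242, max 0.552)
Kruskal-Wallis across subsets: H = 31.14, p = 1.7e-07

Peak local w (PEx patients): mean 1.65 +/- 0.60 (max 2.85)
Threshold w > 0.5: lead 19.5 +/- 6.6 days (n = 10; 2 never crossed)
Threshold w > 1: lead 10.6 +/- 3.7 days (n = 7; 5 never crossed)
```

Reading this: every patient keeps a persistent chronic core (low *w*) while
the intermittent colonizers drive turnover; chronic, whole and intermittent
turnover differ strongly (Kruskal–Wallis); and in patients heading into an
exacerbation, local turnover breaches the 0.5 ecological norm about three
weeks before treatment begins — the two stable patients never cross. The
same computation on one patient in R:

```r
library(cfturnover)
cohort <- generate_cohort(generator_params(), seed = 101)
series <- cohort$series$P01
fine <- sliding_quadrat(series)
detect_onset(fine, series$treatment_start, threshold = 0.5)
#> <onset_estimate> P01 @ w > 0.5: crossed 2014-06-19, lead 18 days
```

Real data enter through `read_taxon_table()` (TSV with a `taxon_id` column,
or BIOM JSON) and `read_sample_metadata()` (CSV with patient, sample, date,
%FEV1, BETR state and treatment columns), then `assemble_patient_series()`;
`run_pipeline(input_dir, output_dir)` runs everything and writes a manifest
with content digests. The methods vignette
(`vignettes/temporal-turnover.Rmd`) documents the models, conventions and
generator assumptions.

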