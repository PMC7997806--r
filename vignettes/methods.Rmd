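---
title: "Deriving and analyzing a rapid pressor-response phenotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and analyzing a rapid pressor-response phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenotype

Phenylephrine is a selective alpha-1 adrenergic agonist given as an
intravenous bolus to treat hypotension during anesthesia. Its onset is very
rapid and its elimination half-life is 15–20 minutes, which makes the
blood-pressure excursion around a single bolus a usable acute drug-response
phenotype. `pressor` defines the response as

> delta = (maximum valid BP in the 5 minutes **after** the bolus) −
> (minimum valid BP in the 5 minutes **before** it),

computed independently for systolic (SBP), mean (MAP) and diastolic (DBP)
pressure, with no smoothing. Five-minute windows accommodate the two
monitoring regimes seen in anesthesia records: non-invasive cuff readings
every 1–5 minutes and arterial-line readings as often as every 15 seconds,
plus non-contemporaneous charting of the bolus itself.

Several definitional choices are genuinely open, and the package fixes them
as follows:

* **Validity bounds are inclusive at both ends** (SBP 60–240 mmHg,
  DBP 30–120, MAP 30–130). Written ranges carry no bracket semantics; the
  inclusive reading keeps boundary readings, which are plausible
  physiology.
* **A reading exactly at the bolus timestamp belongs to neither window** —
  it cannot be attributed to before or after the dose.
* **NIBP and arterial readings are pooled without precedence.** Both
  sources describe the same pressure; when both exist in a window the
  extremum is taken over the pool. A per-source preference rule would need
  evidence the package does not have.
* **Each bp-type's delta is computed independently**: a patient can have a
  defined delta-SBP and an undefined delta-MAP. An undefined delta is data
  (a missing window), never an error.
* **Propofol proximity is symmetric**: a phenylephrine bolus within 10
  minutes of a propofol bolus — before or after — is excluded, because
  propofol's hypotensive effect has immediate onset and ~10 minute
  duration, so contamination is possible on both sides.

## The exclusion cascade

`apply_cascade()` applies the filtering steps in a fixed order and records
a complete attrition table (procedures and patients separately). The order
is part of the contract: inclusion (≥1 phenylephrine bolus), canceled or
manually charted cases, short-duration/rapid-turnover categories
(colonoscopy and endoscopy by default, where bolus under-charting is
common), emergency cases, any blood transfusion, more than 5 L of charted
crystalloid (strictly greater), propofol-proximal boluses, first procedure
and first bolus per patient, then BMI > 100 (data-entry artifacts) and ASA
physical status 5. BMI and ASA come last, mirroring the order in which the
criteria are usually stated; the attrition table is only meaningful for the
stated order, and a test pins it. An optional minimum-duration threshold
(`min_procedure_min`) exists but is off by default — the category rule is
the primary mechanism for short procedures.

Only one bolus-response is kept per patient (the first retained bolus of
the first retained anesthetic), so between-patient comparisons and GWAS see
independent observations; a per-patient dose–response curve is explicitly
out of reach with one response per patient.

## Ancestry comparisons

`compare_ancestry_groups()` reports, per non-reference group (European
ancestry is the reference, as the comparisons of interest are "versus
EA"): group mean ± SE, the Mann–Whitney U test against the reference, and
a covariate-adjusted linear contrast (OLS of delta on ancestry indicators,
covariates, and principal components where supplied). Tests are two-sided
throughout. "Age-adjusted z-scores" are read as z-standardization of age
entered as a covariate — the covariate list names age itself among the
model terms, so the alternative reading (age-stratified phenotype
standardization) is not used.

The Mann–Whitney implementation uses midranks and computes the two-sided p
by exact enumeration of the rank-sum distribution (subset-sum dynamic
programming over ranks) whenever the data are untied and
`n_A * n_B <= 400`, and otherwise a normal approximation with tie and
continuity correction. All-tied input is degenerate and returns p = 1.

## The mixed-model scan

The association model is `y = X beta + g + e` with polygenic random effect
`g ~ N(0, sigma2_g K)` and `e ~ N(0, sigma2_e I)`, where `K` is the
allele-frequency-standardized (VanRaden) genetic relationship matrix over
polymorphic variants, with per-variant mean imputation of missing dosages.
Fixed effects are the configured covariates (age z-score, sex, BMI, ASA,
depth of anesthesia, bolus dose, crystalloid volume) plus the top ten
principal components of `K` (eigenvectors scaled by the square root of
their eigenvalues, sign fixed so the largest-magnitude loading is
positive).

`fit_lmm_null()` estimates the variance components by REML. After one
eigendecomposition of `K` the restricted likelihood is one-dimensional in
`h2 = sigma2_g / (sigma2_g + sigma2_e)`; it is maximized over
`[0, 1 - 1e-6]` by golden-section search with tolerance 1e-6, the total
variance profiled out analytically, and the boundary candidates checked
explicitly so that data without polygenic signal land exactly on `h2 = 0`
(where the fixed effects provably reduce to OLS). REML rather than ML
avoids the downward bias in variance components from estimating the fixed
effects.

`score_test()` then tests each variant against the fitted null without
refitting: with `P` the null-model projection, the statistic is
`(g'Py)^2 / (g'Pg) ~ chisq(1)`, `beta = g'Py / g'Pg` and
`se = 1/sqrt(g'Pg)`. As is standard for score tests, the SE uses the
null-model variance; at `sigma2_g = 0` the effect estimate coincides with
OLS exactly and the SE with the OLS formula evaluated at the null residual
variance. No MAF filter is applied (rare non-responder variants are the
point), but variants with minor-allele count below 3 are flagged unstable,
and monomorphic variants are skipped with a reason. Stratified scans (the
whole cohort plus each ancestry with ≥ 50 samples) recompute the GRM and
the PCs within each stratum; within-stratum axes are the relevant
confounder there, and the alternative (reusing cohort-wide PCs) would
leave within-group structure unmodeled. Genomic inflation is summarized as
`lambda_GC = median(qchisq(1 - p, 1)) / 0.4549364`.

## Region enrichment

`permutation_enrichment()` asks whether candidate regions (e.g. known
blood-pressure loci, built as index position ± 500 kb — 1 Mb total — by
`make_loci_regions()`) contain more association signal than size-matched
random regions. A region is *hit* when it contains at least one variant
with `p` below the threshold (1e-3 by default). The null distribution
comes from `n_perm` draws of one random region per template with exactly
the same length: chromosome chosen with probability proportional to length
among chromosomes that can hold the region, start uniform over valid
positions. Random regions may overlap the candidate regions (forbidding
that would distort the marginal null) but not each other within one draw;
overlap within a draw is resolved by resampling only the offending
regions, which preserves each region's marginal distribution and is the
only practical scheme when the template covers a non-trivial genome
fraction. The empirical p uses the plus-one estimator
`(1 + #{null >= observed}) / (1 + n_perm)` and is therefore never zero.
Matching is by exact length only — not SNP density, gene density or LD.

## The synthetic cohort generator

`simulate_cohort()` produces all five input tables plus genotypes and a
ground-truth record, so every stage is testable with known answers. What
it emulates:

* **Population structure.** Genotypes follow the Balding–Nichols model:
  ancestral frequency uniform on (0.05, 0.95), per-ancestry frequencies
  drifted with `F = 0.1` per group (a typical continental-scale value), so
  Hardy–Weinberg holds within groups while frequencies differ between
  them. Non-responder variants are forced to ~1% MAF in one target
  ancestry and absent elsewhere, mirroring the rare ancestry-specific
  variants whose carriers show no pressor response; their mechanism is a
  multiplicative amplitude factor (0 by default), consistent with carrier
  mean responses near zero.
* **Pharmacodynamics.** Each bolus adds
  `A * (dose/100) * g(t)` to the systolic signal, where `g` rises linearly
  to 1 at 60 s and decays exponentially with a 17.5 min half-life (the
  midpoint of the physiologic 15–20 min range). The linear-rise /
  exponential-decay shape is the simplest one consistent with a very rapid
  onset and first-order elimination; nothing sharper is identifiable from
  a 15 s grid. Propofol subtracts a boxcar of depth 15 mmHg for 10
  minutes with a short exponential tail. MAP is generated as
  `DBP + (SBP − DBP)/3` — the standard one-third-pulse-pressure formula —
  so all three phenotypes exist at every reading.
* **Sampling.** 40% of procedures are monitored by arterial line (15 s
  grid), the rest by NIBP (180 s cycle); per-reading Gaussian noise of
  3 mmHg (oscillometric repeatability scale) is added independently to the
  three series. Because the phenotype is a max-minus-min over windows,
  reading noise inflates the extracted delta — more strongly on dense
  arterial grids — exactly as it would in real records.
* **Cohort shape.** Demographics use ancestry-specific means (age 61/54.8/
  54.9, BMI 27.9/31/30.3 for EA/AA/HA; cohort means ≈ 56.8 y and 29.7),
  1.4 cases per patient, 4.4 boluses per case, and a dose mix with median
  100 µg. The default amplitude is 15 mmHg per 100 µg with a +5 mmHg
  European-ancestry shift and +1 for Hispanic/Latino, 6 mmHg
  between-patient SD, and centered covariate effects (age, BMI, ASA, MAC,
  crystalloid) so the configured mean amplitude is preserved. Exclusion
  flags are drawn at marginal rates of 1–5% per criterion (ASA 5 and
  BMI > 100 at 0.2%).

What it does **not** emulate: heart rate, baroreflex feedback, surgical
stimulation, volume status, infusions (as opposed to boluses), ICD-coded
comorbidity derivation (the comorbidity index is carried as a precomputed
integer), or linkage disequilibrium beyond single-variant drift. Passing
tests therefore demonstrate correctness of the *pipeline* under a
structurally faithful data model, not physiologic realism: parameter
recovery on this generator says the estimators are right, not that real
operating-room data meet their assumptions.

Within-patient variability across repeated boluses is not characterized by
any data available to the package; a per-bolus amplitude jitter parameter
(`pd_bolus_jitter_sd`) exists but defaults to 0.

## Numerical choices and problem sizes

* Timestamps are ISO-8601 in files and integer epoch seconds in memory
  (15 s is the finest cadence, so second resolution suffices).
* Genotype readers never impute; mean imputation happens per variant
  inside the scan, within the tested stratum.
* REML tolerance is 1e-6 on `h2`; the GRM must have smallest eigenvalue
  above −1e-8.
* BED files are 0-based half-open on disk and converted exactly to the
  internal 1-based inclusive convention.
* The test suite runs the generator end to end at 2000 patients × 5000
  variants (the package's reference problem size), heritability recovery
  at n = 2000, score-test calibration at 10^4 variants, and enrichment
  calibration with 500 meta-replicates of 200 permutations over 600
  size-matched 1 Mb regions; these sizes give the property checks adequate
  statistical resolution while staying desk-scale.
* The enrichment calibration fixture uses many regions deliberately: the
  plus-one estimator is discrete, and with few regions the null hit-counts
  tie heavily, making the test conservative rather than informative.

## Limitations

* The derived response is a single max-minus-min contrast; it is biased
  upward by reading noise (more so on dense grids) and carries no
  uncertainty per patient. Comparisons between monitoring regimes should
  adjust for source if the mix differs between groups.
* One response per patient precludes dose–response modeling.
* The mixed model assumes Gaussian residuals and a single GRM variance
  component; rare-variant tests at minor-allele counts below ~3 are
  reported but flagged unstable rather than suppressed.
* The enrichment null matches regions on size only; density or LD matching
  would require annotation the package does not carry.
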