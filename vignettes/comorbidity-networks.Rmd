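---
title: "Methods: comorbidity networks from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity networks from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

comorbnet estimates which ICD-10 diagnosis codes co-occur in the same
patients more often than chance, from longitudinal claims extracts, and
tracks how those co-occurrence patterns move through time. This vignette
is the package's methodological account: the model and its assumptions,
the parameters that matter, what the synthetic generator does and does
not emulate, the numerical choices, and the limitations we know about.

## The unit of analysis: the patient-year

A claim row is a billing event, not a disease observation: one patient
with COPD may generate fifty claims a year carrying J44.9, another only
two. All counting therefore happens on **patient-year diagnosis sets**:
every code (primary or secondary) recorded for a patient within one
calendar year collapses into a set, so a disease pair is counted at most
once per patient per year, and the same patient observed in two years
contributes two independent observations. This choice has three
consequences worth stating plainly:

* **Claim-duplication invariance.** Duplicating any claim row leaves
  every co-occurrence count, and hence every downstream statistic,
  unchanged. This is a tested property, not an aspiration.
* **Calendar windows.** "Twelve-month windows" are implemented as
  calendar years (Jan 1–Dec 31). A rolling window anchored per patient
  would be an alternative reading; it is deliberately *not* implemented,
  because per-year trend counts and the once-per-patient-per-year
  deduplication rule are only jointly coherent on a fixed calendar grid.
* **Pooling.** The pooled co-occurrence matrix over the study span is
  exactly the element-wise sum of the per-year matrices (also tested).

## Pairwise association and the network

For each unordered code pair we form binary presence vectors indexed by
the patient-year entries of the chosen window and compute Spearman's
rank correlation — the Pearson correlation of mid-ranks, which on binary
data equals the phi coefficient of the 2×2 contingency table. Spearman's
ρ is used rather than the raw odds ratio because it is bounded, handles
the heavy ties of binary data through mid-ranks, and doubles as an edge
weight with a meaningful zero.

P-values are two-sided. For n ≥ 30 observations we use the standard
t-approximation t = ρ√((n−2)/(1−ρ²)) on n−2 degrees of freedom. Below
n = 30 the approximation is poor for heavily tied data, so we switch to
permutation: full enumeration of the distinct permutations of one vector
when there are at most 10,000 of them (for binary data this is
choose(n, k), usually enumerable), otherwise a seeded Monte-Carlo test
with 10,000 draws and the add-one correction so a Monte-Carlo p-value is
never exactly zero.

Edges are pairs with p < α; the default is α = 0.05 on **raw** p-values.
Uncorrected screening is the convention this kind of claims network
analysis typically reports, and it is what the package reproduces by
default; because that convention is known to admit false positives, the
Benjamini–Hochberg step-up adjustment is implemented (and tested against
the step-up definition exactly) and can be switched on with
`use_adjusted = TRUE`. Constant presence columns (a code absent from, or
present in, every entry of a window) cannot be ranked; they are flagged
degenerate and excluded from edges rather than raising an error, so a
rare code never aborts a batch run.

Two codes being tested on the *same* patient-year index is what makes
the pairwise tests comparable; an alternative "year-series" mode
(correlating the short per-year count series of a pair) is sometimes
seen in figures of this genre, but with five yearly observations it has
essentially no inferential content, so patient-year vectors are the only
mode the package defends.

### Hubs, ties, and why strength matters

`node_centrality()` reports degree (number of significant partners) and
strength (Σ|ρ| over them), ranking by degree, then strength, then code —
a fully deterministic ordering. Strength is deliberately placed ahead of
the lexicographic tie-break. The reason is a selection effect users of
this package should know about: the correlation universe is the set of
claims-bearing patient-years, so patient-years in which *no* study code
produced a claim are invisible. Conditioning on "at least one observed
code" induces a weak negative dependence among otherwise independent
codes (a Berkson-type effect; we measure |ρ| ≈ 0.05 in cohorts of ten
codes at prevalence 0.2 with mean emission 2 claims/condition-year).
At tens of thousands of patient-years such associations are
*statistically* significant, the significant-edge graph saturates toward
completeness, and degree alone stops discriminating. Strength still
does: genuine comorbidity edges carry |ρ| several times larger than
selection artifacts. This is a property of any significance-screened
co-occurrence network at claims scale — large n makes trivial effects
significant — and is the single best argument for inspecting edge
weights (or enabling BH adjustment) rather than reading the topology
alone.

The force-directed (Fruchterman–Reingold) layout uses |ρ| as the spring
weight, a fixed iteration count (100) and seeded initial positions, so a
given network and seed always reproduce the same coordinates, which
travel with the GraphML export.

## Trends and disruption screening

`pair_counts_by_year()` gives each selected pair its yearly patient-year
co-occurrence count, zero-filled across the study span. Disruption
screening works on relative year-over-year changes
(c_t − c_{t−1})/c_{t−1}: a **dip** is a change ≤ −0.2, a **rebound** a
change ≥ +0.2 occurring after some dip of the same pair. Relative rather
than absolute change makes pairs of very different magnitude commensurable.
The 0.2/0.2 defaults are package choices exposed in the configuration —
disruption magnitudes in published claims analyses are typically reported
qualitatively, so there is no field constant to inherit. Years whose
previous count is zero are skipped (no infinities), and partial-coverage
years (an extract ending mid-year) are either excluded from change
statistics (`"flag"`, the default) or linearly rescaled by coverage and
marked as estimates (`"scale"`).

## The synthetic cohort generator

Real claims warehouses sit behind data-use agreements, so the package
ships a generator whose outputs have *known* structure, making every
downstream stage testable against ground truth.

Disease presence is a Gaussian copula: for each patient-year a latent
multivariate normal Z is drawn and code j is present iff
Z_j > Φ⁻¹(1 − prevalence_j). A planted pairwise odds ratio is converted
to a latent correlation by bisection against a bivariate-normal
upper-orthant probability, evaluated by one-dimensional quadrature of
φ(x)·Φ((rx − b)/√(1−r²)); the bisection tolerance on the achieved odds
ratio is 1e−6. At prevalences 0.5/0.5 the orthant probability has the
closed form 1/4 + arcsin(r)/2π, which gives the test oracle r = 0.5 for
OR = 4. Latent correlations for unplanted pairs default to zero; the
implied matrix must be positive definite, and an explicit
`repair_pd = TRUE` flag allows eigenvalue clipping (at 1e−8, with
rescaling to unit diagonal) when a user wants an approximate repair
instead of an error.

Claims are then emitted per (patient, year, present condition) with a
Poisson count of mean `encounters_per_condition × disruption[year]`, a
uniform service date within the year, and one diagnosis code per claim
row. Putting the utilization shock on *emission*, not on presence,
mirrors what a pandemic-year care dip does: patients remain sick, they
just generate fewer encounters. Because the co-occurrence stage works on
patient-year sets, it must reassemble comorbidity across claims — which
is exactly the path the real analysis takes. Demographics are drawn once
per patient (age from a normal truncated to [0, 90]; sex Bernoulli) and
held fixed across years.

Defaults describe the study conditions the package targets: ten focal
codes at realistic annual claims prevalences (hypertension 0.25,
hyperlipidemia 0.22, anxiety 0.12, type 2 diabetes 0.10, GERD 0.10,
asthma 0.08, COPD 0.06, pneumonia 0.02, COPD with exacerbation 0.015,
acute respiratory failure 0.01), odds ratios 2–4 planted around the two
respiratory codes and the cardiometabolic cluster, mean age 53.8
(SD 21.7), female fraction 0.574, years 2020–2024, 2 encounters per
condition-year, and a 2022 emission multiplier of 0.6.

What the generator does **not** emulate — and therefore what passing
tests do and do not show about real data: no disease persistence across
years (presence is redrawn i.i.d. given prevalence, whereas chronic
disease is strongly autocorrelated), no age- or sex-dependent
prevalence, no care-seeking selection or coding variation across
providers, and no code hierarchy (each normalized string is its own
condition). Tests on synthetic cohorts validate the *pipeline's
arithmetic and inference* under a known truth; they do not validate
claims data as a measure of disease.

## Numerical choices and degenerate inputs

* ICD-10 normalization: trim, uppercase, remove one dot, validate
  against `^[A-Z][0-9]{2}[A-Z0-9]{0,4}$`; idempotent by construction.
* Percentages are rounded half away from zero at one decimal (base R's
  `round()` rounds half to even, which is not how cohort tables are
  reported); age quartiles use the median-of-halves convention.
* Ages above 90 are top-coded to 90, matching the de-identification
  convention of claims extracts; sex values other than F/M map to "U".
* Rows with unparseable dates or no valid diagnosis code are dropped and
  counted in a load report, never silently.
* Empty networks (no pair passes) are a valid result, not an error; the
  empty edge list exports and plots cleanly.
* End-to-end determinism: one seed drives indicator sampling, claim
  emission, permutation tests and layout, and `run_pipeline()` writes an
  MD5 manifest so reproducibility is checkable at the artifact level.

## Validation problem sizes

The test suite validates the copula at 50,000 patient-years (planted
OR = 4 recovered within [3.7, 4.3]); type-I error over 1,035 independent
pairs at 1,000 patient-years each (observed rate ≈ 0.048 at α = 0.05,
and BH-adjusted null discoveries are zero in ≥ 90% of 20 replicates);
hub recovery over 20 replicate cohorts of 10,000 patients × 10 codes
(the planted hub, odds ratio 3 to five partners, is top-ranked in ≥ 95%
of replicates — see the tie-break discussion above for why strength is
part of that ranking); and disruption recovery over 20 seeds × 2 planted
pairs with a 0.5 emission multiplier in 2022 (the 2022 dip flagged in
all cases measured). These sizes are chosen so the whole suite runs in a
few minutes on a single CPU while leaving each Monte-Carlo check enough
resolution to be meaningful.

## Known limitations

Beyond the generator's simplifications listed above: the pipeline treats
codes as exact normalized strings (no J44.x rollup); the significance
screen at claims scale saturates for the reasons discussed, so network
topology should be read jointly with edge weights; uncorrected p-values
are the default by design and inherit the false-positive risk that
convention carries; and partial-year rescaling assumes uniform claim
intensity within a year, which seasonal conditions (pneumonia) violate.
None of these are silent: each surfaces in the configuration, the run
log, or a flagged column.
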