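# comorbnet

Comorbidity networks from ICD-10 healthcare claims.

Chronic respiratory diseases (asthma, COPD, pneumonia, respiratory
failure) rarely occur alone: they travel with hypertension,
hyperlipidemia, type 2 diabetes, GERD, anxiety and depression. One way to
see this structure at population scale is to treat de-identified billing
claims as longitudinal observations of diagnosis codes, and ask which
codes co-occur in the same patients more often than chance. comorbnet
implements that analysis as a tidy, fully tested R pipeline for
epidemiologists and health-services researchers working with claims
extracts:

1. **Ingestion** — read delimited claims (one row per claim: patient,
   service date, primary + secondary ICD-10 codes, age, sex), normalize
   codes across dotted/undotted dialects, and summarise cohort
   demographics at the record level.
2. **Patient-year aggregation** — collapse all codes recorded for a
   patient within a calendar year into a set, so each disease pair is
   counted at most once per patient per year, and build the symmetric
   co-occurrence matrix.
3. **Association network** — for each unordered code pair *(a, b)*,
   compute Spearman's rank correlation of the binary presence vectors
   over patient-years,

   ρ(a,b) = corr( rank(x_a), rank(x_b) ),

   which on binary data equals the phi coefficient of the 2×2 table.
   Pairs with two-sided *p* < α (default 0.05, raw; Benjamini–Hochberg
   adjustment available) become edges of an undirected network weighted
   by ρ. Hubs are ranked by degree, then strength Σ|ρ|; a seeded
   force-directed layout makes figures reproducible.
4. **Trends** — per-pair yearly co-occurrence counts, partial-year
   handling (flag or rescale), and disruption screening: year *t* is a
   *dip* if (c_t − c_{t−1})/c_{t−1} ≤ −0.2 and a later year a *rebound*
   if the relative change is ≥ +0.2 (thresholds configurable).
5. **Synthetic cohorts** — because real claims warehouses sit behind
   data-use agreements, a Gaussian-copula generator plants known per-code
   prevalences and pairwise odds ratios (latent correlation solved by
   bisection against a bivariate-normal orthant probability), realistic
   demographics, and per-year utilization shocks, so every stage can be
   validated against ground truth.

## Worked example

```r
library(comorbnet)

cfg    <- default_cohort_config(n_patients = 2000, seed = 42)
claims <- simulate_cohort(cfg)       # 17,827 claims, 1,948 patients, 2020-2024
summarize_cohort(claims)
#>   n_records age_mean age_sd age_median age_q25 age_q75 ... pct_female pct_male
#> 1     17827     52.5   19.1         53      39      67 ...       57.6     42.4

sets  <- aggregate_patient_windows(claims)
tests <- pairwise_associations(sets, names(cfg$codes))   # 45 pair tests
net   <- build_network(tests)
net
#> <disease_network> 10 nodes, 30 edges (alpha = 0.05, raw p-values, window pooled)

head(node_centrality(net), 5)
#>   code  label            degree strength  rank
#> 1 K219  GERD                  8    0.677     1
#> 2 I10   Hypertension          7    0.667     2
#> 3 J189  Pneumonia             7    0.325     3
#> 4 F419  Anxiety disorder      6    0.622     4
#> 5 E785  Hyperlipidemia        6    0.504     5

tr <- trend_series(pair_counts_by_year(
  sets, tibble::tibble(code_a = "E785", code_b = "I10")))
glance(detect_disruption(tr))
#>   code_a code_b dip_years rebound_years n_dips n_rebounds max_drop
#> 1 E785   I10    2022      2023               1          1   -0.282
```

Reading the output: the cohort's record-level demographics match the
generator's configuration (57.6% female records, mean age 52.5). The
pooled network keeps the 30 of 45 pairs whose Spearman association passed
*p* < 0.05; degree counts significant partners while strength sums |ρ|
over them, and the cardiometabolic cluster (hypertension, hyperlipidemia,
GERD, anxiety) planted with the largest odds ratios carries the highest
strengths. The hyperlipidemia–hypertension pair shows a 28% drop in
patient-year co-occurrence in 2022 — the generator's planted utilization
shock — followed by a 2023 rebound, exactly the dip/rebound pattern the
disruption screen is designed to flag.

`autoplot(compute_layout(net, seed = 1))` draws the network;
`plot_trends(tr)` draws the trend lines. `run_pipeline()` (or
`inst/scripts/comorbnet-pipeline.R` from a shell) chains all stages and
writes every artifact — cohort summary, matrices, edge tests, GraphML
network, centrality, trends, disruption report — plus a manifest of MD5
checksums; identical configuration and seed reproduce identical
checksums.

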