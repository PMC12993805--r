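# peatfire

Tools for synthesising macroscopic charcoal records from tropical peat
cores into regional fire-history composites, for palaeoecologists and
fire-regime researchers working with multi-site charcoal compilations.

Peat profiles preserve macro-charcoal (> 100 µm) from local burning, but
individual records differ in quantification method, sampling resolution
and chronological quality. `peatfire` provides the full standardisation
and synthesis chain as tidyverse-style functions:

* **Monte-Carlo age-depth ensembles** from calendar-age controls
  (piecewise-linear, rejection-sampled monotone draws, median
  chronology), with the ≥ 2-controls-in-3000-yr quality rule;
* **influx conversion** (concentration × accumulation rate) and the
  **proportional relative scaling (PRS)** transform
  `PRS_i = (C_i / C_max) · 100 · (f / N)`, which puts records counted
  in different units on a common 0–100 scale down-weighted by each
  record's proportion of charcoal-bearing samples;
* **composite curves**: 25-yr binning over 0–2000 CE, tricube local
  linear smoothing with a 200-yr metric window, and a site-resampling
  bootstrap (1000 reps, 5–95 % limits), plus an 800-km haversine buffer
  for pairing landscape records;
* **at-most-one-change (AMOC)** detection of a joint mean/variance
  shift on composite curves (Gaussian profile deviance, MBIC-style
  `4 log n` penalty);
* a per-site **20th-century change map** (mean PRS 1900–2000 CE minus
  0–1900 CE, classified into eight signal classes);
* **site statistics**: Kruskal-Wallis and one-way ANOVA group tests,
  correlation-matrix PCA of climate space, and correlation-screened
  multiple regression with backward elimination;
* a **synthetic-data generator** that emulates a ~58-site tropical
  compilation with known fire regimes, so every stage can be verified
  against ground truth.

## Worked example

Generate the default synthetic study (58 sites, 16/15/16/8/3 across
the Neotropical, Afrotropical, Indomalayan, Australasian and Oceanian
realms, with a ×5 influx step at 1900 CE injected into Indomalayan and
Australasian sites and a ×0.5 step elsewhere) and run the full
pipeline:

```r
library(peatfire)

study <- synth_study(n_sites = 58, seed = 7)
run <- run_pipeline(study, pipeline_config(), seed = 7,
                    group_by = "region")
run
#> <peatfire_run> 58 of 58 sites included; 5 composites; 58 sites in the change map
#>   significant change-points: region:Afrotropical @ 1900 CE;
#>   region:Australasian @ 1875 CE; region:Indomalayan @ 1875 CE;
#>   region:Neotropical @ 75 CE; all @ 1900 CE

dplyr::select(run$changepoints, group, tau_year, statistic, significant)
#> # A tibble: 5 × 4
#>   group               tau_year statistic significant
#> 1 region:Afrotropical     1900      29.0 TRUE
#> 2 region:Australasian     1875     213.  TRUE
#> 3 region:Indomalayan      1875     178.  TRUE
#> 4 region:Neotropical        75      44.8 TRUE
#> 5 all                     1900      91.6 TRUE

run$stats$kw_region_delta
#> # A tibble: 1 × 5
#>   statistic    df     p_value     n     k
#> 1      37.4     4 0.000000152    58     5
```

The Indomalayan and Australasian composites place their change-points
at 1875 CE — the bin boundary nearest the injected 1900 CE regime shift
once 25-yr binning and 200-yr smoothing have spread the step — while
the Kruskal-Wallis test on the per-site 20th-century deltas separates
the regions decisively (p ≈ 1.5e-7). The change map classifies the
break-carrying sites as positive signals (e.g. 7 of 16 Indomalayan
sites "strong positive") and the Neotropical/Afrotropical sites as
predominantly weak-negative, matching the injected contrast.
`autoplot(run$composites[["region:Indomalayan"]])` draws the composite
with its bootstrap band, and `plot_change_map()` maps the classified
sites.

Real compilations enter the same way: three delimited tables
(`sites.csv`, `charcoal.csv`, `age_controls.csv`; see
`?read_site_tables` for the schema) read with `read_site_tables()` or
processed end-to-end with `run_pipeline_dir(in_dir, out_dir)`, which
also writes every result table as CSV plus a JSON manifest recording
configuration, seed and per-site exclusion reasons.

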