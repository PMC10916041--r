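# mapsrts

Scoring, inter-rater reliability, and observation-route sampling for the
**Micro-scale Audit of Pedestrian Streetscapes for Safe Routes to School
(MAPS-SRTS)** instrument — a 90-item direct-observation audit of the street
environment around schools, built for researchers, planners and Safe Routes
to School practitioners who need reliable, comparable measurements of how
supportive a school's streetscape is for children walking and bicycling.

The package provides:

* a **machine-readable scoring dictionary** for the instrument's three
  sections — school access segments (33 items), other segments near school
  (30 items), crossings (27 items) — in its initial (30-subscale) and final
  (26-subscale) versions, with validation, versioning and diffing;
* the **hierarchical valence scorer**: item points sum into leaf subscales
  per audited unit and across units, then

  ```
  overall_section = overall_positive − overall_negative
  total           = Σ section overalls
  ```

  so a higher total always means a more walkable, bikeable school
  environment;
* the **reliability engine**: one-way random-effects single-measure
  intraclass correlation, ICC(1,1) = (MSB − MSW)/(MSB + (k−1)·MSW), with
  the exact F-based confidence interval, an inclusive 0.60 acceptability
  threshold, stepwise item pruning, and the subscale retention decision
  rules (remove on low reliability unless a same-content counterpart
  subscale is reliable or a registered recode — the >4-lane road-width
  dichotomy — restores it);
* the **nearest-neighbor observation-route sampler** on street-network
  graphs: all crossings touching the school access segment, then every
  incident segment on one side of the street, with school driveways counted
  as crossings without splitting their segment;
* a **synthetic-data generator** producing paired-rater audit datasets with
  per-subscale target ICCs (calibrated rater noise over a latent
  between-school propensity), so the whole pipeline is testable without
  field data.

## Worked example

Simulate a 36-school paired-rater study in which four subscales — the
buffer and shade subscales of both segment-type sections — are engineered
to have near-zero agreement, then run the full reliability workflow:

```r
library(mapsrts)

schema <- load_schema(version = "initial_v1")   # 30 subscales
net    <- generate_grid_network(3, 3)           # school mid-block

audits <- generate_rater_audits(schema, net, agreement_spec(
  target_icc = c(sas_positive_buffer = 0.05, sas_positive_shade = 0.05,
                 seg_positive_buffer = 0.05, seg_positive_shade = 0.05,
                 default = 0.95),
  n_schools = 36, seed = 42))

study <- run_reliability_study(audits, schema)
study
#> MAPS-SRTS reliability study
#>   subscales tested: 30; initially acceptable: 26
#>   removed: 4; revised: 0; retained via counterpart: 0
#>   retained in final schema: 26 (86.7%)
```

The four engineered subscales are the four removed; all 26 reliable ones
survive. Individual pieces are just as accessible:

```r
score_school(audits[[1]], schema)
#> MAPS-SRTS score report: school school_001, rater pair pair_1
#>   school_access_segment  overall 6
#>   other_segment          overall 34
#>   crossing               overall 21
#>   total: 61

icc_oneway(build_rating_matrix(audits, "total", schema))
#> ICC(1) [total] = 0.919 (95% CI 0.848, 0.958)
#>   n = 36 subjects, k = 2 raters; MSB = 561.6, MSW = 23.72
```

Here the total and the three section overalls are sums of item points
(positive minus negative), and the ICC row reports how much of the score
variance is between schools rather than between rater pairs — 0.92 means
the two independent field teams order the 36 schools almost identically.

A thin command-line interface over the same functions ships in
`inst/cli/mapsrts.R` (subcommands `schema`, `audits`, `score`,
`reliability`, `route`, `simulate`, `study`).

## Documentation

The methods vignette (`vignettes/mapsrts-methods.Rmd`) documents the
scoring model and its assumptions, the ICC estimator and interval, the
retention decision rules, the route-sampling conventions, what the
synthetic-data generator does and does not emulate, and the package's
numerical choices and known limitations.
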