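---
title: "Scoring and reliability methods for school streetscape audits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and reliability methods for school streetscape audits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapsrts)
```

## The instrument and its data model

The Micro-scale Audit of Pedestrian Streetscapes for Safe Routes to School
(MAPS-SRTS) is a direct-observation instrument for the street environment
children traverse on the way to school. Trained two-person field teams (a
*rater pair*, treated throughout as a single rating source) walk a fixed
observation route around a school and record 90 items in three sections:

* **school access segment** (33 items) — the street segment(s) directly
  fronting the main school entrance;
* **other segments near school** (30 items) — the surrounding blocks on the
  route;
* **crossings** (27 items) — every place the route traverses an
  intersection or school driveway.

`mapsrts` encodes the instrument as a machine-readable dictionary
(`maps_dictionary_path()`): each item carries a response domain (binary,
ordinal, count), a score map, a valence (positive, negative, or unscored)
and its subscale assignment. Two instrument versions are materialized from
the same dictionary: `initial_v1` with 30 non-total subscales (11/11/8 per
section) and `final_v2` with 26 (9/9/8), the version that survived the
reliability-driven revision described below.

```{r}
load_schema(version = "initial_v1")
load_schema(version = "final_v2")
```

## Hierarchical scoring with valence

Item points are summed into leaf subscales per audited unit, and summed —
not averaged — across the units of a school (a school with nine audited
segments accumulates roughly nine segments' worth of points). Summation is
the aggregation consistent with the instrument's published subscale score
magnitudes, where multi-unit sections score several times higher than the
single-unit access-segment section with identical item content. Leaf
subscales roll up as

$$\text{overall}_{\text{section}} =
  \sum \text{positive leaves} - \sum \text{negative leaves}, \qquad
  \text{total} = \sum_{\text{3 sections}} \text{overall}_{\text{section}},$$

so a higher total always denotes an environment more supportive of walking
and bicycling to school: raising any positive-valence response can never
lower a score, and raising a negative-valence one can never raise it. These
identities hold exactly for every audit and are enforced by property tests.

Two numerical conventions deserve mention:

* **Road width.** The original coding trichotomized the sum of travel and
  turn lanes. The published revision replaces it with a dichotomy — one
  negative point when travel + turn lanes exceed 4 — reflecting crash-risk
  evidence for roads wider than four lanes. The dichotomy is pinned down
  exactly; the original trichotomy bands are not printed anywhere, so the
  package reconstructs them as ≤ 2 → 0, 3–4 → 1, > 4 → 2. Only the revised
  rule feeds the final instrument.
* **Removed subscales.** When a subscale is removed (buffer, shade), its
  items are kept in the dictionary as *unscored* so audits collected under
  the initial version re-score under the final version without data loss.

## Inter-rater reliability: ICC(1) with an exact F interval

Reliability of a subscale is the one-way random-effects single-measure
intraclass correlation of the schools × rater-pairs score matrix. With
between/within mean squares from the one-way ANOVA decomposition,

$$\widehat{\rho} = \frac{MS_B - MS_W}{MS_B + (k - 1) MS_W},$$

and the confidence interval maps the F quantiles of $MS_B/MS_W$ on
$(n-1,\; n(k-1))$ degrees of freedom through $(F^*-1)/(F^*+k-1)$
(Shrout & Fleiss's ICC(1,1)). This estimator was chosen because it is the
standard estimator bearing that name, admits negative estimates (observed
for the buffer and shade subscales), and produces the strongly asymmetric
intervals typical of $n = 5$ reliability subsamples. Defaults are
$\alpha = 0.05$ and an acceptability threshold of 0.60, *boundary
inclusive*.

Degenerate matrices are handled explicitly rather than silently: a matrix
with no variability at all yields an *undefined* result (the analogue of an
"N/A" reliability entry), and perfect agreement with between-school spread
yields an estimate of exactly 1 with no finite interval. The estimate is
bounded below by $-1/(k-1)$.

```{r}
icc_oneway(cbind(c(1, 3, 5, 7, 9), c(2, 3, 4, 8, 9)))
```

## Retention decision rules

The instrument revision is reproduced by `apply_retention_rules()`, a pure
function of the classifications:

1. acceptable subscales are retained;
2. a failing subscale with a registered recode is *revised* (road width);
3. a failing or undefined subscale whose counterpart — the subscale with
   identical item content in the other segment-type section — is acceptable
   is retained (`retain_by_counterpart`); lack of variability on a section
   with typically one audited unit is not taken as evidence against the
   item content itself;
4. anything else is removed; composite parents are re-derived over their
   surviving children.

"Theoretical relevance", the qualitative criterion accompanying these rules
in practice, is operationalized *only* through the counterpart and revision
mechanisms — the two mechanisms that were actually exercised — since no
broader notion of relevance is computable from audit data. Encoding the
published initial classifications (22 of 30 acceptable; buffer and shade
failing in both segment-type sections; bicycle infrastructure undefined on
the access segment; the overall-positive and overall access-segment
composites failing; road width failing before its recode) yields exactly
four removals and 26 retained subscales (86.7% retention), with the revised
schema structurally identical to `final_v2`.

`stepwise_prune()` complements the rules: it removes the least reliable
child of a failing subscale one at a time, re-estimating the parent's ICC
after each removal, until acceptability is restored or one child remains.

## The observation route

Routes are sampled from a street-network graph (intersections = nodes,
segments = edges; driveways are point annotations on an edge — they count
as crossings but never split their segment) by the nearest-neighbor rule:
all crossings touching the school access segment(s), then every segment
incident to those crossings, audited on one side of the street. Design
choices the field protocol leaves open were fixed as follows:

* **Frontage is declared, not inferred.** Access segments come from
  `access_edge_ids` when present (entrances are confirmed manually in
  practice); otherwise the edges incident to the entrance node are used.
* **Which side of the street** is unspecified in the protocol beyond "one
  side" (the two sides of a segment correlate highly). The default label is
  the side toward the school, recorded explicitly in the output so field
  teams can override it.
* **Mid-block driveways on non-access segments** are not crossings; the
  driveway-as-crossing rule is stated for the school access segment only.
* Output lists are sorted by id, making routes deterministic and invariant
  to node/edge insertion order.

```{r}
select_route(generate_grid_network(3, 3))
```

## The synthetic-data generator

The generator exists so that scoring, reliability, and the full pipeline
are testable end to end without field data; it emulates the *design* of a
paired-rater audit study, not any particular city's streets. Defaults
mirror the study conditions the instrument was developed under: 36 schools,
two independent rater pairs, and a 3×3 grid network whose route has one
access segment, two crossings and six other segments (the field medians
were 1, 7 and 9; the grid keeps enumeration by hand possible).

Per school and subscale, a latent propensity $p_s =
\operatorname{logit}^{-1}(\eta_s)$, $\eta_s \sim N(0, \sigma_b^2)$ with
$\sigma_b = 1.5$ by default, drives the item truths shared by both rater
pairs; each pair then observes the truths with independent error: binary
items flip symmetrically, ordinal items are re-sampled uniformly, lane
counts are perturbed by ±1. The error rate is solved by root-finding from a
closed-form variance decomposition so the population ICC of the subscale
sum equals the requested target. The calibration is exact for binary-item
subscales; for ordinal and count subscales the variance bookkeeping ignores
boundary clipping and score recodes, so achieved reliability can sit a few
hundredths above target. Count-item disagreement bounded at one lane also
implies a reliability *floor*; targets below it raise an error stating the
attainable range rather than silently missing. The continuous latent model
itself is exposed as `simulate_rating_matrix()` — the reference design for
parameter-recovery and interval-coverage checks.

What passing tests on synthetic data do **not** show: real audits have
spatially correlated items, heterogeneous route sizes, and rater error that
is neither symmetric nor independent across items (shade disagreement, for
instance, varies with season and time of day). Synthetic results validate
the *machinery*, not field reliability of any particular deployment.

## Problem sizes and numerical choices

The test suite and the reproduction script use problem sizes chosen to make
Monte Carlo noise small relative to the tolerances they assert: 1,000
random small matrices for oracle agreement (tolerance $10^{-12}$), 500
replicates at $n = 200$ for mean recovery (±0.03), 1,000 replicates at
$n = 36$ for interval coverage (93–97%), and 1,000 randomized audits for
the scoring identities, which are exact. The engineered revision scenario
uses 36 schools with target ICCs of 0.95 (reliable subscales) and 0.05
(buffer/shade analogues), far enough from the 0.60 threshold that the
4-removal outcome is stable across seeds.

Other numerical conventions: ICC location/scale invariance is exact in
floating point for scaling and holds to ~1e-9 under large translations
(catastrophic cancellation in sums of squares is avoided by centering at
subject means); quadrature for the logit-normal moments uses a 2,001-point
midpoint rule on normal quantiles; all randomness flows from a single
user-supplied seed.

## Known limitations

* The shipped dictionary reconstructs the instrument's *structure* (item
  counts per section and subscale, response domains, valences); full item
  wording lives in the instrument's own data dictionary, and placeholder
  prompts mark items whose wording is not printed. Counts, not wording, are
  what the scoring and reliability machinery depends on.
* Items per section exceed the scored items of that section's subscales
  (e.g. 27 crossing items vs 23 scored); the remainder are carried as
  unscored contextual items so that both published counts hold
  simultaneously.
* One published table labels the overall-negative access-segment node "2
  subscales" while describing three children; the dictionary follows the
  three-child description. Similarly the overall-positive segment node is
  labelled "4 subscales" with three children listed; three are encoded.
* Scores are reported per rater pair; pooling across pairs (e.g. averaging
  for descriptive tables) is left to the caller.
* GIS buffer analytics, spatial matching of units between rater pairs, and
  validity analysis against active-commuting outcomes are out of scope.
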