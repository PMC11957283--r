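---
title: "The Health Index: scoring model, statistics and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Health Index: scoring model, statistics and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandHI)
```

## The scoring model

The Health Index condenses a necropsy and its histopathology into one
number. Eight parameters are each scored on an ordinal 0–3 scale and
multiplied by a weight reflecting how consequential that kind of finding is
for the animal's short-term survival:

| parameter | source | score | weight |
|---|---|---|---|
| body score | external exam | 0 excellent … 3 cachectic | 1 (seabird, marine mammal), 2 (sea turtle) |
| systemic conditions, macroscopy | necropsy | count of affected systems: 0 / 1–3 / 4–6 / >6 | max weight class of affected systems (1–3) |
| cutaneous injuries | necropsy | 0 none … 3 diffuse | 1 |
| organized lesions | necropsy (± histo) | count of affected systems | max weight class (default scheme) |
| systemic conditions, histopathology | histo | count of affected systems | max weight class (1–3) |
| parasitosis with tissue lesions | histo | 0 … 3 severity | 1 |
| lymphoid depletion | histo | 0 … 3 severity | 2 |
| thyroid alterations | histo | 0 … 3 severity | 2 |

Organ systems carry weight classes by their importance for short-term
homeostasis: 1 — reproductive, musculoskeletal, lympho-hematopoietic;
2 — digestive, respiratory, urinary; 3 — nervous, endocrine,
cardiovascular. When several systems are affected, the highest class
applies. The index is

$$\mathrm{HI} = 1 - \frac{\sum_{i=1}^{8} \mathrm{Score}_i \times
\max(\mathrm{Weight}_i)}{\mathrm{HI}_{max}}$$

with $\mathrm{HI}_{max}$ the raw sum of a hypothetical worst-case animal,
so HI ∈ [0, 1] with 1 = healthy.

### Scheme variants and design choices

Two details of the published weight tables admit more than one mechanically
consistent reading, and the package makes both choices explicit:

* **Organized-lesions weight.** The parameter is scored, like the two
  systemic-conditions parameters, from a count of affected systems. With
  its weight fixed at 1 the maxima come to 42 (seabirds, marine mammals)
  and 45 (sea turtles); with a system-dependent weight 1–3 they come to 48
  and 51, the values the index was standardised against. The default
  `scoring_scheme("paper")` therefore treats organized lesions as
  system-weighted; `scoring_scheme("literal")` keeps the fixed weight of 1
  and maxima 42/45. Other single-parameter reconciliations (e.g. raising
  the cutaneous or parasitosis weight to 3) could also produce 48/51, but
  only the organized-lesions reading reuses a rule already present in the
  scheme rather than inventing a new one. Both variants satisfy
  `himax(sea_turtle) − himax(seabird) = 3`, the body-score weight
  difference times the maximal score.
* **Integumentary weight.** Ten organ systems are recognised but only nine
  appear in the weight listing. The integumentary system is assigned class
  1: skin disease already has its own dedicated parameter, so counting it
  at the lowest weight avoids double-penalising cutaneous findings. It
  still counts toward the affected-system tally.
* **"More than 6"** is read as ≥ 7; counts are capped at the ten defined
  systems. The empty system set takes weight 1 by convention — its score is
  0, so the weight never contributes.
* **Missing data.** Any unassessed parameter makes the HI indeterminable
  (`determinable = FALSE`, `hi = NA`) with the missing parameters named.
  A partial sum would only ever lower the raw score, inflating the apparent
  health of incompletely examined animals, which is why no partial HI is
  ever produced.
* **Body-score weight for reptiles** is applied to all sea turtle species
  alike; the package has no species-level weight overrides.
* Carcass condition code is carried on records but never affects scoring;
  restricting analyses to fresh carcasses (code 2) is an I/O-level filter
  (`read_records(filter_fresh = TRUE)`), because decomposed carcasses
  rarely allow all eight parameters to be assessed.

Numerically the HI is exact ⁠— integer arithmetic divided by an integer
maximum — computed in double precision and serialized to four decimals by
`write_hi_results()`. Package tests compare scoring output against an
independently coded brute-force evaluator at absolute tolerance 1e-9.

## Cohort statistics

`cohort_summary()` reports per-group n, mean, sample standard deviation
(n−1 denominator), min, max and the Fisher–Pearson standardized moment
coefficient $g_1 = m_3 / m_2^{3/2}$ with population-form central moments
(denominator n); the sample-adjusted $G_1$ is available via
`skewness_g1(x, sample_adjusted = TRUE)`. Singleton groups report
`sd = 0`; g1 is `NA` where undefined (n < 3 or constant values) rather than
an error, so a table over many species never aborts on a rare one.

HI values are binned into five categories for frequency and contribution
analyses: `<0.20`, `0.20–0.39`, `0.40–0.59`, `0.60–0.79`, `0.80–1.0`.
Since HI is continuous, the printed two-decimal labels are interpreted as
half-open intervals [0, 0.20), [0.20, 0.40), …, with the top bin closed at
1.0, so the bins partition [0, 1] exactly.

Group differences (e.g. HI across subjective "good"/"fair"/"poor"
veterinarian ratings) use the Kruskal–Wallis test — tie-corrected H via
`stats::kruskal.test()`, chi-square p on k−1 df — followed by Dunn's
pairwise z tests on mean pooled mid-ranks with the tie-corrected pooled
variance $N(N+1)/12 - \sum(t^3-t)/(12(N-1))$. No adjustment is applied to
the pairwise p-values by default, matching the common reporting convention
for this design; Bonferroni and Holm adjustments are available via
`adjust =`. The degenerate all-values-identical case returns H = 0, p = 1
instead of failing.

`parameter_contribution()` profiles the mean and standard deviation of each
parameter's weighted value within each HI category. Body-score values are
standardized to [0, 1] by the taxon-specific maximum (3 or 6) before
aggregation, because body score is the only parameter whose scale differs
between taxa.

## The synthetic cohort generator

No raw per-animal dataset ships with the package, so the simulator provides
cohorts with known ground truth. Each animal receives a latent morbidity
$m \in [0,1]$; every observable derives from it:

* $m \sim \mathrm{Beta}(2, 5)$ by default — right-skewed, mean ≈ 0.29,
  emulating a stranding cohort where most animals are in fair-to-good
  condition. A bounded index driven by right-skewed morbidity is left-skewed,
  reproducing the negative g1 seen in real cohorts.
* Ordinal parameters use a cumulative-threshold link: the score is the
  number of thresholds (default 0.15 / 0.45 / 0.75) that $m$ exceeds, then
  with probability `ordinal_noise` (default 0.05) the score shifts one
  category up or down (equally likely, clamped to 0–3), emulating observer
  variation.
* Affected-system sets include each of the ten systems independently with
  probability $\min(1, \mathrm{scale} \cdot m)$ — `system_scale = 1.0` for
  the two systemic parameters, `organized_scale = 0.6` for the rarer old
  resolved lesions — with the weight-3 systems down-weighted by
  `weight3_factor = 0.6`, since catastrophic nervous or cardiovascular
  involvement is less common than digestive or respiratory disease in
  stranded animals.
* Veterinarian ratings threshold $m$ at 0.25 and 0.50 into
  good/fair/poor, then move to an adjacent category with probability
  `vet_noise = 0.1`, emulating raters who systematically lean harsher or
  kinder.

With these defaults a 2 000-animal cohort has mean HI ≈ 0.70, negative
skewness (g1 ≈ −0.45), and Spearman correlation between latent morbidity
and HI around −0.88; the thresholds and scales were chosen once to sit in
that regime and are defaults, not empirical claims. All randomness is
governed by `sim_config()$seed` through a single seeded stream
(`withr::with_seed()`), so a config byte-identically determines its cohort.

What the simulator does **not** emulate: species-specific pathology
profiles, correlations between parameters beyond those induced by the
shared latent $m$, decomposition codes other than "fresh", seasonal or
spatial stranding structure, and real inter-veterinarian rating structure
(each simulated rating is an independent noisy threshold, not a panel of
raters). Passing tests on simulated cohorts therefore demonstrate that the
pipeline recovers a known monotone health signal under realistic noise —
not that any particular field cohort has these distributions.

## Test and verification design

* Scoring is checked against an exhaustive grid over all $4^5$ ordinal
  combinations crossed with cycling small system subsets, and against
  random records, using an independently coded evaluator; taxon maxima are
  confirmed attained by brute force.
* Rank statistics are checked on small tied instances (pooled N ≤ 12)
  against naive rank-sum oracles, and Kruskal–Wallis additionally against
  `stats::kruskal.test()`; skewness against `e1071::skewness(type = 1)`.
* Stochastic properties (morbidity recovery, rating separation, test power
  at n = 300 over 200 replicates) run under fixed seeds at the simulator's
  default cohort sizes: 2 000 animals for distributional checks, 300 per
  replicate for power — sizes at which the checked effects are stable yet
  the whole suite runs in well under a minute.
* The benchmark against the deposited per-animal raw HI table runs only
  when that table has been fetched and placed at
  `inst/extdata/s1_dataset_raw_hi.csv`; it is not redistributable with the
  package, so that check reports a failure rather than silently passing in
  its absence.

## Known limitations

* The HI is a screening summary, not a diagnosis: it deliberately ignores
  cause of death and anthropogenic-interaction evidence.
* Weights are expert-assigned integers; the package implements the two
  documented variants but offers no data-driven reweighting.
* Subjective parameters (body score, severity grades) inherit observer
  bias; large multi-rater cohorts average this out but small ones may not.
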