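---
title: "Monte Carlo bias analysis of loss-to-follow-up misclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo bias analysis of loss-to-follow-up misclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltfbias)
```

## The model

A historical cohort mortality study classifies every subject at study end
as a case (death from the cause of interest), a living non-case, or a
non-case dead of another cause. Subjects lost to follow-up are tabulated
as alive, so any lost subject who actually died of the cause of interest
is misclassified as a living non-case. For an odds ratio comparing the
highest-exposure stratum with the never-exposed reference, the
relationship between the observed and the adjusted estimate is
multiplicative:

$$\mathrm{OR}_{\text{adjusted}} = \frac{\mathrm{OR}_{\text{observed}}}{\varepsilon},$$

where the error factor $\varepsilon$ is the ratio of the observed to the
adjusted odds ratio. The bias analysis places probability distributions on
the unobservable classification parameters and propagates them by Monte
Carlo sampling; each trial yields one adjusted table, hence one
$\mathrm{OR}_{\text{adjusted}}$ and one $\varepsilon$, and the trial
distributions are the result.

Each trial runs a four-stage chain whose supports are nested — every
stage's maximum is the previous stage's drawn value:

1. $AD$, the all-cause deaths among the $n_{\text{lost}}$ losses, from a
   negative binomial (number of failures before the `size`-th success)
   truncated to $[0, n_{\text{lost}}]$ and renormalized;
2. $ID \sim$ integer BetaPERT$(0,\; p \cdot AD,\; AD)$, with $p$ an
   external cause-specific death proportion;
3. $ID_{\text{never}} \sim$ integer BetaPERT$(0,\; f \cdot ID,\; ID)$,
   the allocation to the reference stratum, with $f$ the differential
   fraction;
4. $ID_{\text{high}} \sim$ integer BetaPERT$(0,\; \min(\tfrac12
   ID_{\text{ever}}, c),\; \min(ID_{\text{ever}}, c))$, where
   $ID_{\text{ever}} = ID - ID_{\text{never}}$ and $c$ is the cap.

The $ID_{\text{high}}$ subjects move from living non-case to case in the
highest stratum, the $ID_{\text{never}}$ subjects likewise in the
reference stratum; row totals are conserved. The middle stratum absorbs
the residual $ID_{\text{middle}}$ for bookkeeping but never enters the
odds ratio.

## Assumptions

* Losses could have died at any rate between "none died" and "all died";
  the location of the all-cause distribution's peak encodes the analyst's
  best estimate (here, observed cohort death proportions).
* The cause-specific proportion $p$ is constant over the study period
  (external vital-statistics data supply 0.204 and 0.139 for the bundled
  scenarios — the highest and lowest gender/ethnicity-specific values).
* Misclassification can be differential by exposure: under
  "Differential A" the never-exposed are more likely misclassified
  ($f = 3/4$), under "Differential B" less likely ($f = 1/4$); the two
  fractions are complementary by construction.
* Only subjects classified as *living* non-cases can have been
  misclassified, so the highest-stratum allocation is capped at that
  stratum's living non-case count (112 in the bundled cohort; the
  reference stratum needs no cap there because $n_{\text{lost}} = 338 <
  414$ living reference non-cases, but the engine enforces the analogous
  bound defensively for other data).

## Parameters that matter

| Parameter | Meaning | Bundled default |
|---|---|---|
| `allcause` (prob, size) | truncated negative binomial for $AD$ | (0.02, 3) peaked near 104, or (0.027, 2) near 37 |
| `cause_proportion` | share of all-cause deaths due to the cause | 0.204 / 0.139 |
| `never_fraction` | likeliest reference-stratum share of $ID$ | 3/4 (A) or 1/4 (B) |
| `high_fraction` | likeliest highest-stratum share of $ID_{\text{ever}}$ | 1/2 |
| `high_cap` | living non-cases of the highest stratum | 112 |
| `n_trials` | Monte Carlo trials per scenario | 50,000 |
| `lambda` | PERT shape weight | 4 (classic PERT) |

All counts are dimensionless subjects; proportions and fractions are
probabilities in (0, 1).

## Numerical choices

* **Negative binomial convention.** "Failures before the `size`-th
  success", whose support starts at 0 — required so the stated lower
  truncation bound of 0 is reachable. Truncation *conditions and
  renormalizes* (inverse-CDF on the truncated support); clamping would
  pile spurious mass on the upper bound.
* **Mode-based fitting.** `fit_negbin_from_mode()` exists because
  elicited inputs arrive as (minimum, likeliest, maximum) while the law is
  parameterized by (probability, shape). It searches shape over a small
  integer grid and probability over a fine grid for the spec whose
  truncated mode is closest to the likeliest value, breaking ties toward
  smaller shape, then toward the probability whose continuous parent mode
  is closest, then toward the larger (more concentrated) probability. The
  bundled scenarios use their published (probability, shape) pairs
  directly; the fitter is a convenience for new studies.
* **Integer conversion.** PERT draws are truncated toward zero
  (`trunc()`), never rounded — matching how the original spreadsheet
  implementation discretized, with a reportedly negligible effect — and
  the same convention is applied to elicited real-valued inputs.
* **Continuous modes.** Mode expressions like $p \cdot AD$ are passed to
  the PERT un-truncated; only drawn values are discretized. When
  $\tfrac12 ID_{\text{ever}}$ would exceed the cap the mode is lowered to
  the cap (preserving mode $\le$ max); the alternative — capping only the
  maximum — is not well defined for a PERT.
* **Zero-propagation.** A zero at any stage zeroes the downstream stages
  of that trial. This is a first-class model rule, not an implementation
  workaround, and such trials are retained: dropping them would bias the
  summaries toward larger misclassification.
* **Quantiles.** Certainty intervals are empirical central quantile
  intervals with linear interpolation between order statistics
  (`quantile()` type 7). The convention is pinned for reproducibility;
  with 50,000 trials any standard convention differs negligibly. The
  intervals are summaries of the simulation distribution, not confidence
  intervals, and no Bayesian posterior computation is attempted.
* **Randomness.** One seeded stream per simulation; the chain is drawn
  stage by stage across all trials, with conditional stages consuming
  randomness only for trials still live. Identical (scenario, table,
  seed) triples replay exactly. Batch runs derive scenario $i$'s seed as
  `seed + i`.
* **Degenerate inputs.** Zero cells make the crude odds ratio undefined
  and raise a classed error; fractional counts are rejected, not rounded;
  adjusted tables with a zero cell (impossible for the bundled cohort,
  whose post-cap minimum cell is 36) are flagged with `NA`, warned about,
  and excluded from summaries rather than silently dropped.

## The synthetic-data generator

`generate_synthetic_table()` draws random valid cohort tables — positive
cells of occupational-cohort magnitude (tens of cases, hundreds of
non-cases per stratum) and a loss-to-follow-up total of 15–25% of the
cohort, the range typical of historical occupational studies. It emulates
only the *table structure* the method consumes: counts are independent
across strata, so it encodes no exposure–response gradient, no
correlation between stratum size and mortality, and no real vital-status
process. Property tests on synthetic tables therefore demonstrate that
the chain's invariants (nesting, conservation, caps, zero-propagation)
hold on arbitrary valid inputs — not that the method recovers truth on
real data, which depends entirely on how well the elicited distributions
describe the actual losses.

## Design choices in open territory

* The highest-exposure stratum defaults to the *last* stratum of the
  ordered table (the reference stratum is explicit); every user-facing
  function takes an `exposed_label` override.
* `high_cap` generalizes the bundled cohort's hard-coded 112 to "living
  non-cases of the target stratum" and is validated against the bound
  table.
* Scenario configuration is YAML: one named block per scenario mirroring
  the result-table columns, round-trip tested, with malformed blocks
  rejected by block name and field.
* The across-scenario acceptance checks run the full published problem
  size (eight scenarios at 50,000 trials); distribution-level checks use
  up to $6 \times 10^6$ draws, at which sampling noise sits well inside
  the stated total-variation bound.

## Known limitations

* The residual-split allocation (reference share, then half of the
  remainder to the top stratum) is specific to a three-level exposure; the
  package requires at least three strata and does not model
  arbitrary-depth allocation.
* Only the loss-to-follow-up misclassification error is modelled; other
  error sources (exposure misclassification, confounding) would enter the
  same framework as additional factors but are out of scope, as are
  person-time estimators and inverse-probability weighting.
* A time-varying cause-specific proportion is not modelled; if the true
  proportion declined over the study period, a constant recent value
  understates both the misclassified count and the uncertainty.

## Problem sizes used in the test suite

Unit and property tests run the chain at $10^3$–$2\times 10^4$ trials per
scenario and the invariant sweep at 125,000 trials per bundled scenario;
the end-to-end reproduction runs all eight scenarios at the full 50,000
trials. These sizes make the whole suite complete in well under a minute
while keeping Monte Carlo error far below every stated tolerance.
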