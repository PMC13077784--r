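---
title: "Modelling differential access to preferred and high-quality skilled nursing facilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling differential access to preferred and high-quality skilled nursing facilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snfchoice)
```

## The scientific problem

When a hospital discharges a Medicare patient to post-acute care, the
skilled nursing facility (SNF) the patient enters is shaped by the
hospital's referral relationships: a small set of "preferred" SNFs absorbs
most of each hospital's discharges. If patients with opioid use disorder
(OUD) are routed away from preferred or high-quality (4-5 star) SNFs, the
referral network itself becomes a mechanism of differential access.
`snfchoice` implements the full analytic pipeline for studying this
question — choice-set construction, preferred-network classification,
matching and propensity-score weighting, hospital fixed-effect linear
probability models, a McFadden conditional logit with OUD-by-attribute
interactions, and counterfactual closest-SNF marginal effects — together
with a synthetic discharge generator with known ground truth, so that every
stage is testable without access to restricted claims data.

## The choice model

Each discharge $i$ faces a choice set $C_i$ of SNF alternatives. The
probability of entering SNF $j$ is the conditional-logit softmax

$$P_{ij} = \frac{\exp(v_{ij})}{\sum_{k \in C_i} \exp(v_{ik})},
\qquad
v_{ij} = x_{ij}'\beta + d_i \,(x_{ij}'\delta),$$

where $x_{ij}$ collects the ten SNF attributes (preferred status, star
rating, distance to home, distance to hospital, for-profit ownership, chain
membership, hospital affiliation, beds, occupancy, percent Medicaid
residents) and $d_i$ is the OUD flag. Because $d_i$ is constant within a
choice set, its main effect cancels from every within-set contrast and is
unidentified; OUD enters only through the interactions $\delta$, whose
preferred and star components are the coefficients of interest. The
likelihood, analytic gradient, and observed information are implemented
directly (`loglik_and_gradient()`, `fit_clogit()`); estimation is Newton
with step-halving line search and a BFGS fallback for non-positive-definite
information, converging when the score max-norm falls below `1e-8` (on the
internally standardized scale). The per-set log-sum-exp is max-stabilized,
so linear indices up to about $\pm 700$ are safe.

Continuous attributes are standardized internally for optimizer
conditioning and estimates are reported on the original scale. Star rating
enters linearly (one coefficient per star), matching the "+1 star"
marginal-effect framing; a categorical entry would change the margin's
meaning. Standard errors are a cluster-robust sandwich with scores summed
within state clusters and a $G/(G-1)$ small-sample factor; with one cluster
per choice set this reduces to the heteroskedasticity-robust form, an
identity the test suite checks numerically.

## Choice sets and preferred networks

Choice sets are frozen at the hospital-year level: the union of (a) every
same-state SNF that received at least one discharge from the hospital that
year, (b) every SNF within 22 km of the hospital, and (c) the 15 SNFs
nearest the hospital. The radius and nearest-k rules keep sets sensible in
both dense and sparse markets, and category (a) guarantees each chosen SNF
belongs to its own set. Distances are haversine great circles on a sphere
of radius 6371.0088 km; at sub-25-km scales the discrepancy from an
ellipsoidal geodesic (below 0.3%) cannot flip any rule threshold, and the
closed form is testable exactly.

A hospital-year's preferred SNFs are the top of its descending prior-year
volume ranking, accumulated until the cumulative share first reaches the
threshold (default 50%, with a 10%-80% sensitivity grid). The crossing is
inclusive — the facility that attains the share is preferred — because
"receiving a cumulative 50%" reads as attaining it; volume ties break by
ascending facility id for determinism. Prior-year volumes are counted on
the full discharge flow, before cohort exclusions, on the view that
referral relationships reflect total patient flow. Hospitals with no
prior-year volume get an empty preferred set (with a logged warning) rather
than exclusion, keeping their markets analyzable.

Cohort filters retain adults admitted to a SNF within one day of discharge,
with no SNF stay in the prior year, a same-state chosen SNF, and complete
geocoding, applied in that order so the exclusion log is well defined.

## Matching, weighting, and subclassification

Because patient-level covariates are unidentified in the conditional
logit, confounding is handled upstream: each OUD discharge is greedily
matched without replacement to up to $k \in \{1,2,3\}$ non-OUD discharges
from the same hospital within $\pm 2$ days, nearest dates first with seeded
random tie-breaks. Greedy matching inside exact hospital strata is
essentially as good as optimal matching here and stays deterministic under
the seed.

The propensity model is a logistic regression of OUD on a two-piece linear
age spline, sex, race/ethnicity, dual eligibility, Medicare Advantage,
ESRD eligibility, RUCA category, and the Elixhauser index. The spline knot
defaults to 65 years — the Medicare eligibility boundary — and is
configurable. Weights are ATE-style ($1/e$ for OUD, $1/(1-e)$ otherwise):
weighted balance tables show both groups pulled toward a common blend,
which ATT weighting (which leaves the treated group unmoved) would not
produce. Scores outside $[0.01, 0.99]$ are trimmed before weighting —
trimming clearly occurred in the motivating analysis but the rule is not
recorded, so a conventional symmetric default is used — and weights are
normalized to mean 1 within each group. Quintile subclassification cuts
the pooled trimmed score distribution into fifths; the within-quintile
choice models are unweighted, since subclassification is the alternative
to weighting.

## Linear probability models

The three binary outcomes — preferred-SNF entry, high-quality (4-5 star)
entry, and high-quality entry among preferred-SNF discharges — are fit by
OLS with hospital fixed effects absorbed by group demeaning. Singleton
hospitals are dropped and counted; degrees of freedom are corrected for
the absorbed effects; and standard errors are heteroskedasticity-robust
(HC1), since LPM residuals are heteroskedastic by construction and the
variance estimator of the motivating tables is unstated. Discharges whose
chosen SNF lacks a star rating are excluded listwise from the quality
models only, preserving the preferred-outcome sample.

## Counterfactual closest-SNF margins

Marginal effects in a conditional logit differ alternative by alternative,
so they are evaluated at each patient's closest SNF (minimum home
distance, facility-id tie-break): the closest SNF's preferred status is
set to 1 versus 0, or its star rating raised by one, all other attributes
of all alternatives held fixed, and the change in its predicted
probability recorded and averaged within OUD groups, in percentage points.
The computation is a deterministic re-evaluation of the fitted softmax —
no simulation error — and equals the closed-form probability difference
exactly, which the tests assert to `1e-12`. Under the linear star entry a
5-star closest SNF admits no +1 manipulation, so such discharges are
excluded from the star margin and counted, avoiding dilution of the
estimand with structural zeros. Group differences are tested through the
Wald statistic of the corresponding interaction coefficient under the
cluster-robust covariance, not through the simulated margins themselves.
When the fit is weighted, group averages use the same weights, keeping the
estimand aligned with the weighted model.

The independence-of-irrelevant-alternatives (IIA) assumption is probed by
thinning: removing 5%-20% of non-chosen alternatives per set (never the
chosen one, always retaining at least one competitor), refitting, and
expressing coefficient shifts in full-model standard-error units. Under
data generated from the model itself, drift stays within sampling error.

## The synthetic-data generator

`generate_population()` emulates the structure of the restricted inputs:
states as rectangular tiles, hospitals uniform within tiles, SNFs anchored
to hospitals with exponentially decaying radial offsets (mean 8 km), so
both the 22 km and 15-nearest rules bind in some markets; patient homes
scatter around the discharging hospital (zip-centroid geometry adds
nothing testable). OUD status is drawn from a logistic model whose
intercept is calibrated by root-finding so the realized prevalence targets
the configured value — 1.2% by default, the share observed among national
SNF-bound Medicare discharges. Default propensity coefficients make OUD
patients younger and more often dual-eligible, the direction seen in the
motivating cohort (mean age roughly a decade lower; dual eligibility
almost twice as common); prevalence conditional on covariates is not
reported anywhere, so these are directional choices, fixed once.

Chosen SNFs are drawn from the conditional-logit probabilities implied by
configurable true coefficients. Default main effects favour preferred
status (+1.4), quality (+0.25 per star) and proximity (−0.12 per km of
home distance); default interactions carry the differential-access signal
(OUD-by-preferred −0.25, OUD-by-star −0.20, all others zero). The first
configured year is a burn-in generated with an empty preferred network;
each later year's preferred flags come from the previous year's realized
referral volumes, so networks are self-reinforcing as real ones are. Star
ratings are categorical 1-5 with a 3% missingness rate; missing stars are
imputed at the midpoint 3 in both the generating utility and the
estimation table (the count is logged), while outcome construction uses
the raw rating and drops missing-rating rows from quality models.
Elixhauser indices are truncated-Poisson integers; no ICD coding is
simulated. Admission lags of 2+ days, prior-year SNF stays and other
filter violations can be injected deterministically for filter tests.

What the generator does *not* emulate: real U.S. geography, facility
entry/exit within years, serial correlation in a patient's repeat
hospitalizations, unmeasured confounding, or misclassified OUD flags.
Passing tests therefore demonstrate that the estimators recover the truth
when the model is correctly specified and choice sets are known — not that
the substantive estimates from any real claims data are unbiased.

## Problem sizes and numerical choices

The test suite exercises parameter recovery at 5,000 choice sets of 10
alternatives, confidence-interval coverage over 200 replicates of 1,000
sets, Wald-test calibration over 400 null replicates (with 40 state
clusters, enough for the cluster-robust variance to be well behaved), and
an LPM recovery at 100,000 discharges; the acceptance script runs the full
pipeline on a 100,000-discharge cohort at the default 1.2% prevalence,
large enough that the rare-exposure matched subsample supports stable
choice-model estimates. Convergence tolerances (score max-norm `1e-8`,
brute-force agreement `1e-10`, margin identity `1e-12`) are fixed for
reproducibility. Ties — in volume rankings, candidate control dates, and
closest-SNF distances — all break deterministically (ascending id, seeded
uniform, ascending id respectively).

## Known limitations

- Star ratings enter the choice model linearly; a categorical entry is a
  plausible alternative the interface does not currently expose.
- The preferred classification assumes a single hospital-year network;
  mid-year network changes are out of scope.
- No delta-method standard errors for the margins themselves: differences
  are tested via interaction terms only.
- Multi-state choice sets, caliper matching on the score, and
  doubly-robust estimators are deliberately not implemented.
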