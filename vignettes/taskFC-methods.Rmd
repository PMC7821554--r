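---
title: "Methods: task-based functional connectivity and age-group inference"
author: "taskFC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-based functional connectivity and age-group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskFC)
```

## The analysis problem

Healthy ageing is associated with changes in the brain's functional network
organisation: weaker correlations among regions of the same network, less
segregated systems, and lower whole-brain modularity. Whether these effects
are visible, and how strongly, depends on what the subject is doing in the
scanner. **taskFC** implements a complete analysis chain for studies of this
question: ROI time series recorded during tasks from four cognitive domains
(vocabulary, perceptual speed, fluid reasoning, episodic memory) are turned
into per-domain correlation matrices, summarised by a hierarchy of
connectivity metrics, and compared across four age groups (YA 20--34,
yMA 35--49, oMA 50--64, OA 65--80 years) with repeated-measures factorial
MANCOVAs and brain--behaviour partial correlations.

Because scanner data for such cohorts are rarely redistributable, the
package ships a synthetic-cohort generator whose statistical structure is
known in closed form; every downstream stage is validated against it.

## Parcellation model

The node set is a Power-style 264-node parcellation in which 214 ROIs are
assigned to ten networks (visual 31, somatomotor mouth 5, somatomotor hand
30, auditory 13, default mode 58, salience 18, cingulo-opercular 14,
frontoparietal 25, dorsal attention 11, ventral attention 9); the remaining
nodes are `unassigned` and dropped from analysis. `powerLikeParcellation()`
builds a synthetic stand-in with these counts: coordinates are laid on a
24 mm grid inside typical MNI ranges, not the published centres, so the
default fixture passes the proximity filter unchanged.

ROIs whose centres lie within 20 mm of one another in standard space are
excluded before analysis (`applyProximityExclusion()`). Two reading choices
were open here:

* *Node removal versus edge masking.* The exclusion is implemented as node
  removal — both members of every offending pair are dropped — which is the
  literal reading of "ROIs ... were excluded". Edge masking (zeroing only
  the short-distance edges) is a recognised alternative in the parcellation
  literature but is not what the rule states.
* *Boundary.* "Within 20 mm" is treated as an open bound: a pair at exactly
  20 mm survives. Real coordinates essentially never sit on the boundary,
  so this only matters for synthetic data.

The filter is evaluated on the currently surviving set, which makes it
idempotent, and survivor order always preserves input order so that time
series, matrices and parcellation stay aligned by construction.

## Synthetic cohort generator

Each ROI signal follows a network factor model

$$x_i(t) = \sqrt{w_k}\, g_k(t) + \sqrt{1 - w_k}\,\sigma\, e_i(t)
          + \beta\, s(t),$$

where $g_k$ is the factor of ROI $i$'s network $k$ (factors drawn with a
network-coupling correlation matrix $\rho$), $e_i$ is unit white noise, and
$s(t)$ is a block task regressor (alternating 30 s off/on boxcar convolved
with a canonical double-gamma haemodynamic response, TR = 2 s). A factor
model was chosen over direct covariance sampling because it guarantees a
positive-semidefinite implied covariance and yields closed-form expected
correlations — `expectedCorrelation()` returns $w_k$ for within-network
pairs and $\sqrt{w_k w_l}\,\rho_{kl}$ for cross-network pairs (at the
unit-variance default $\sigma = 1$) — which the tests use as exact recovery
targets.

Generator defaults reproduce the emulated study's conditions:

* group sizes 72/60/86/84 (302 subjects), age drawn uniformly within each
  group's band;
* domain volume counts 388 (VOCAB), 595 (SPEED), 1290 (FLUID), 517 (MEM),
  with the constituent task runs of each domain concatenated;
* within-network loadings declining linearly from $w = 0.45$ (YA) to
  $0.36$ (OA) in every network. The emulated study reports no effect sizes
  in correlation units, so this planted decline is illustrative — chosen as
  a moderate, detectable effect of about 0.03 per age band — and is
  configuration, not a constant;
* network coupling 0.3 among sensorimotor networks, 0.2 among association
  networks and $-0.15$ between the two systems in the youngest group,
  planting the negative between-system correlations that the
  negative-correlation analysis needs (every group's matrix is verified
  positive semidefinite at construction);
* an age gradient on the coupling (`couplingAgeStep`, default 0.5):
  positive couplings scale up by $1 + 0.5(g-1)$ and negative couplings
  attenuate by $\max(0, 1 - 0.5(g-1))$ across group index $g$. This
  models the aged brain's dedifferentiation — relatively stronger
  between-network integration and loss of anticorrelation. It is needed
  because scaling $w$ alone cannot express that contrast: it rescales
  within- and between-network correlations together, the between/within
  ratio stays fixed, and both segregation and the weighted modularity of
  a proportionally thresholded graph are asymptotically unchanged (at
  2–10 % density the edge budget is below the within-network pair count,
  so the retained graph contains essentially only within-network edges
  under uniform loadings). The step magnitude was calibrated so the
  young-minus-old modularity difference is of the order the emulated
  study reports (about 0.02), consistent with its near-zero older-adult
  segregation;
* task amplitude $\beta = 1/3$, putting roughly 10 % of signal variance in
  the task block structure so the task-regression stage is exercised
  non-trivially;
* per-domain scrubbing fractions from Beta(2, 15) (mean 0.12, with a tail
  above the 0.30 exclusion bound calibrated so that roughly a tenth of
  subjects are excluded over the four domains, matching the emulated
  study's reported attrition);
* behavioural z-scores drawn around group means that mirror the emulated
  demographic table's qualitative pattern (speed scores increasing with
  age group under its reverse coding, memory and fluid scores decreasing);
  behaviour is generated independently of the connectivity signal;
* gender and education generated independently of group.

A single master seed drives everything; per-subject seeds are drawn from a
dedicated pseudo-random stream of the master seed (rather than derived
arithmetically from the subject index, which can leave an index-linked
trend in the streams that a between-group test on index-blocked groups
would detect), so any subject can be regenerated independently.

**What the generator does not emulate:** autocorrelated or physiological
noise, drift, motion beyond a scalar scrub fraction, spatial structure
within networks, and any true coupling between connectivity and behaviour.
Tests passing on this generator therefore demonstrate correctness of the
computational chain and of the statistical calibration under the planted
model — not robustness to real fMRI artefacts.

## Connectivity stage

Per domain, the constituent runs are concatenated, the task design (one
convolved regressor per run, plus an always-included intercept) is
regressed out of each ROI time series by least squares, and Pearson
correlations are computed over the residuals. Residuals are orthogonal to
the design by construction, so the correlation matrix is invariant to
adding any linear combination of design columns to the input — a property
the tests check directly.

The diagonal convention is explicit: `missing` for averaging analyses,
`zero` for graph analyses. Sign splitting (`splitPosNeg()`) keeps $r > 0$
on the positive side and $r < 0$ on the negative side; exact zeros carry no
sign and appear on neither side. Constant ROI columns yield missing
correlations with a warning rather than an error, so a degenerate synthetic
subject cannot abort a cohort run. Subjects are included only if their
scrub fraction is strictly below 0.30 in all four domains.

## Metrics

*Network means* (`networkMean()`): for each network, the mean positive
within-network correlation, mean positive between-network correlation and
mean negative between-network correlation, where "between" pools a
network's pairs with all other analysed networks (not pairwise means of
means). Means are of raw $r$; a network with no qualifying entry yields a
missing value, and subjects missing any positive within- or between-network
mean are flagged out of the positive-correlation analysis subset,
mirroring the emulated study's 302-to-282 reduction mechanism.

*System segregation* (`systemSegregation()`): restricted to one system's
networks (sensorimotor = auditory, visual, somatomotor hand/mouth;
association = DMN, frontoparietal, cingulo-opercular, ventral/dorsal
attention, salience; or the whole brain), negatives are set to zero and

$$SS = \frac{\bar z_{within} - \bar z_{between}}{\bar z_{within}},$$

with $SS$ missing when $\bar z_{within} \le 0$. Two conventions needed
deciding. First, zeroed negatives are *included* in the averages — that is
the canonical set-to-zero definition of the statistic, and the
implementation follows it (the alternative of averaging only the strictly
positive entries would inflate both means). Second, values are Fisher-z
transformed (`atanh`) before averaging, as the "z" in the defining formula
indicates; raw-$r$ averaging is available via `fisherZ = FALSE` for
sensitivity checks.

*Graph metrics*: the zero-diagonal matrix is proportionally thresholded at
edge densities 2 %–10 % (step 1 %), retaining the top
$\lceil d \cdot P \rceil$ positive undirected edges by weight
($P = N(N-1)/2$), with ties broken by (weight, smaller ROI pair) for
determinism — no tie rule is standard, so an explicit deterministic one was
chosen. All negatives are zeroed. Metrics are weighted (edge length
$1/r$), matching the weighted variants of the standard toolbox: global
efficiency is the mean inverse Dijkstra distance with disconnected pairs
contributing zero, and modularity is weighted Newman--Girvan $Q$ at
resolution 1, optimised by Louvain over 20 deterministically seeded
restarts (plus the trivial one-block partition as baseline candidate, so
$Q \ge 0$ always). The reported $Q$ is re-evaluated from the stored
partition by the package's own `modularityQ()`, so it is exactly
reproducible.

## Statistics

Every factorial analysis is a repeated-measures MANCOVA: the long metric
table is reshaped to one response vector per subject across within-subject
cells (domain, network, correlation direction, system or threshold, as the
design requires), and a multivariate linear model is fitted on the age
group (sum-to-zero coding, type III tests — appropriate for these
unbalanced group sizes) plus the scrubbing covariate, defined as the mean
of the four per-domain scrub fractions since no aggregation is prescribed.
Within-subject effects use the multivariate (contrast-matrix) approach —
each within effect is a Kronecker product of orthonormalised Helmert
contrasts — tested by Wilks' $\Lambda$ with Rao's F approximation; Pillai's
trace is available by flag. The implementation is the package's own and is
cross-checked in the tests against an independent general-purpose
multivariate ANOVA routine; between-subject tests collapse exactly to the
univariate ANCOVA F on subject means, a second identity the tests assert.
Complete-case analysis is used for missing cells. Effects whose transformed
response cells are exactly collinear (possible in deliberately reduced
designs, e.g. two networks make the two between-network means identical)
are reported as not testable rather than aborting the run.

Follow-up tests mirror the emulated study's post hocs: one-way ANCOVAs on
slices, covariate-adjusted pairwise group contrasts Bonferroni-corrected
over the contrasts within a domain (default $m = 10$, one per network), and
partial correlations between each metric and the matching domain's
behavioural z-score controlling for education and gender (numeric dummy),
with a second set additionally controlling for age; no correction is
applied to these exploratory correlations.

## Numerical choices and degenerate inputs

* Correlations are symmetrised to machine precision and clipped to
  $[-1, 1]$; Fisher z clamps its argument below 1 to avoid infinities on
  degenerate perfect correlations.
* The MANCOVA refuses singular designs and reports an informative error
  when the error SSCP is singular; a covariate that is constant is dropped,
  which makes the zero-covariate model exactly equal to the covariate-free
  one.
* A thresholded matrix with no positive entries yields an all-zero
  adjacency with a warning; a zero-weight graph yields missing modularity.
* All randomness flows from explicit seeds; rerunning any configuration
  reproduces manifests and metric tables byte-identically.

## Problem sizes used by the test suite

The validation suite chooses simulation sizes that keep the full run in the
range of a few minutes while leaving the statistical conclusions
meaningful; these are the package's own choices of test scale:

* generator-recovery checks: 2 networks x 6 ROIs, series of 1290 volumes,
  20 subjects (tolerance $\pm 0.05$ on mean correlations);
* null calibration of the age test: 200 replicate cohorts at the full
  default group sizes (72/60/86/84) on a reduced 2-network, 120-volume
  design, expecting the rejection rate at $\alpha = .05$ within
  $0.05 \pm 0.03$;
* direction recovery: 20 replicate cohorts of 15 subjects per group on a
  quarter-scale ten-network parcellation (59 ROIs) with 200-volume
  domains, expecting a $p < .001$ age effect on positive within-network
  correlations and lower mean segregation and modularity in OA than YA in
  at least 95 % of replicates;
* graph-metric oracles: Floyd--Warshall on 12-node graphs, exhaustive
  partition enumeration (Bell(8) = 4140 partitions) on 8-node graphs.

The acceptance script (`scripts/acceptance.R`) runs the full pipeline on
the complete 214-ROI parcellation with 15 subjects per group and 200-volume
domains, and reports the quantities it computes at run time.

## Known limitations

* The emulated study's printed F statistics, demographic table and group
  means derive from a non-deposited cohort; they are not reproducible here
  and the package does not attempt to match them numerically — validation
  is by closed forms, independent oracles and calibration properties.
* Whether the original graph metrics were weighted or binary, and whether
  segregation averaged transformed or raw correlations, is not stated in
  the source description; the package defaults to weighted metrics and
  Fisher-z averaging with flags for the alternatives.
* The generator's planted effect sizes are illustrative, anchored only to
  the emulated study's qualitative directions and its reported modularity
  difference magnitude.
* With the coupling age gradient, absolute between-network positive
  correlations *rise* with age in the generator, whereas the emulated
  study observed them to weaken; a single-factor-per-network model cannot
  produce simultaneously falling absolute between-network correlations and
  falling segregation/modularity. Analyses of the between-network positive
  direction on default synthetic cohorts therefore show the opposite sign
  to the study.
* For the same reason, weighted global efficiency tends to *increase*
  with age on default synthetic cohorts (the added between-network edges
  act as shortcuts), whereas the study observed a small age-related
  decline confined to fluid-reasoning tasks. The generator plants no
  global-efficiency contrast of its own.
* Only global graph metrics are implemented (no nodal degree, clustering
  or participation coefficients), and negative-weight graph variants are
  out of scope.
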