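---
title: "Symptom networks from ordinal ratings: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom networks from ordinal ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symnet)
```

symnet models a set of ordinal symptom ratings — canonically the 17 DSM-IV
PTSD symptoms rated 0–3 — as a network in two complementary ways: an
undirected Gaussian graphical model (GGM) of regularized partial
correlations, and a directed acyclic graph (DAG) learned as a Bayesian
network. This vignette is the package's own account of both models: what
they assume, which knobs matter, what the synthetic-data generator does and
does not emulate, and where the methods' known weak spots are.

## The data model

Input is a participants × symptoms matrix of ordinal codes with possible
missing cells (`SymptomDataset`). Two source instruments are supported: an
interview scale already on 0–3 (`PSS_0_3`) and a questionnaire scale on 1–5
(`PCL_1_5`). `rescalePclc()` harmonizes the latter by the fixed map
1→0, 2→1, 3→2, {4,5}→3: the two most extreme questionnaire points collapse
onto the single most extreme interview point, leaving both instruments on a
common 4-level scale. The map is many-to-one at the top, so it is not
invertible, and — read as 0–3 codes — re-applying it would shift the value
3; harmonization is applied exactly once, at ingestion.

Missing cells are empty CSV fields or `NA`, never a numeric sentinel, so
missingness can never collide with a valid code. The undirected branch uses
pairwise-complete observations by default (each correlation uses every
participant who answered both items); the directed branch always drops
incomplete rows (`listwiseComplete()`), because the node-wise regressions
of the BIC score need complete records. With 179 participants of whom 14
have a missing item, the DAG branch therefore runs on 165.

Both branches treat the 0–3 codes as manifestations of underlying *metric*
phenomena (a symptom's frequency or intensity), which is what justifies a
Gaussian model on ordinal input: the GGM via the latent-normal polychoric
model, the DAG via linear-Gaussian regressions on the codes themselves.

## Polychoric correlations

For each pair of items the two-step profile estimator is used: thresholds
first (cut-point *k* of an item is Φ⁻¹ of the cumulative proportion through
category *k*, computed from the pair's own margins), then a 1-D likelihood
maximization over the latent correlation ρ, where the likelihood is
Σ nᵢⱼ log πᵢⱼ(ρ) and πᵢⱼ is the bivariate-normal rectangle probability
between consecutive cut-points. Full joint ML would re-estimate thresholds
per pair jointly with ρ; at 4 levels and a few hundred observations the
two-step estimator is standard, much faster, and equally accurate for
practical purposes.

Numerical choices worth knowing:

* Rectangle probabilities come from a fixed 48-point Gauss–Legendre
  quadrature of the correlation-derivative identity (accuracy ~1e-8 over
  |ρ| ≤ 0.999, verified against adaptive integration in the tests).
* The maximizer is a coarse 41-point scan plus golden-section refinement to
  1e-7 — the profile likelihood is unimodal in practice, and the scan
  protects the bracket.
* Estimates are clipped to the interior |ρ| ≤ 0.999 so perfectly concordant
  tables (e.g. duplicated items) cannot produce a singular matrix.
* Zero-probability cells are floored at 1e-12 inside the log-likelihood;
  with valid thresholds such cells carry zero observed count, so the floor
  never moves the maximizer.
* The pairwise-assembled matrix need not be positive semi-definite. If its
  smallest eigenvalue is negative it is projected to the nearest
  correlation matrix (Higham's alternating projections, via
  `Matrix::nearPD`, tolerance 1e-8) and the projection is recorded in the
  returned object. A variable whose observed margin has a single category
  has no finite thresholds and is reported by name as degenerate.

## The regularized partial-correlation network

`ebicGlasso()` maximizes log det Θ − tr(SΘ) − λΣᵢ≠ⱼ|Θᵢⱼ| by blockwise
coordinate descent (each column update is a lasso regression on the current
covariance estimate). The diagonal is not penalized, which gives the clean
boundary behaviour used by the tests: any λ at or above the largest
absolute input correlation produces the empty network, and λ = 0 reproduces
S⁻¹. The penalty path is 100 log-spaced values from that λ_max down to
0.01·λ_max — the established convention for EBIC-tuned graphical lasso;
the path is recorded in the output so runs are self-describing. The EBIC,
−2ℓ + E log n + 4Eγ log p with ℓ evaluated at the penalized estimate (no
post-selection refit), selects the model; γ defaults to 0.5, the
specificity-favouring end of the usual 0–0.5 range, and ties go to the
sparser model. Entries below 1e-10 in absolute value are treated as
structural zeros when counting E, a guard against coordinate-descent dust.

Two properties of this selector deserve honesty:

* **Edge counts along the path are not perfectly monotone.** The exact
  lasso path occasionally lets an edge leave and re-enter between adjacent
  penalties; the test suite asserts near-monotonicity (unit-sized transient
  dips) rather than the idealized strict version.
* **The no-refit EBIC keeps weak spurious edges at large n.** In recovery
  experiments (17 nodes, true partial correlations ≥ 0.3, n = 5000) recall
  of true edges is 1.0, but the selected model also carries a tail of tiny
  false edges (|w| mostly < 0.03): the likelihood keeps improving as the
  true edges unshrink, which drags the EBIC optimum toward smaller λ. This
  is characteristic of EBIC selection at the penalized estimate, not a
  solver defect — the fitted precision matrices agree with an independent
  graphical-lasso implementation to the convergence tolerance. Remedies
  such as stepwise refitting or weight thresholding change the estimator
  and are deliberately out of scope; users ranking edges should weight by
  magnitude, not mere presence.

## Centrality and stability

Strength is Σⱼ|wᵢⱼ|; shortest-path metrics use edge length 1/|w|, so all
three indices ignore edge signs. Closeness is 1/Σⱼ d(i, j); betweenness
counts shortest-path membership with credit split equally over tied
geodesics. In a disconnected network a node with any unreachable partner
gets closeness 0 and the result is flagged — a rule the package must state
because sparse selected networks are routinely disconnected even when the
underlying truth is not. z-scored columns standardize each metric across
nodes; a metric that is constant across nodes (e.g. betweenness in an
empty network) yields `NA` rather than a fabricated zero.

Stability analysis follows the bootstrap conventions of the psychometric
network literature: percentile 95% intervals for edge weights from full
re-estimation (polychoric → EBIC-glasso) on row resamples; a node-pair
centrality difference test that flags a pair when the bootstrap interval of
the difference excludes zero, with no multiplicity correction (matching the
source convention — interpret counts, not individual pairs); and the
case-dropping CS-coefficient: for each drop proportion in
{.10, .25, .40, .55, .70, .75}, subsamples are drawn without replacement,
the network is re-estimated, subsample centralities are correlated with the
full-sample ones across nodes, and the CS value is the largest drop
proportion at which ≥ 95% of correlations are ≥ .70. Values ≥ .50 indicate
stable centralities; below .25 they should not be interpreted. The
subsample count per drop proportion (250 by default, smaller in the test
profiles) and the grid are recorded in the output; study-scale runs
(B = 10,000 for edge intervals) are a configuration away, with desk-scale
defaults chosen so the full pipeline and test suite complete in minutes on
one CPU.

The restricted-variance diagnostics correlate per-item SD (and skewness)
with strength centrality, two-tailed Pearson with t-based p on p − 2
degrees of freedom: a strong SD–strength correlation would warn that
apparent centrality merely tracks differential item variability.

## The Bayesian-network branch

The score is the linear-Gaussian BIC in its node-wise decomposition:
Σᵢ [ℓᵢ(parents) − (kᵢ/2) log n], kᵢ = |parents| + 2 (intercept and residual
variance), higher is better. Family scores are computed from the MLE
covariance matrix and memoized per (node, parent set), so the bootstrap
loop re-scores only what a move changes. The search is greedy best-move
hill climbing over single-edge additions, deletions and reversals that
preserve acyclicity, starting from the empty graph, with moves enumerated
in fixed lexicographic order and strict-improvement acceptance — fully
deterministic given a seed. Each restart perturbs the incumbent optimum by
a few random valid moves (defaults: 10 restarts × 5 perturbations, the
counts being ours since only the mechanism is prescribed by the method)
and re-climbs.

Model averaging runs the search on B row resamples. Per unordered pair,
*strength* is the fraction of bootstrap networks containing the edge in
either direction; the retention cut-point is data-driven: the noise
proportion t* minimizes the L1 distance between the empirical strength CDF
and the ideal two-point CDF with mass t at 0 and 1 − t at 1 (computed
exactly as the Lebesgue-weighted median of the empirical CDF), and the
cut-point is the t*-quantile of the strengths, edges strictly above it
retained. The degenerate boundary t* = 0 means "no noise edges", so the
cut-point is 0 and every observed pair survives — without this reading the
all-ones fixture would paradoxically retain nothing. Retained edges are
oriented by the majority direction *among the bootstrap networks that
contain them* (the standard model-averaging convention; the alternative —
majority among all B — is noted as an open reading). An exact 50/50 split
is broken toward the lexicographically smaller source label and flagged.
If majority orientation ever produces a cycle, the cycle edge with the
lowest direction probability is re-oriented (its recorded probability
floored at the uninformative 0.5), or dropped on a second offence, each
repair logged as a warning. Finally each retained edge is annotated with
its BIC importance — the score loss if that single edge were removed —
which is the "thickness" of the fit-oriented rendering; the
direction-probability rendering uses the orientation fractions instead.

Because a two-node linear-Gaussian model is Markov-equivalent in both
orientations, direction probabilities for such edges hover near 0.5 — the
bootstrap cannot orient what the likelihood cannot distinguish. Colliders
(X → Z ← Y) break the equivalence and are oriented correctly at moderate n;
the tests assert both behaviours.

## The synthetic-data generator

`randomGGM()` draws a sparse unit-diagonal precision matrix whose
off-diagonal entries are (minus) the target partial correlations, so the
ground-truth partials are exactly the sampled weights; positive
definiteness is ensured by bounded redraws rather than diagonal inflation,
which would dilute the partials. `randomDAG()` samples edges in the upper
triangle of a random node permutation (acyclic by construction) with
linear-Gaussian coefficients. `sampleOrdinal()` draws the implied latent
multivariate normal (analytically standardized for the DAG case) and
discretizes each variable by its thresholds. Defaults emulate the shape of
the motivating study: `csaPtsdPreset()` gives 17 items on 4 levels, 179
participants, 14 rows with one missing cell each (so listwise completion
leaves 165), predominantly positive sparse structure (85% positive edge
signs — symptom networks are overwhelmingly positive in practice), and a
half-and-half mix of symmetric and right-skewed marginals, the skewed
thresholds (cumulative .55/.80/.92) mimicking infrequently endorsed
symptoms. One RNG stream per operation, seeded explicitly and restored on
exit, so no call perturbs another's randomness — a direct answer to the
reproducibility worries that motivate bootstrap averaging in the first
place.

What the generator does *not* emulate: real item-level measurement error
structure, instrument effects between the two source scales (the optional
source indicator is carried but never used in estimation), sample
heterogeneity (mixtures), or missingness that depends on symptom severity
(injection is uniformly random, i.e. MCAR). Passing recovery tests on this
generator therefore shows the estimators work under their own assumptions,
not that any specific empirical dataset satisfies those assumptions.

## Problem sizes in the shipped tests

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own test profile: bootstrap sizes of 40–500
replicates, CS subsampling at 40–50 draws per drop proportion, recovery
runs at n between 300 and 20,000 with 2–17 nodes. Study-scale settings
(B = 10,000) are plain configuration changes and alter no code path.

## Known limitations

* The GGM branch inherits the EBIC-at-penalized-estimate behaviour
  described above: excellent recall, conservative only about *strong*
  edges, permissive about trace edges as n grows.
* The DAG branch forbids cycles by construction; feedback loops — plausible
  in symptom dynamics — can only show up indirectly, as low direction
  probabilities on edges whose orientation flips across resamples.
* Linear-Gaussian scoring treats 4-level codes as metric. With strongly
  skewed items this coarsens the likelihood; the discrete multinomial BIC
  is a known alternative and is intentionally not implemented.
* Hill climbing with restarts is a heuristic: on three nodes it attains the
  exhaustive optimum in ≥ 95% of seeded runs (tested), but no global
  guarantee exists at 17 nodes; bootstrap averaging is the mitigation.
* All inference is cross-sectional and between-person; nothing here
  licenses within-person dynamic conclusions.
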