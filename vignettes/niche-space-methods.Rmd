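---
title: "Modelling multidimensional niche spaces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multidimensional niche spaces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichescape)
```

`nichescape` quantifies species' niches as locations in a multidimensional
trait space and asks two kinds of questions about them: *where* species sit
relative to one another (uniqueness, specialisation — proxies for
interspecific competition), and *how* their locations evolved (phylogenetic
signal, evolutionary mode, and which niche elements predict the competition
proxies). This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
establish.

## From raw traits to niche elements

The raw analytical substrate is a species-by-trait table with 16 variables:
six life-history durations in days (maximum longevity, female maturity,
gestation length, interbirth interval, weaning age, generation length),
adult body mass in grams, foraging stratum (ground / scansorial /
arboreal), activity cycle (nocturnal / diurnal / cathemeral), diet breadth
(count of major diet categories), trophic guild (six levels from folivore
to insectivore), habitat breadth (count of suitable habitat types), and the
mean and range of both temperature (°C) and precipitation (mm) across the
species' geographic range. Species with any missing cell are removed
(listwise deletion, `drop_incomplete()`); no imputation is attempted, since
imputed trait values would leak phylogenetic structure into analyses whose
purpose is to measure that structure.

The six durations are mutually correlated along the slow–fast life-history
continuum (a correlation screen, `correlation_screen()`, makes this
visible; the conventional cut for "highly correlated" is |r| > 0.6).
Leaving them in the table would let one latent axis dominate the factor
analysis, so they are collapsed to the first principal component of the
z-scored block (`life_history_score()`), oriented so that maximum longevity
loads positively — high scores mean slow life histories. That leaves 11
niche elements: 8 continuous and 3 categorical.

Breadth counts are treated as continuous. An `elevation_range` column is
tolerated in input files but excluded from the analysis set: the 11-element
design is fully specified by the variables above, and range-derived
elevation spread duplicates information already carried by the climate
ranges.

## Factor analysis of mixed data

`famd_fit()` implements the standard weighted-indicator construction.
Quantitative columns are centred and scaled to unit *population* variance.
Each categorical level becomes an indicator column divided by the square
root of its relative frequency and then centred; this weighting makes a
categorical variable with \(K\) observed levels contribute \(K - 1\) units
of inertia, so with the study schema the total inertia is
\(8 + 2 + 2 + 5 = 17\) — an identity the tests assert exactly. The
decomposition is the SVD of the expanded matrix divided by \(\sqrt{n}\);
species coordinates are *principal* coordinates, whose per-component
population variance equals the component eigenvalue. Downstream distances
use these coordinates, so axes are weighted by the variance they explain.

Numerical conventions:

* **Component signs** are indeterminate in any SVD; each component is
  oriented so its largest-magnitude column loading is positive, making
  output bit-stable across runs.
* **Kaiser retention** (`retain_kaiser()`) keeps eigenvalues strictly
  greater than 1 — no tolerance band. An eigenvalue of exactly 1 (e.g. a
  single standardised variable) is not retained, and a model with no
  eigenvalue above 1 is an error rather than a silently empty space.
* **Rare levels**: unobserved levels are dropped with a warning; singleton
  levels are kept (their indicator weight is large) with a warning, since
  dropping a species' only level would silently change the species set.
* **Contributions** (`variable_contributions()`) are squared loadings in
  percent, with the levels of a categorical variable summed into their
  parent element; per-dimension contributions over the 11 elements sum
  to 100. The default reporting threshold of 9% marks the elements treated
  as defining a dimension.

No rotation is applied: the Kaiser-retained principal axes are the niche
space, and rotating them would detach the axis variances from the
eigenvalues that justified retaining them.

## Uniqueness and specialisation

Both metrics live in the retained space. *Uniqueness*
(`uniqueness_scores()`) is the mean Euclidean distance to the \(k = 5\)
nearest neighbours, self excluded; low values mean many species share the
trait combination — the signature of intense interspecific competition.
*Specialisation* (`specialisation_scores()`) is the distance to the
arithmetic centroid: extreme trait combinations score high. The neighbour
count is a tunable with a robustness harness
(`neighbour_robustness()` correlates the score vector across
\(k \in \{1, 3, 5, 10, 100\}\)); distance ties at the \(k\)-th neighbour
are resolved by species identifier so rankings are reproducible.

Outliers are flagged by the Tukey upper fence, score \(> Q_3 + 1.5\,
\mathrm{IQR}\). This is a design choice: a boxplot-style outlier count is
the natural reading of "outliers" for a skewed, non-negative score, and it
is parameter-free. Subset re-analysis (`subset_rerun()`) restricts the
candidate-neighbour pool while keeping the full-space coordinates — the
subset's positions are still defined relative to the whole order — with a
`refit = TRUE` escape hatch that redoes the factor analysis on the subset
for sensitivity analysis.

## Models of trait evolution

Writing \(s_{ij}\) for the shared root-to-MRCA path length of tips \(i,
j\) and \(T\) for tree height, the package builds model-implied tip
covariances (`model_covariance()`):

* Brownian motion: \(C_{ij} = \sigma^2 s_{ij}\);
* Pagel's \(\lambda\): off-diagonals multiplied by \(\lambda \in [0, 1]\);
* Ornstein–Uhlenbeck:
  \(C_{ij} = \frac{\sigma^2}{2\alpha} e^{-2\alpha (T - s_{ij})}
  (1 - e^{-2\alpha s_{ij}})\);
* early burst: rate \(\sigma^2 e^{r t}\) with \(r < 0\), giving
  \(C_{ij} = \sigma^2 (e^{r s_{ij}} - 1)/r\) on an ultrametric tree.

The OU model fixes the root state and constrains the optimum to equal it
(a three-parameter OU). On an ultrametric tree a free optimum is only
weakly identifiable from tip data, and this convention keeps the
\(\alpha \to 0\) limit exactly Brownian — a property the tests check
numerically (agreement within \(10^{-5}\)), along with the matching
\(r \to 0\) early-burst limit. A consequence worth knowing: because
early-burst variance accrues early, on branches shared by related tips,
EB *raises* tip correlations relative to BM rather than lowering them
(\((1 - e^{rs})/(1 - e^{rT}) \ge s/T\) for \(r < 0\)).

Likelihoods are multivariate normal with the root state and rate profiled
out in closed form (GLS mean; quadratic form over \(n\)), reducing every
fit to a bounded 1-D search: \(\lambda\) over \([0, 1]\) with a 21-point
pre-scan, \(\alpha\) over \([10^{-8}/T, 50/T]\) and \(-r\) over
\([10^{-8}/T, 10/T]\) on log scale with 20-point pre-scans, each followed
by golden-section refinement. Pre-scans guard against multimodal profiles;
boundary solutions and zero residual variance are flagged in the fit's
`convergence` field, never silently accepted. All solves are Cholesky
factorisations; a failed factorisation triggers a \(10^{-10}\) diagonal
jitter with a warning. Trees are not rescaled, so \(\sigma^2\), \(\alpha\)
and \(r\) carry the tree's time units; ultrametricity is required (relative
tolerance \(10^{-6}\)) for OU/EB and checked, not repaired.

Model comparison uses AICc (\(k = 2\) for BM, 3 for OU/EB) and Akaike
weights; `evo_across_trees()` repeats signal estimation and model selection
over a tree sample, Holm-correcting the boundary likelihood-ratio tests
within each tree across the retained dimensions (the two boundary families,
\(\lambda = 0\) and \(\lambda = 1\), are corrected separately — the
correction family is per tree because each tree yields one joint report
across dimensions).

## Tree-replicated PGLS

`multi_tree_pgls()` regresses a niche score, min–max scaled to \([0, 1]\),
on the 11 elements: continuous elements centred to unit variance,
categorical elements as treatment dummies with folivore, arboreal and
nocturnal as reference levels — 18 terms including the intercept. The
error covariance is the Brownian matrix of each tree by default; a
per-tree ML \(\lambda\) structure is available via
`correlation = "lambda"` for sensitivity analysis, since the equation
itself does not dictate the correlation structure. Estimation is exact
GLS via Cholesky whitening, t tests on \(n - p\) degrees of freedom.
Within each tree, p-values are Holm-corrected across the full 18-term
family — the intercept included, because its significance count is part of
the reported table — and across trees the package reports per-term medians
(rounded to 4 decimals) and the count of trees with adjusted \(p <
0.05\).

## The synthetic-data generator

`simulate_study()` exists so that every stage is testable against known
truth without any downloads. Its defaults mirror the study conditions: 191
species, 100 trees, and a trait table with the full 16-variable schema.
Choices a user should know about:

* **Trees** are Yule trees rescaled to unit height; the tree *sample* is a
  set of independent topologies on the same tip set, emulating the
  uncertainty of a posterior sample of dated phylogenies. Traits are
  generated on the first (reference) tree, so cross-tree analyses see
  realistic topology mismatch.
* **Life history** is one latent Brownian factor plus independent noise
  per duration, with the latent share tuned so the block's PC1 explains
  about 80% of its variance (an equicorrelated block with pairwise
  \(\rho\) puts \((1 + 5\rho)/6\) of its variance on PC1; the default
  targets 0.8). Durations are mapped to plausible day scales.
* **Continuous traits** evolve under declared BM, \(\lambda\) or OU
  models; mass is Brownian on log scale; counts are rounded with a floor
  of 1; ranges are floored at 0.
* **Categorical traits** evolve under symmetric Mk processes (rate 2 per
  unit height) simulated as continuous-time Markov walks along branches.
  A draw that fails to realise every declared level is redrawn with a
  deterministic seed offset (at most 50 attempts), so synthetic tables
  always satisfy the 17-unit inertia identity.
* Everything derives from one master seed and a config; `write_truth()`
  serialises the generating parameters so any dataset is reproducible
  byte-for-byte.

What the generator does *not* emulate: real primate trait values or their
empirical covariances, geographic or climatic structure, correlated
evolution between elements, or taxonomic sampling gaps. Passing tests
therefore establish that the machinery is correct (oracle equivalence,
parameter recovery, error control, determinism) — not that any biological
conclusion about primates transfers; analyses of real data stand on their
own inputs.

## Problem sizes and verification

The test-suite simulations are sized for routine runs on a single core:
\(\lambda\) recovery uses 100 replicates of 200-tip trees per generating
value (median absolute error below 0.15; Brownian data recovers
\(\hat\lambda \ge 0.9\)); model-selection sanity uses 100 trees of 100
tips per scenario (the generating model must win a majority; under BM
truth, spurious early-burst support stays below 30%); PGLS recovery uses
100 replicates at 200 tips (estimates within two Monte-Carlo standard
errors of truth) and 200 null replicates for family-wise error control;
and the full pipeline is rerun twice at study scale (191 species, 100
trees) to assert byte-identical output. `scripts/acceptance.R` recomputes
the same classes of quantities from scratch at comparable sizes.

## Known limitations

* Each niche dimension is analysed independently; there is no multivariate
  (correlated-dimension) evolutionary model and no branch-specific rate
  shift detection.
* The OU fit assumes a single optimum tied to the root state; regimes and
  free optima are out of scope.
* Uniqueness depends on the sampled species pool: it is a statement about
  the analysed set, not about unsampled or extinct relatives (the subset
  machinery makes the pool explicit rather than removing the dependence).
* The Tukey-fence outlier rule and the \(k = 5\) default are conventions;
  both are exposed as parameters and the robustness harness quantifies
  sensitivity to \(k\).
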