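---
title: "Methods: stomach-content diet analysis with tunadiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stomach-content diet analysis with tunadiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and estimators, the assumptions behind them, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, and the numerical choices made where the design was open.
Every empirical claim here is one the test suite or
`scripts/acceptance.R` computes; nothing is quoted from elsewhere.

## The data model

The unit of analysis is one predator stomach (`stomach_id`, collection
`year`, optionally month, coordinates, fork length FL and operculum
length OL in cm). Each prey item carries a taxon (broad group
fish/cephalopod/crustacean, family, optionally genus/species), a
measurement state (`whole_length`, `hard_part`, `unmeasured`, values in
mm: standard length for fishes, mantle length for cephalopods, total
length for crustaceans), and a bait flag. Bait items and empty stomachs
are excluded from every analysis at construction time; exclusions are
counted and reported. Hyperiid amphipods are grouped at suborder level
("Hyperiidea") because family-level identification of hyperiids is
unreliable in partially digested material; prey not identified to family
are carried as class-level "Unidentified ..." categories.

Allometric conversions and energy densities are *data*, not code: CSV
tables with a taxonomic scope per row, resolved per query by the fallback
chain species → genus → family → broad group, with declared input/output
units converted on application. This keeps published regression
coefficients out of the source and makes the resolution order testable
(an exhaustive precedence test covers all sixteen presence patterns).

## Diet composition

Within a stomach, proportional abundance is the count fraction per prey
group; using proportions rather than counts stops stomachs full of many
small prey from dominating similarity analyses, and removes most of the
predator-size signal from prey importance. Mean proportional abundance
(p̄) across stomachs is an unweighted mean: every stomach counts equally.

Rare families are pooled before similarity analyses: a family is kept as
its own prey group only if its p̄ across **all** stomachs is strictly
greater than the lumping threshold (default 0.01); the rest join "Other
fishes"/"Other cephalopods"/"Other crustaceans". Class-level unidentified
categories are never lumped, because they are not families and already
aggregate unknown diversity. The strict inequality at the threshold is a
deliberate reading of "more than 1%".

%N and %FO are computed per predator grouping (calendar year, or the
fitted tree's terminal nodes) at taxon or family resolution. Reported
percentages are rounded half away from zero to one decimal only for
display and table comparison; internal values are never rounded. The
package ships the published 2008–2016 SCB bluefin composition counts as a
reference surface (`scb_reference_counts()`); rebuilding per-stomach
records from those counts and recomputing %N/%FO reproduces every printed
percentage, except that the printed 2015–16 %FO column is internally
consistent only with a denominator of 134 stomachs rather than the stated
194. The package does not silently replicate either choice: it computes
%FO from the stated stomach counts and raises a warning describing the
implied denominator (`check_reference_fo_consistency()`).

## The compositional regression tree

The response for the tree is the stomachs × prey-groups proportion
matrix. Node impurity is the within-node sum of squared Euclidean
deviations about the node-mean composition; a split's quality is its
impurity decrease. Squared Euclidean distance on proportions is the
simplest multivariate-regression-tree criterion consistent with
"minimise an error criterion", is exactly decomposable (between-group SS
= impurity decrease), and is fully testable against brute force; it is a
package design choice and is isolated behind `node_impurity()` so an
alternative criterion could be swapped in.

Splitting is exhaustive: all midpoints between sorted distinct values for
numeric covariates, all binary level partitions for categorical ones
(capped at 12 levels). Ties break by covariate order, then by the smaller
threshold, making fits reproducible. The affirmative condition goes left.
Rows missing the split covariate do not participate in scoring that
covariate; at routing time they follow *surrogate splits* — for each
other covariate, the rule that best reproduces the primary left/right
assignment, kept only when its agreement exceeds the majority-direction
baseline ((matches − majority)/(n − majority) > 0) — and failing all
surrogates, the majority direction. Surrogates also contribute
agreement × decrease to variable importance, so a predictor masked by a
correlated rival still shows up; importances are normalised to max = 1.

Model size comes from cost-complexity (weakest-link) pruning and k-fold
cross-validation (default 10): per candidate complexity, held-out sums
of squares are pooled over folds and divided by the root sum of squares
(relative error); the standard error is the standard deviation of
size-normalised per-fold relative errors divided by √k. The selected
subtree is the smallest whose cv error is within one SE of the minimum
(1-SE rule). R² is defined as 1 − cv relative error of the selected
subtree, an identity the acceptance suite checks on every fit. Default
control: `min_split = 20`, `min_bucket = 7`, minimum gain 1% of root
impurity, maximum depth 30 — all overridable via `cart_control()`.

## Diversity and coverage

Stomachs are the sampling units (incidence framework): the analysis asks
how diet diversity accumulates as stomachs are added, which is also how
sample completeness is reported. For incidence frequencies Y_j over T
units (U = ΣY_j), the order-1 Hill number at subsample size t ≤ T is the
exponential of the expected plug-in entropy of a hypergeometric subsample,
with entropy terms scaled by the *expected* incidence total u_t = tU/T.
That scaling makes the estimator linear in the expected incidence
frequency counts E[Q_k(t)], hence analytic, and it reduces exactly to the
observed incidence entropy at t = T. The same definition is enumerated
directly (all C(T,t) subsamples) as the test oracle for T ≤ 6. Coverage
uses the standard incidence singleton/doubleton estimator at t = T, its
rarefied form for t < T, and its geometric extension beyond T; its oracle
is a leave-one-out subsample enumeration. Extrapolated diversity blends
observed and asymptotic entropy in proportion T/t, with the asymptotic
entropy from a coverage-adjusted (Horvitz–Thompson-corrected) estimate;
extrapolation past 2T warns. Order-0 richness is exposed
(`hill_richness()`) but is not part of the validated surface.
Abundance-based framing was rejected because completeness is reported per
number of stomachs, which only the incidence framework yields.

## Distance-based statistics

Bray–Curtis dissimilarity on the proportion matrix is the community-
ecology default and is bounded [0, 1] with 1 for disjoint prey supports.
PERMANOVA uses Anderson's distance-based pseudo-F with unrestricted
permutation of raw labels and the add-one p-value correction; pairwise
contrasts report t = √F with raw (unadjusted) p-values, as pairwise
results are conventionally reported for this analysis, with an exact
enumeration mode for small n used by the oracle tests. Group similarity
summaries are 100 × (1 − mean pairwise dissimilarity) within and among
groups. PERMDISP delegates to the established implementation of
Anderson's dispersion test (distances to group centroids in the PCoA
embedding with the negative-eigenvalue correction; permutation of
least-squares residuals). PCoA is the classical double-centred
eigendecomposition, returning coordinates only for positive-eigenvalue
axes while reporting the full spectrum, since Bray–Curtis is semi-metric
and produces negative eigenvalues.

## Prey reconstruction and energetics

Reconstruction proceeds in four ordered stages, each recording
provenance per prey item:

1. **Hard parts to lengths.** Resolved hard-part regressions convert
   vertebrae/beak/carapace measurements to whole lengths. Unidentified
   squids with measured beaks get the mean prediction over all
   beak-to-length regressions used for the study's identified
   cephalopods. Unresolvable hard parts stay unmeasured and are counted.
2. **Hierarchical imputation.** Unmeasured prey of a measured taxon take
   the unweighted arithmetic mean length of measured conspecifics from,
   in order: the same stomach, the same sampling year, the same tree
   group (sources `imputed_stomach`/`imputed_year`/`imputed_group`).
   Family-level identifications use family-level means through the same
   hierarchy; unidentified prey take year-level (else group-level) means
   over their broad group (`imputed_fallback`). Taxa with no measured
   representative anywhere are excluded from mass/energy totals, with a
   count reported. The unweighted mean is a choice: no weighting is
   implied by "mean lengths", and it keeps the estimate order-independent.
3. **Mass.** Cephalopods with measured beaks convert beak → mass
   directly (mean over all cephalopod regressions for unidentified
   squids); everything else converts length → mass. Non-positive lengths
   are rejected.
4. **Energy.** mass × resolved energy density (kJ/g wet mass).
   Unidentified prey use the unweighted mean density over identified prey
   *items* (not species) of the same broad group in the same year, else
   the same tree group — item-level averaging reproduces "annual or
   group-level averages" while staying order-independent.

Stomach totals are additive over constituent prey. Contents above 3% of
predator body mass (strictly greater; exactly 3.0% is retained) are
excluded from mass/energy analyses, since reported maximum daily rations
for bluefin of the sampled sizes are about 2–3% BM and heavier contents
indicate overestimated prey mass or multi-day accumulation. Stomachs
without any predator size estimate are excluded from %BM analyses under
their own log category rather than silently dropped. Predator mass
derives from fork length (and fork length from operculum length) through
user-supplied conversions — the package hard-codes no coefficients.

## Rank-based comparisons

Per-stomach prey metrics are skewed, so group contrasts are rank-based:
Kruskal–Wallis (average ranks, ties correction) with Bonferroni-adjusted
pairwise Wilcoxon tests when variances are homogeneous; Welch's
heteroscedastic ANOVA on global average ranks with Games–Howell post hoc
contrasts (studentized-range reference, Welch df per pair) otherwise.
The homogeneity screen in `choose_rank_test()` is Brown–Forsythe (Levene
on medians) at α = 0.05 — the screening procedure is an assumption of
this package, documented rather than inherited. All tests are invariant
under monotone transformation of the response, which the suite checks.
Games–Howell is implemented in the package and verified against an
independent computation from the textbook formulas.

## The synthetic generator

`simulate_diet_study()` emulates the study conditions: three temporal
regimes with distinct family-level compositions (2008
myctophid/enoploteuthid; 2009–14 diverse with hyperiids at p̄ ≈ 0.22;
2015–16 pelagic red crab ≈ 0.52 and anchovy ≈ 0.14), stomach numbers
allocated 88:439:194, 25% empty stomachs, zero-truncated negative
binomial prey totals with regime means 22.7/34.4/20.1 (dispersion 1.5 —
real stomach counts are overdispersed, with maxima above a hundred),
per-stomach Dirichlet perturbation of the regime composition, taxon-
specific lognormal lengths (typical prey < 10 cm), independent per-prey
measurement states (measured cephalopods are always beaks), predator fork
lengths uniform in regime ranges within 42–174 cm, and months drawn with
regime-specific means so that month correlates with year as in seasonal
fisheries sampling. Hard-part values are generated by *inverting* the
supplied regressions, so reconstruction is exactly invertible, and true
lengths/masses/energies go to a hidden side table used only by recovery
tests. The beak-to-mass table is composed from beak-to-length and
length-to-mass so both mass routes agree exactly.

The Dirichlet concentration per regime is a free parameter of the design
(no within-stomach clustering value is implied by the study conditions).
Defaults are 12 / 4 / 8 for 2008 / 2009–14 / 2015–16: the ordering
matches the reported within-group similarity ordering (2008 most
homogeneous, 2009–14 least), and the magnitudes are set so the fixture
behaves like regime-structured data — the pruned tree recovers exactly
three year-split terminals with year importance 1 in at least 95 of 100
seeds at n = 300, which the acceptance suite measures. Much smaller
concentrations produce data substantially noisier than the fit quality
published for the real study and are better thought of as a stress test
than as the study conditions.

What the generator does **not** emulate: spatial structure (coordinates
are uniform in a bounding box), seasonal migration, digestion-state
biases, correlated measurement availability within a stomach, and
aggregation feeding in the default regimes — per-stomach compositions
vary smoothly around the regime mean rather than flipping between
near-monospecific feeding events. A low-concentration regime
(concentration < 1) produces near-vertex compositions and is how the
test suite represents feeding on dense monospecific aggregations for the
specialist/generalist classification. Passing tests on synthetic data
therefore validate the estimators and their contracts, not any
biological claim about real stomachs.

## Problem sizes and runtime choices

The validated problem sizes are: 300-stomach fixtures for tree recovery
(100 seeds), 1000 null datasets of n = 40 for PERMANOVA type-I
calibration (199 permutations each) and 1000 for Welch-on-ranks,
exhaustive oracles at n ≤ 12 rows (splits), n ≤ 8 (PERMANOVA
enumeration), T ≤ 6 (diversity subsampling), and 300-stomach recovery
experiments for energetics. These sizes give stable Monte-Carlo estimates
at interactive runtimes; all simulations are seed-controlled and
reproducible.

## Known limitations

- The tree's split criterion and surrogate-agreement formula are
  implementation-defined (documented above); other diet-tree software may
  make different choices and produce different importances.
- Bootstrap confidence intervals — on tree structure and on diversity
  estimates — are out of scope.
- Extrapolated diversity beyond 2T is unreliable and only warned about,
  not prevented.
- The optional ingestion of spreadsheet-deposited specimen data is not
  part of the tested core; the delimited-text schemas are the interface.
- Pairwise PERMANOVA p-values are reported raw by default; a
  multiple-testing adjustment is available but off, matching how pairwise
  results are conventionally reported for this analysis.
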