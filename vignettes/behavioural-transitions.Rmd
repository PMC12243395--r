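---
title: "Charting transitions in behavioural difficulty profiles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting transitions in behavioural difficulty profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Behavioural difficulties in childhood rarely sort themselves into stable
diagnostic boxes: profiles of emotional, conduct, hyperactivity, peer and
social difficulty co-occur, and the mix changes as children grow. A
population-level way to study this is to (i) identify, at each developmental
wave, data-driven subgroups of children with similar parent-rated difficulty
profiles, (ii) follow individual children across waves and test which
subgroup-to-subgroup transitions occur more often than chance, and
(iii) ask which earlier-life factors distinguish children who move from one
elevated-difficulty profile to another from children with the same starting
profile who move to no apparent difficulties.

`sdqtransitions` implements that pipeline for the parent-rated Strengths and
Difficulties Questionnaire (SDQ): 25 items, each scored 0 = not true,
1 = somewhat true, 2 = certainly true, in five 5-item subscales (emotional,
conduct, hyperactivity, peer, prosocial). Because real national-cohort data of
this kind is access-restricted, the package ships a synthetic cohort generator
with fully known ground truth, and every stage of the pipeline is validated
against that truth.

## Scoring and partition

Each subscale score is the sum of its five items (0–10). The prosocial scale
is reverse-scored into an "antisocial" difficulty (`10 - prosocial sum`) so
that higher always means more difficulty. Children missing any item are
excluded from scoring (the analysis assumes complete SDQ responses); an
out-of-range item is an error, not an exclusion.

Each subscale score is assigned to one of three bands. The shipped band table
(`inst/extdata/bands_parent_sdq.yaml`) carries the published parent-SDQ
cutpoints; it is data, not code, and fully overridable. The boundary
convention is fixed and explicit: *normal* includes `cut1` (`score <= cut1`),
*borderline* includes `cut2`, *abnormal* is everything above. A child is
**non-elevated** iff all five bands are normal; one borderline band suffices
for **elevated**. Partition is therefore monotone: raising a difficulty score
can never move a child out of the elevated group.

Clustering operates on the elevated group only. The non-elevated majority
would otherwise dominate the space with overall-severity variance and flatten
the profile structure the analysis is after. Consequently, z-scoring
(`zscore_subscales`) is computed *within* each wave's screened elevated group
— that group is the population being clustered — using the sample SD
(n−1; a `sd_type` switch gives the population convention).

## Outlier screening

Two scale-relative rules run on the same input within each (wave, partition
group) stratum, and their union is removed:

* **Univariate**: flag a child whose score on any subscale deviates from the
  subscale *median* by more than 3 *standard deviations* (the hybrid
  centre/spread pair is deliberate; the boundary is strict, so a point at
  exactly 3 SD stays).
* **Multivariate**: flag a child whose squared Mahalanobis distance to the
  stratum mean, under the classical sample covariance, exceeds the
  chi-square(df = 5) quantile at `alpha = 0.999`. The quantile probability is
  a conservative screening default and is exposed in the interface; the
  classical (non-robust) covariance is used because nothing in the design
  calls for a robust estimator.

Running the two rules in parallel on the same input (rather than
sequentially) keeps the result order-invariant. Both rules are invariant to
positive rescaling of the scores, and re-screening retained data can only
shrink the flag set.

## Embedding and cluster selection

The five z-scored subscales are projected to two dimensions with UMAP using a
deliberately conservative configuration: `n_neighbors = 50` (large
neighbourhoods suppress fine-grained structure that is more likely noise),
`min_dist = 0.01` (dense, well-separated clusters), and a correlation
distance metric (children are similar when their difficulty *patterns*
correlate, regardless of overall severity, which the z-scoring has already
partialled out).

One numerical subtlety matters here. Subscale scores are discrete 0–10 sums,
so a cohort of a few thousand elevated children contains hundreds of children
with *exactly identical* profiles. Feeding those duplicates to the
nearest-neighbour search directly degrades the embedding: tied zero distances
crowd each child's neighbour list with copies of itself. `embed_profiles`
therefore fits UMAP on the unique profile rows and assigns each duplicate its
representative's coordinates — the same treatment umap-learn exposes as
`unique=True`. This also guarantees the obvious contract that identical
inputs receive identical coordinates. The embedding is deterministic given
its seed (single-threaded optimisation).

k-means (10 restarts, seeded) is then scanned over `k = 2..10`, and a
solution must pass three criteria:

1. **Silhouette**: mean silhouette above 0.5, and every per-cluster mean
   silhouette positive.
2. **Calinski–Harabasz "steep increase"**: candidates are ranked by the
   backward relative jump `(CH(k) - CH(k-1)) / CH(k-1)`. The smallest k in
   the range has no preceding value and scores 0, which gives it a sensible
   role: it wins only when no larger k shows a genuine jump (for data with
   two clean clusters, CH peaks at 2 and all later jumps are negative). A
   `ch_rule = "max"` switch falls back to plain maximum CH.
3. **Bootstrap Jaccard stability**: for the ranked candidates in turn, 1,000
   bootstrap resamples (package default; the test suite and acceptance study
   use 30–200 to keep runtimes proportionate) refit k-means on the resampled
   coordinates, each original cluster is matched to its best-overlapping
   bootstrap cluster by Jaccard similarity over the children present in the
   resample (a child drawn twice counts once), and the per-cluster mean over
   resamples must reach 0.85 for every cluster.

The first candidate passing all three is accepted; otherwise the best
available solution is returned with `accepted = FALSE` and the full
diagnostic table, never a silent fallback. Stability resampling refits
k-means on the *fixed* embedding rather than re-embedding each resample: the
question it answers is whether the partition of this embedding is stable, and
it keeps the procedure tractable at cohort scale.

## Transition testing

Children are linked across consecutive waves by an inner join on id; children
lost to follow-up simply drop out of the denominators. Each
(source group × destination group) cell is tested against the **equal-split
null** `p0 = 1/K`: if membership carried no information, children from a
source group would spread uniformly over the K destination groups. K counts
*all* destination groups including the non-elevated group (configurable).
The test is the standard one-sample proportion z test,
`z = (p̂ - p0)/sqrt(p0(1-p0)/n)`, two-sided, Bonferroni-corrected over all
cells of the wave-pair table (each wave pair is its own correction family).
A cell is reported significant only when the adjusted p is below 0.05 *and*
the observed proportion exceeds the null — only above-chance transitions are
of interest, but the two-sided test with a direction filter keeps the
correction honest.

A significant transition could still be an artefact of clustering
imprecision: borderline members of a cluster can "switch" labels between
waves without any behavioural change. `validate_transition` therefore
compares the source-wave silhouette scores of the transitioning children with
those of their whole source cluster by a two-sample Kolmogorov–Smirnov test
(the KS choice is ours; any two-sample distributional test would serve). A
small p here is a *warning* that the transition is carried by poorly-anchored
members. Cells with fewer than 5 members are skipped with an explicit reason.

## Risk-factor identification

For one significant transition, the **transition of interest** (source
cluster → elevated destination cluster) is contrasted with the **control
transition** (same source cluster → non-elevated group); children going
anywhere else are excluded. The classifier pipeline is leakage-guarded
end to end:

1. children missing more than 30% of the features are removed (strictly more
   than: exactly 30% stays);
2. stratified 80/20 train/test split (stratification keeps imbalanced
   contrasts testable);
3. k-nearest-neighbour imputation (`k = 5` default) with distances over the
   mutually observed coordinates, fit on the training rows only and applied
   to both splits;
4. min–max scaling, again fit on train only (test values may leave [0, 1]);
5. gradient-boosted trees (XGBoost) tuned by exhaustive grid search with
   stratified 5-fold CV on the training sample over `nrounds`, `eta`,
   `max_depth`, `min_child_weight`, `gamma` and `reg_alpha`, with
   `scale_pos_weight` fixed to the inverse class ratio. The selection score
   is the unweighted mean of accuracy and F1 (a lexicographic alternative
   would be easy to add; the unweighted mean keeps both objectives active).

Candidate risk factors are then filtered twice:

* **Gain thresholding**: sweep the distinct gain-importance values; for each
  threshold refit on the training set with the surviving features and score
  on the test set; keep the best-scoring set, breaking ties toward fewer
  features. Scoring the sweep on the test sample follows the design this
  pipeline reproduces and is optimistically biased; the bias is confined to
  *selection* and the final report carries the test metrics so the reader can
  judge.
* **Permutation survival**: shuffle each feature's test column 20–50 times
  and record the mean accuracy drop. A feature survives only if its drop
  (a) is positive, (b) exceeds one standard error of the test accuracy
  estimate, `sqrt(acc(1-acc)/n_test)` — a smaller drop cannot be
  distinguished from evaluation noise — and (c) after centring all drops by
  their median (every drop shares the same unshuffled baseline, so a lucky
  baseline shifts all of them together and the median of the mostly-irrelevant
  candidate set estimates that shift), exceeds a noise floor: the 95th
  percentile of the centred drops of zero-gain features or, when the ensemble
  touches every feature, of the magnitudes of the negative centred drops,
  whose sign proves they are chance. These three conditions are a priori
  statistical calibrations of a survival criterion that is otherwise
  underdetermined; with them, the all-noise null yields well under one
  genuine factor among 50 candidates on average, while two planted 1.5
  log-odds effects are recovered essentially always at n = 2,000 (both are
  exercised in the test suite).

**Genuine risk factors** are the intersection: selected by the threshold
sweep *and* surviving permutation.

## The synthetic cohort generator

`generate_cohort` is first-class, tested code, and defines the study
conditions for everything above. It emulates:

* per-wave latent cluster structure: each group has a mean vector over the
  five subscales; each item is drawn `Binomial(2, p)` with
  `p = clamp(mean/10 + Normal(0, dispersion), 0, 1)`, so the expected
  subscale sum equals the profile mean and every item value is legal. The
  prosocial items are generated from `10 - antisocial mean`, so the scoring
  reversal recovers the intended difficulty. This item model is a stand-in:
  nothing in the source data dictates a generative model, and real SDQ items
  have correlated residuals this model does not attempt;
* a designated non-elevated majority profile (default 60% of the first
  wave);
* Markov transitions between waves, with covariate effects entering as
  additive terms on the destination log-odds (multinomial logit): zero
  coefficients reduce exactly to the base matrix, and structural zeros stay
  zero;
* child-level covariates (normal / Bernoulli / uniform) with MCAR or MAR
  missingness — MAR modulates the masking probability on the logit scale by a
  named standardised conditioning covariate — and simple monotone per-wave
  dropout. Truth labels are never masked.

Everything is deterministic given the spec's single seed. What the generator
does *not* emulate — survey weights, stratified sampling designs, informative
attrition, item-level response styles — bounds what passing tests show: they
validate the statistical machinery under known truth, not the demographic
fidelity of any particular cohort.

## Problem sizes and runtime choices

The package defaults (bootstrap B = 1,000; k range 2–10) suit a real
analysis. The test suite and the acceptance script scale the simulations to
keep a full run proportionate: planted-profile recovery uses 20 cohorts of
1,500 elevated children with B = 100; transition error rates use 200
simulated wave pairs of 500 children per source; risk-factor recovery uses 20
cohorts of 2,000 children with 52 covariates and a compact 8-point
hyperparameter grid; the end-to-end acceptance study uses one 14,000-child,
three-wave cohort (the scale of a national birth-cohort sweep) with B = 200.

## Limitations

* Hard k-means assignment: soft or latent-class clustering would express
  membership uncertainty but is out of scope by design.
* The equal-split null is a deliberately simple chance model; it asks "more
  than uniform", not "more than a fitted Markov baseline".
* The threshold sweep's use of the test sample biases its selection score
  optimistically (kept, documented above).
* The three-band cutpoints ship as an overridable default; analyses of other
  informant versions of the questionnaire need their own band table.
* UMAP preserves neighbourhood structure, not metric structure: distances in
  the embedding (and hence silhouette/CH magnitudes) are tool-relative, which
  is why cluster acceptance rests on three criteria rather than any one
  number.
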