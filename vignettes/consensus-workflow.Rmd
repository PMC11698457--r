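---
title: "Two-branch consensus prediction of bioactive metabolites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-branch consensus prediction of bioactive metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzConsensus)
```

## The problem

An untargeted LC-MS screen of a plant extract yields a table of m/z
features (peak responses per sample) and, per extract sample, bioassay
potencies: the IC50 of alpha-glucosidase inhibition (AGI) and of the DPPH
radical-scavenging assay. The goal is to predict *which features are the
bioactive compounds* without knowing any compound identity in advance.
The design studied here uses five ethanol/water solvent mixtures (0, 25,
50, 75, 100% ethanol), six replicate extractions each, so 30 samples over
80 features. Because IC50 falls as potency rises, all modelling uses the
reciprocals 1/IC50, which increase with activity.

`mzConsensus` implements this analysis as two independent branches whose
predictions are intersected:

* **Branch A (chemometrics).** A suite of 25 latent-projection models
  (PCA; PLS/OPLS on each activity scale singly and in pairs; PLS-DA and
  OPLS-DA on the active/non-active class split) is fitted on the
  unit-variance-scaled table. Models must pass a three-part validity
  gate; each valid model contributes its top-25 activity-aligned features
  (first-component loading rank, VIP > 1), and features appearing in more
  than 50% of the valid models' lists are the branch prediction.
* **Branch B (machine learning).** A random-forest regressor of 1/IC50
  AGI is trained on the raw responses, with and without stratified
  bootstrap augmentation from 30 to 50 samples. Each forest yields a
  permutation-importance list (mean increase of RMSE over 100 shuffles
  per feature) and a SHAP list (mean absolute Shapley attribution per
  feature); the fifth list is the top-25 correlation ranking. After
  removing features that correlate non-positively with the target
  (importance also flags *suppressors*; the screen keeps only
  activity-raising candidates), features in at least 50% of the five
  lists are the branch prediction.

The final prediction is the intersection of the branches, collapsed to
compounds by m/z equality (two features with the same m/z at the reported
3-decimal precision are one compound). On the packaged published branch
lists this reproduces the reference result:

```{r reference}
ex <- referenceExample()
ex$features
ex$compounds
```

## The validity gate

A projection model is kept only if all of the following hold:

1. **Fit-prediction gap**: R2Y - Q2 <= 0.3, where Q2 = 1 - PRESS/SS under
   7-fold cross-validation. A large gap flags overfitting.
2. **Response permutation** (20 permutations): rows of Y are shuffled, the
   model refitted at its original component configuration, and R2Y and Q2
   regressed on the absolute correlation of the permuted response to the
   original. The intercepts at correlation zero must satisfy
   R2 intercept <= 0.4 and Q2 intercept <= 0.05. The regression includes
   the unpermuted point at correlation 1 (the usual plotting convention);
   `includeOriginal = FALSE` switches it off.
3. **CV-ANOVA**: F = ((SS - PRESS)/A) / (PRESS/(n-1-A)) with A the total
   number of fitted components, upper-tail p <= 0.05 per target. F is
   clamped at zero when the model does not beat the response mean, so
   p = 1 in that case.

Two properties of this gate deserve emphasis. First, CV-ANOVA is
*conservative under the null*: for a response unrelated to X the
cross-validated PRESS typically exceeds the total SS, F clamps at 0 and
the p-value is 1. Null p-values are therefore far from uniform — the test
under-rejects; it never inflates false positives. Second, the
discriminant models' response (the 100%-ethanol class) is a function of
the experimental design, not of the assay: when activities are scrambled
but the table is intact, DA models can legitimately remain valid because
the class really is encoded in X. A "global null" therefore requires
decoupling X from *all* annotations (permuting the table's rows), under
which the gate passes almost nothing.

## Modelling choices

* **NIPALS throughout.** PCA and PLS components are extracted by NIPALS
  with deflation; initialization is deterministic (largest sum-of-squares
  column) and each weight vector's sign is fixed so refits are
  bit-reproducible. OPLS removes Y-orthogonal components from X (weights
  orthogonalized against the predictive weight basis) and fits the
  predictive part on the filtered matrix; with a single response,
  OPLS(1 predictive + a orthogonal) fits Y exactly like PLS(a+1) — a
  numerical identity the test suite asserts.
* **Component counts.** The number of components is not reported for the
  original models, so the standard forward rule is used: add a component
  (orthogonal component for OPLS) while cross-validated Q2 improves by
  more than 0.01, capped at 5 (+5). Cross-validation uses 7 interleaved
  folds — a common chemometrics default — with a seeded-random
  alternative.
* **Discriminant encoding.** The 2-class split (active = 100% ethanol
  extracts) is encoded as one UV-scaled indicator column per class. The
  continuous output listed alongside the DA rows of the model suite is
  used only to orient feature selection toward higher activity.
* **Orientation.** Feature selection ranks by the first predictive
  component's loading, oriented by the sign of the correlation between
  the first score and the activity on the 1/IC50 scale; for IC50-scale
  models the corresponding reciprocal target provides the orientation, so
  "top" always means activity-raising. Ties break by stable feature
  order; VIP must strictly exceed 1.
* **Trees.** No tree-ensemble backend ships with the environment's R, so
  the package implements CART regression trees, bagged forests, gradient
  boosting and AdaBoost.R2 in compiled code. Fixed settings follow the
  study: single tree (binary splits, min leaf 2, no split below 5
  samples, stop at 95% purity — read for regression as the node variance
  falling to 5% of the root variance); forest of 100 trees with min split
  2; boosting with 100 depth-3 trees at rate 0.05; AdaBoost with 100
  stumps, linear loss, rate 0.01. The forest samples p/3 features per
  split (the standard regression-forest default; the study fixed only the
  tree count and minimum split).
* **Shapley values.** Attributions are exact interventional Shapley
  values for tree ensembles: every explicand/background pair is walked
  once, enumerating the divergent-feature paths, and leaf values are
  combined with exact coalition weights, so local accuracy (attributions
  summing to prediction minus mean background prediction) holds to
  machine precision. The background set defaults to the training data.
  The suite checks the values against brute-force coalition enumeration.
* **Importance evaluation set.** The original description does not say
  whether importances were computed on train, test or all data; the
  default here is the full dataset, and the evaluation set is an
  argument.
* **Resampling order.** The default augments *after* splitting (only the
  training side is bootstrapped), so no bootstrap copy of a test extract
  can leak into training. `augment_then_split` mirrors the
  pool-then-split reading of the original protocol and warns about the
  leakage it permits.
* **m/z merge.** Exact equality at three decimals by default (the
  precision of the reported tables); a ppm mode (single-linkage chaining,
  default 10 ppm) suits raw data.

## What the synthetic generator emulates

`simulateExtractStudy()` generates the stated design: 5 solvent classes x
6 replicates, 80 features, log-normal responses (nonnegative,
right-skewed, zero meaning not detected is possible in principle but not
typical at the default scale). Its structure:

* **Planted actives** (defaults mirror the reference variable IDs: Var31,
  Var42-Var50) gain log-response with ethanol fraction (slope 1.5 from 0
  to 100%); three **negative-influence features** (Var5/8/11) mirror that
  slope downward and are subtracted from the activity.
* **Correlated blocks** (within-block correlation 0.9) mimic the three
  compound groups visible in the reference correlation heatmap: one block
  of six actives, one of three, and one pairing Var42 with two background
  companions.
* **Background covariance.** The remaining features carry mild solvent
  slopes (sd 0.3) and co-vary through five gradient-independent
  "chemical family" factors (correlation 0.7). This choice is what makes
  the emulation honest: real feature tables have low effective
  dimensionality, which is exactly why permuted-response refits of a
  p >> n projection model do *not* reach high R2Y and why the published
  permutation intercepts sit around 0.2-0.4. Without it (independent
  background features) the permutation gate rejects everything; with
  solvent-dominated background every feature becomes an activity proxy.
* **Activity.** On the 1/IC50 scale: the standardized planted responses
  (equal weights, negatives subtracted), standardized, times
  `effectSize = 1`, plus Gaussian noise (`noiseSd = 0.5`), shifted
  positive by five total standard deviations; IC50 is the reciprocal.
  This calibration places the planted feature-target correlations in
  roughly 0.5-0.85, the range of the reference correlation table. The
  DPPH activity reuses the same planted chemistry with per-compound
  random potency weights (an assay weights compounds differently), giving
  a strong but non-collinear AGI-DPPH association.

What it does **not** emulate: retention time, adducts and isotopes,
missing-value structure from gap filling, heteroscedastic technical
noise, or any nonlinearity between compound amount and assay response. A
green recovery test therefore establishes that the pipeline's logic
recovers a planted linear-signal world of realistic dimension and
covariance — not that it would recover the truth of any particular real
extract.

## Numerical notes and degenerate inputs

* UV scaling uses the n-1 standard deviation; zero-variance features are
  dropped with a warning (the vote depends on feature identity, never on
  column position).
* NIPALS stops early when deflation exhausts variance; requesting more
  components than the matrix rank is an error naming the achievable
  rank. For tiny fixtures with fewer samples than CV folds the fold count
  drops to leave-one-out.
* Permutation refits reuse the original component configuration (no
  re-selection), matching the usual permutation-plot construction.
* The final-feature order is always the sorted variable ID; m/z merging
  and intersection are input-order independent.
* An empty branch (no valid model, or every feature screened out)
  produces an empty consensus with a warning, not an error.

## Limitations

* With n = 30, sampling noise alone produces background features whose
  in-sample correlation to the activity rivals weak true actives; no
  in-sample importance measure can separate those, and the consensus
  design (vote + intersection) is precisely the mitigation.
* CV-ANOVA p-values are conservative (see above); the gate's power comes
  from the permutation intercepts and the R2Y-Q2 gap.
* Compound identity is an external annotation joined by variable ID;
  fragmentation-based identification is out of scope.
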