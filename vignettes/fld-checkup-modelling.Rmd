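---
title: "Modelling fatty liver disease from longitudinal checkup data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fatty liver disease from longitudinal checkup data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fldcast)
```

## The problem

Health-screening centres accumulate long, irregular visit histories: a
subject returns every few months to a few years, each visit recording
hundreds of lab values and questionnaire answers plus an abdominal
ultrasound verdict — fatty liver disease (FLD) or not (NFLD). Two
prediction tasks matter clinically:

* **Current-visit prediction (CVP).** Classify FLD status from the same
  visit's features, so low-risk patients can skip the ultrasound.
* **Next-visit prediction (NVP).** Classify FLD status at the *next*
  visit from the full history, so physicians can intervene before fat
  accumulates. This is the preventive-medicine task, and it is harder:
  visits are irregular, and the strongest naive predictor — "tomorrow
  looks like today" — is already very accurate because FLD status is
  sticky.

`fldcast` implements the full pipeline for both tasks: a synthetic cohort
generator with known ground truth, preprocessing, wrapper feature
selection, a multi-classifier CVP harness, two sequence encodings for NVP,
compact recurrent classifiers, and the baseline comparisons that make an
NVP accuracy number interpretable.

## The synthetic cohort generator

Real screening data of this kind are proprietary, so every stage here is
exercised on simulated cohorts whose structure mirrors what the analyses
assume. The generator (`simulate_cohort()`) emulates:

* irregular monthly visit gaps and a mix of single- and multi-visit
  subjects (counts and gaps are `min + Poisson(mean - min)` truncated at
  `max`, a right-skewed shape with interpretable parameters);
* gender-dependent class balance — default targets are NFLD/FLD
  class-size ratios of 0.66 for males and 2.02 for females, the imbalance
  profile typical of screening populations where male FLD prevalence
  exceeds 50%;
* a small planted set of informative features with realistic units
  (BMI-like, body fat, waist, triglyceride, fasting-glucose analogues)
  among many numeric and questionnaire noise features;
* heavy, feature-specific missingness (two of the default lab noise
  features are >= 90% missing, so the high-missingness drop rule has
  something to do);
* label persistence between consecutive visits.

### The label process

The generative model is a per-subject latent "adiposity" random walk
$z_{it}$ feeding a logistic link

$$\pi_{it} = \operatorname{logit}^{-1}(\alpha_g + \gamma\, z_{it}),$$

with the observed label evolving as a two-state chain built from
$\pi_{it}$ and the persistence target $a$:

$$P(\text{stay FLD}) = 1 - \frac{1-a}{2\pi_{it}}, \qquad
  P(\text{switch to FLD}) = \frac{1-a}{2(1-\pi_{it})}.$$

This construction has two properties the tests rely on. First, the chain
preserves the marginal $\pi_{it}$, so the per-gender intercepts
$\alpha_g$ — calibrated by root-finding against the realized latent draws
— deliver the target class ratios. Second, consecutive labels agree with
probability $a$ *itself*, not $a$ plus a chance-agreement term, so the
persistence baseline's accuracy is directly calibrated by the
`label_persistence` parameter. The price is a constraint: $\pi$ must stay
in $[(1-a)/2,\; 1-(1-a)/2]$, so very low persistence narrows the
achievable prevalence range; $\pi$ is clamped to that interval before the
chain is built.

Informative feature $j$ is
$x = \mu_j + \sigma_j (e_j z + \varepsilon)/\sqrt{e_j^2+1}$ with
$\varepsilon \sim N(0,1)$: the effect size $e_j$ sets the feature–label
correlation through the same latent link, and $e_j = 0$ severs it.

The link slope defaults to $\gamma = 2.5$, a deliberately sharp link. An
ultrasound diagnosis is strongly driven by true adiposity, so label
*switches* should be largely predictable from the feature trajectory;
with a flat link, switches are mostly exogenous noise and no sequence
model could beat the persistence baseline, which would make the NVP
comparison vacuous. At $\gamma = 2.5$ a noticeable fraction of visits sit
near the clamp boundaries, where transitions become nearly deterministic
(an NFLD subject at the upper boundary switches with probability one) —
exactly the kind of feature-predictable event a recurrent model can
learn.

What the generator does **not** emulate: real marginal distributions of
the 400-plus raw screening features, informative missingness (missing
cells are MCAR, consistent with mean/mode imputation being the right
tool), measurement error correlated across features, or calendar effects
such as the 2014 enrolment drop in real screening data. Passing tests on
this cohort therefore demonstrate that the *machinery* is correct and
calibrated, not that any particular real-data accuracy is reproducible.

## Preprocessing

The canonical order is drop → impute → consolidate → normalise:

1. `drop_features()` removes configured useless/redundant columns;
   `drop_high_missing()` eliminates features whose missing fraction is
   `>= 0.9` by default (the comparison is inclusive: a feature exactly 90%
   missing is dropped).
2. `impute_features()` uses the column mean for numeric features and the
   column mode for questionnaire features — the quick, scalable choice.
   Modal ties are resolved to the smallest level, a deterministic rule the
   tests pin down by enumeration. Model-based imputation (MICE-style) is
   out of scope.
3. `consolidate_features()` turns several questionnaire items into one
   numeric feature as a gated weighted product
   (`gate != 0` × $\prod_j w_j x_j$): weekly alcohol grams gated on
   "drinks or not", exercise MET-hours as frequency × duration ×
   intensity. The coefficients are configuration — the mechanism (many
   items → one number) is what downstream stages need.
4. `normalize_features()` applies the z-score $(x - \bar{x})/S$ with
   $\bar{x}, S$ computed **from the designated fitting rows only**; held
   -out rows are transformed with the fitted statistics, never their own.
   Whole-data normalisation is available by leaving `fit_rows` at its
   default. Constant features map to zero with a warning. Running the
   z-score before imputation is rejected by contract.

## Wrapper feature selection

Both selectors wrap a pluggable classifier and evaluation scheme
(`fld_classifier()`, `eval_spec()`; default 1-nearest-neighbour with
leave-one-out evaluation, the classic fast wrapper):

* **One-pass ranking** (`opr_rank()`) scores each feature *alone*, ranks
  by accuracy, takes the top $k$: exactly $F$ evaluations for $F$
  features.
* **Sequential forward selection** (`sfs_select()`) greedily adds the
  accuracy-maximising feature: $\sum_{i=0}^{k-1}(F-i)$ evaluations,
  roughly $k$ times dearer. Every greedy step is re-evaluated in full; the
  test suite checks each step against exhaustive best-addition search.

Ties break by schema order, so results are deterministic. The default
$k = 24$ matches the size of a domain-expert feature panel, against which
selections are compared with `feature_iou()`
($|S_1 \cap S_2| / |S_1 \cup S_2|$) and `feature_coverage()`
($|S_1 \cap S_2| / |S_1|$). The neighbour count for the k-NN wrapper is
not prescribed anywhere; the default is $k_{nn} = 1$ with a knob.

## Current-visit prediction

`train_eval_cvp()` fits any of eight classifiers — k-NN, AdaBoost, SVM,
logistic regression, random forest, Gaussian naive Bayes, and two decision
trees (entropy-split as a C4.5 stand-in, Gini-split CART) — on a training
table and reports confusion counts, accuracy, precision, recall, F1 and
AUROC (FLD positive) on a test table. Hyperparameters are library
defaults under a fixed seed; AdaBoost is an in-package AdaBoost.M1 over
depth-1 trees because no installed package provides it. AUROC uses each
classifier's continuous score; for 1-NN that is the neighbour vote
fraction. No resampling or rebalancing is applied anywhere — training is
on the data as it comes, and `imbalance_factor()` quantifies the
consequence (a majority predictor scores exactly the bigger-class
fraction).

`year_window_sweep()` asks how many years of history to train on: for
every suffix window ending the year before the test year it runs feature
selection *inside the window*, trains, and evaluates on the held-out
year. The test year never enters selection or training. Ties go to the
longest window. `menopause_split()` partitions visits at an age threshold
(age at visit = visit year − birth year; month ignored) and evaluates
independently on each side, the design used to probe hormonal influence;
empty subsets are reported as missing rather than erroring.

## Next-visit prediction

### Sequence encodings

For a history of $N$ visits, `extract_prefix_pairs()` yields the $N-1$
pairs (first $i$ visits → visit $i+1$); single-visit subjects drop out.

**Feature set 1 (fixed interval).** `interpolate_monthly()` resamples a
history onto a monthly grid: numeric features via a shape-preserving
piecewise cubic (monotone Hermite; it never overshoots between monotone
observations — important for clinical values — and degenerates to linear
with two visits), questionnaire features and the label via linear
interpolation rounded to the nearest integer level. Exact halves round
toward the later visit's value, i.e. in the direction of change; this
tie rule is arbitrary but documented and oracle-tested.
`build_fs1_samples()` then slides a 12-step window with stride 1
predicting 12 months past the anchor. Anchors are admissible only while
the target month stays inside the observed series — no training target is
fabricated. When the series is long enough, the first anchor sits at
month 12 so inputs are fully observed; a shorter series still yields one
sample whose input is back-filled by duplicating the earliest month.

**Feature set 2 (variable interval).** `build_fs2_samples()` keeps the
raw visits and prepends two timing inputs per step: months since the
previous visit (0 on the first step) and months from the prefix's last
visit to the prediction point (constant across the sample's steps). A
$d$-feature visit becomes a step of width $d+2$, and the encoding is
lossless for timing: dates and horizon are reconstructible from the two
channels. This avoids interpolation entirely, yields far shorter
sequences, and supports prediction at any future time. The per-visit FLD
label can be appended as an extra channel (`include_label = TRUE`); past
ultrasound outcomes are genuinely known at prediction time, but the
default keeps them out so a model cannot shortcut through pure
persistence.

`split_samples()` partitions samples 70/30 with 10% of the training
portion for validation, stratified by target. By default all samples of a
subject stay in one partition: windowed samples from one history overlap
heavily, and letting them straddle the split leaks near-duplicates into
the test set. Sample-level splitting (exact to ±1 per stratum) is
available via `group_by_subject = FALSE` for pipelines that split
windowed pairs directly.

### Models and baselines

`train_sequence_model()` trains one of five recurrent architectures —
LSTM, bidirectional, two-layer stack, bidirectional stack, and additive
attention pooling — implemented in-package in plain matrix algebra with
analytic backpropagation through time, verified against finite
differences in the test suite. Inputs are standardised per channel with
statistics fitted on the training samples (the timing channels live on a
months scale, the features on a z-score scale; recurrent nets train
poorly on mixed scales). Training minimises mean binary cross-entropy
with Adam on minibatches bucketed by sequence length (no padding), and
the returned model carries the parameters of the epoch with the highest
validation accuracy. Defaults are desk-scale: 16 hidden units, 30
epochs, batch 128, learning rate 0.02; everything is recorded in the
model object and deterministic given the seed. The decision threshold is
fixed at 0.5, ties labelled FLD; no calibration is attempted.

Two baselines anchor the evaluation. `baseline_majority()` always
predicts the larger training class; its accuracy equals that class's
test fraction. `baseline_persistence()` predicts the previous visit's
label; its accuracy is the label-persistence rate of the test pairs, and
on sticky-label data it is strong. `error_reduction()` reports
$(e_b - e_m)/e_b$ with $e = 1 - \text{accuracy}$ — the fraction of the
baseline's error a model removes. The formula is pinned down by an
algebraic consistency check: back-solving the shared baseline from any
one published (accuracy, reduction) pair reproduces the other pairs of
the same cohort to three decimals.

## Numerical choices and degenerate inputs

* Mode ties → smallest level; score ties in selection → schema order;
  interpolation half-ties → direction of change; classification ties at
  score 0.5 → FLD.
* IoU of two empty sets is defined as 1 (warning); coverage of an empty
  expert set is an error; class ratio and imbalance factor report an
  `Inf` sentinel (warning) when a class is absent.
* A feature that defeats its wrapper classifier (e.g. 1-NN with too many
  tied distances after heavy imputation) is scored at chance level with a
  warning rather than failing the whole ranking.
* All randomised operations take explicit seeds and restore the caller's
  RNG stream.

## Problem sizes

The shipped tests and the acceptance script run the full machinery at
desk scale, chosen so the complete suite finishes in minutes on one CPU:
cohorts of 350–2,500 subjects for calibration and recovery checks, 20,000
subjects for class-ratio calibration, and an end-to-end pipeline
(simulate 2,000 subjects → preprocess → one-pass ranking of 24 features →
variable-interval encoding → LSTM, 20 epochs) repeated over five seeds.
At these sizes the recurrent models train in seconds per seed; the
wrapper selection dominated by leave-one-out 1-NN is the slowest stage.

## Known limitations

* The generator's missingness is MCAR and its noise features are
  independent; correlated panels and informative missingness are not
  modelled.
* The in-package recurrent nets are compact reference implementations:
  single-threaded, no dropout or weight decay, no gradient clipping.
  They are adequate for desk-scale cohorts, not for hundreds of
  thousands of windowed samples.
* The C4.5 classifier is approximated by an entropy-criterion CART; true
  C4.5 (gain ratio, pruning rules) differs in detail.
* Real-data accuracies from proprietary screening cohorts are not
  reproducible here and are not targeted; the package's claims are about
  calibration, internal consistency, and orderings (e.g. models beating
  the persistence baseline on feature-predictable cohorts).
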