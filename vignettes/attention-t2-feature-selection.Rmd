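---
title: "Attention-based feature selection with a differentiable Hotelling T² objective"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based feature selection with a differentiable Hotelling T² objective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2select)
```

## Motivation

Small clinical cohorts with class-imbalanced binary outcomes — here the
motivating setting is new-onset persistent left bundle branch block (NOP-LBBB)
after transcatheter aortic valve replacement (TAVR), observed in roughly a
fifth of patients — combine a few hundred observations with dozens of mixed
numeric/binary/categorical candidate predictors drawn from clinical history,
echocardiography, electrocardiography and CT anatomy. Per-feature univariate
tests ignore interactions; an all-features logistic model at such n/p ratios is
unstable and typically finds nothing at the 5% level. `t2select` implements a
middle path: learn a small self-attention encoder over per-feature token
embeddings so that each feature's representation absorbs context from all
others, drive the representations apart between outcome groups with a
differentiable two-sample statistic, and afterwards test each feature's learned
representation with the exact Hotelling T² test.

## Model

Each preprocessed feature value is mapped to a `d_token`-dimensional vector:
numeric (and binary) feature $j$ with value $x$ becomes $x\,w_j + b_j$ with
learned $w_j, b_j \in \mathbb{R}^d$; a categorical feature selects a learned
embedding row. A shared learned CLS vector is prepended, giving $p+1$ tokens
per patient. There are deliberately no positional encodings: features are
nominal, each token carries its identity through its own parameters, and the
encoder is therefore exactly equivariant under permutations of the feature
tokens — a property the test suite checks numerically.

The encoder is a standard pre-norm block (repeatable via `n_layers`):
LayerNorm, multi-head self-attention (`n_heads` heads), residual connection,
LayerNorm, position-wise feed-forward network with expansion factor 4 and ReLU,
residual connection. No dropout is used by default: training is full-batch on
tiny data, and determinism under a fixed seed is part of the package contract.
A final affine head maps the encoded CLS token to one logit per patient.

Training minimizes

$$L_\text{total} = L_\text{cls} + \lambda_1 L_\text{stat} + \lambda_2 R,$$

where $L_\text{cls}$ is the binary cross-entropy of the CLS logit,
$L_\text{stat} = -\tfrac{1}{p}\sum_j T^2_\text{ridge}(j)$ is the negative mean
of per-feature ridge-regularized Hotelling statistics computed between outcome
groups on the encoded token vectors, and $R$ is the mean squared norm of the
input token embeddings. Two points here were genuinely open and are resolved
as package design choices:

* **Which losses the two coefficients weight.** We keep the task loss
  unit-weighted (the usual convention), let $\lambda_1$ weight the statistical
  loss, and let $\lambda_2$ weight an embedding-norm penalty. The penalty
  matters: without it the optimizer can inflate $T^2$ indefinitely by scaling
  representations. Both coefficients are configurable so either reading can be
  reproduced.
* **Which representations are tested.** The per-feature encoded tokens, not a
  pooled representation: the post-training selection is per feature, so the
  statistic that drives training is the same one that is tested afterwards.

For two groups of encoded vectors with sizes $n_0, n_1$, mean difference
$\delta$ and pooled covariance $S$ (denominator $n_0+n_1-2$),

$$T^2_\text{ridge} = \frac{n_0 n_1}{n_0+n_1}\,
  \delta^\top (S + \varepsilon I)^{-1} \delta .$$

Inside the loss $\varepsilon$ defaults to $10^{-3}$, which keeps the inverse
differentiable and well-conditioned; the gradient of the full objective —
through the inverse, the attention block and the tokenizer — is derived
analytically in compiled code and verified against central finite differences
at $10^{-4}$ relative tolerance in the test suite.

Optimization is full-batch Adam. The package defaults are sized for
few-hundred-patient cohorts: `d_token = 32`, one layer, 8 heads,
`lr = 1e-4`, `epochs = 3500`, $\lambda_1 = \lambda_2 = 10^{-5}$. Parameter
initialization is scaled-normal (sd $1/\sqrt{d}$) from the run's seeded
generator; initialization is a free design point, and this choice
keeps early attention weights near-uniform.

## Post-hoc selection

`feature_significance()` encodes the full cohort, splits each feature's token
vectors by outcome, and applies the exact test: $T^2$ with $\varepsilon = 0$,
transformed to $F = \frac{n-d-1}{d\,(n-2)} T^2$ on $(d,\, n-d-1)$ degrees of
freedom. Features with $p < \alpha$ (default 0.05) form the selected ("OURS")
set, ordered by descending $T^2$ with the feature name as deterministic
tie-break. Three documented choices:

* **No multiplicity correction in the headline selection** — the selection
  operates at a per-feature 5% level; Bonferroni and Benjamini–Hochberg
  adjusted columns are always reported alongside for transparency.
* **Selection on the full cohort with the single full-cohort-trained
  selector.** The selector fit has no held-out split (its output is a feature
  set, not a performance claim); the benchmark module, which does make
  performance claims, refits preprocessing per training split.
* **Singular covariances** fall back to a Moore–Penrose pseudo-inverse
  (singular values below $10^{-10}$ of the largest dropped) and the result is
  flagged; `t2_pvalue()` refuses degrees of freedom below 1 and points to the
  permutation fallback `permutation_pvalue()`.

## Preprocessing

Schema-driven: every column is declared (`numeric`, `binary`, `categorical`,
plus its clinical group and domain-knowledge flag) in a YAML/JSON schema.
Categorical labels are validated and integer-encoded `0..K-1` in schema
category order at load time; numeric columns are z-scored with training-split
means and standard deviations (sample sd, denominator $n-1$, matching the
pooled-covariance convention of the statistic); binary columns stay on the
{0,1} scale. Missing values are rejected at load — imputation is a modelling
decision we refuse to make silently. Constant numeric training columns raise a
degenerate-feature error rather than producing infinite z-scores.

## The synthetic cohort generator

The clinical dataset this method targets is not redistributable, so the
generator emulates its shape: `lbbb_cohort_config()` produces 242 patients at a
21% event rate over 69 candidate features (40 numeric, 20 binary, 9
categorical), 26 of which are flagged as the clinically established
(domain-knowledge) set. The total of 69 and the established-set size of 26 are
the counts underlying the selection-vs-knowledge agreement structure the
package carries as a worked example (12/8/14/35). Outcomes are drawn first
(Bernoulli), then features conditionally: informative numeric features get a
standardized mean shift in the event group, informative binary/categorical
features a log-odds shift; numeric features carry compound-symmetric
correlation 0.3 in blocks of 5, loosely mimicking correlated CT anatomy
measures (our choice). A `logistic` mode (features first, outcome from a
calibrated logistic model) is available for benchmark realism.

What the generator does **not** emulate: real marginal distributions
(skewness, heavy tails, mixed units), missingness, site effects, or the true
dependence structure between clinical and imaging variables. Passing tests on
these cohorts therefore demonstrate statistical correctness and calibration of
the machinery, not clinical validity on real data.

## Benchmark harness

`run_benchmark()` evaluates feature sets (ALL / DK / OURS / custom) with seven
conventional classifiers (logistic regression, decision tree, random forest,
SVM, LDA, QDA, gradient boosting) under repeated stratified 70/30 holdout
(five fixed seeds by default) with inner stratified 5-fold grid search on the
training split. The inner selection metric is the positive-class F1 at the 0.5
threshold: at ~21% prevalence, accuracy selects degenerate majority-class
models. Metrics are positive-class (a macro switch would be a one-line change
in `binary_metrics`); means and sds are over the outer repeats, and test
scores are pooled across repeats for ROC/AUC (trapezoidal, equal to the
Mann–Whitney concordance), calibration bins, and the Youden-optimal threshold
(midpoints of sorted unique scores, lowest maximizer on ties). Preprocessing
is fitted inside each training split only — a leakage-guard test asserts that
perturbing held-out rows cannot change any fitted quantity. Models that fail
numerically on a given split (QDA with more features than per-class
observations, for instance) fall back to a flagged prevalence predictor rather
than aborting the benchmark, mirroring how such models degrade in practice.
SVM scores are monotone transforms of the decision margin rather than Platt
probabilities, keeping runs deterministic.

## Agreement analysis

`compare_selection()` scores any selection against the schema's
domain-knowledge set over the candidate universe as a 2×2 confusion matrix, and
`agreement_metrics()` reports accuracy/precision/recall/F1 in percent. The
established set is data (schema flags), never hard-coded. The traditional
comparator `baseline_logistic_selection()` fits one unpenalized all-features
logistic model and selects by Wald p-values; on wide correlated cohorts it is
expected to be flagged unstable and select nothing — reproducing the mechanism
that motivates the learned selector.

## Numerical and reproducibility notes

* All randomness flows through seeded private RNG streams; the pipeline derives
  stage seeds from one global seed by fixed offsets, so an end-to-end run is
  reproducible from a single integer, and a manifest records the config hash.
* The attention softmax uses a range-reduced polynomial exponential (~1e-12
  relative accuracy) for speed; the identical function is used in every
  forward pass, so analytic gradients are exact for the objective actually
  computed.
* LayerNorm has a constant-vector null space; tests that perturb tokens do so
  in a single coordinate for this reason.
* Tie-breaks are deterministic everywhere (selection order by T² then name;
  Youden threshold lowest maximizer; first-best grid row in tuning).

## Problem sizes used by tests and the acceptance script

Simulation studies run at the study shape (n = 242, 69 features) but with a
reduced training configuration (`d_token = 8`, 2 heads, 200 epochs at
`lr = 1e-3`) chosen so that multi-seed studies complete in minutes; the
package defaults remain the full configuration. Calibration of the
per-feature null test is checked on 200 independent null replicates with an
untrained (randomly initialized) selector: per-feature selection rates across
replicates are binomial at the nominal 5% level, while rates pooled across
features within a replicate are over-dispersed because the features share one
outcome split and one encoder — the replicate-level scale is the correct one
for a calibration test. Planted-feature recovery uses 5 informative features
(standardized effects 1.0–1.5) among 69; with these effect sizes the selector
recovers essentially all planted features, and the mean T² of planted features
exceeds that of null features in every seed.

## Limitations

* The selection set on trained cohorts tends to be large: attention mixes a
  strong planted signal into many features' representations, so after training
  many features pass the per-feature test. This mirrors the method's design
  (contextual representations) and is why the agreement analysis against an
  established list, not the raw selection size, is the headline comparison.
* The F-based p-values assume approximate multivariate normality of token
  representations; they are exact under the null for Gaussian tokens and
  asymptotically correct otherwise. The permutation fallback is provided where
  the F degrees of freedom are invalid.
* No imputation, no multi-site harmonization, no image ingestion: inputs are
  tabular, complete, and already harmonized.

## A minimal run

```{r, eval = FALSE}
cfg <- lbbb_cohort_config(seed = 1)
gen <- generate_cohort(cfg)
fit <- train_selector(gen$cohort,
                      selector_hyperparams(d_token = 8, n_heads = 2,
                                           epochs = 200, lr = 1e-3, seed = 1))
pre <- apply_preprocessor(fit$preprocessor, gen$cohort)
sel <- feature_significance(fit, pre, alpha = 0.05)
m <- compare_selection(sel$selected, domain_knowledge_set(gen$schema),
                       schema_names(gen$schema))
agreement_metrics(m)
```
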