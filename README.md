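# t2select

Attention-based feature selection for small clinical tabular cohorts, built
around a differentiable two-sample Hotelling T² objective.

## The problem

Predicting new-onset persistent left bundle branch block (NOP-LBBB) after
transcatheter aortic valve replacement (TAVR) — and, more generally, any rare
binary complication in a cohort of a few hundred patients described by dozens
of mixed clinical/echo/ECG/CT variables — sits in an awkward regime: p is
large relative to n, features interact, the outcome is imbalanced (~21%
prevalence), and a single all-features logistic model is too unstable to find
anything at the 5% level. `t2select` is for biostatisticians and clinical ML
researchers who want a feature-selection method that models interactions but
still ends in a classical significance test.

## The method

Each feature value is mapped to a learned `d`-dimensional token (numeric
feature `j`: `x·w_j + b_j`; categorical: an embedding row); a shared CLS token
is prepended; one pre-norm multi-head self-attention block (with feed-forward
sublayer and residuals, no positional encodings) produces contextually
enriched per-feature representations. Training minimizes

```
L_total = L_cls + λ₁·L_stat + λ₂·R,      L_stat = −(1/p) Σ_j T²_ridge(j)
```

where `L_cls` is binary cross-entropy on the CLS logit,
`T²_ridge(j) = (n₀n₁/n)·δᵀ(S + εI)⁻¹δ` is the ridge-regularized two-sample
Hotelling statistic on feature `j`'s encoded tokens between outcome groups,
and `R` is an embedding-norm penalty. Optimization is full-batch Adam with
hand-derived analytic gradients (validated against finite differences).
After training, each feature's representation is tested with the exact
T² F-transform, `F = (n−d−1)/(d(n−2))·T² ~ F(d, n−d−1)`; features with
`p < 0.05` form the selected ("OURS") set.

Around the core, the package provides: schema-driven cohort I/O and
preprocessing; a synthetic cohort generator with planted effects (the
clinical data the method targets is not redistributable); a repeated-holdout
classifier benchmark (7 conventional models × feature sets, inner 5-fold
tuning, ROC/AUC, calibration, Youden threshold); and agreement scoring of any
selection against a clinically established feature list.

## Worked example

Generate a study-shaped synthetic cohort (242 patients, 21% event rate, 69
mixed-type features of which 26 form the domain-knowledge set and 10 carry
planted effects), train the selector, test features, and score the selection
against the domain-knowledge list:

```r
library(t2select)
gen <- generate_cohort(lbbb_cohort_config(seed = 1))
fit <- train_selector(gen$cohort,
                      selector_hyperparams(d_token = 8, n_heads = 2,
                                           epochs = 200, lr = 1e-3, seed = 1))
pre <- apply_preprocessor(fit$preprocessor, gen$cohort)
sel <- feature_significance(fit, pre, alpha = 0.05)
sel
#> selection_report:  14 of 69 features significant at alpha = 0.05
#>   selected: num_01, num_02, num_21, num_03, cat_03, num_24, bin_01, ...

head(sel$results[order(-sel$results$t2), c("feature", "t2", "p_value", "p_bh")], 4)
#>    feature       t2      p_value         p_bh
#> 1   num_01 42.22928 6.789156e-06 0.0004684518
#> 2   num_02 34.63435 1.008443e-04 0.0034791274
#> 21  num_21 31.06250 3.552289e-04 0.0081702648
#> 3   num_03 28.23100 9.549781e-04 0.0164733723

m <- compare_selection(sel$selected, domain_knowledge_set(gen$schema),
                       schema_names(gen$schema))
round(agreement_metrics(m), 2)
#>  accuracy precision    recall        f1
#>     65.22     57.14     30.77     40.00
```

The top-ranked features are exactly the strongest planted ones (`num_01`,
`num_02`, `num_21`, `num_03` carry the largest standardized shifts in this
cohort), the T² column orders the selection, and the raw/BH-adjusted p-values
are reported side by side. The agreement row reads the selection against the
26-member established list over the 69-candidate universe: precision 57% of
selected features are established, recall 31% of the established list was
recovered. The traditional comparator reproduces its known failure mode on
wide correlated cohorts:

```r
b <- baseline_logistic_selection(gen$cohort)
length(b); attr(b, "flagged")
#> [1] 0
#> [1] TRUE
```

A single unpenalized logistic model selects nothing and is flagged unstable.

The exact test machinery is usable on its own:

```r
t2 <- hotelling_t2(matrix(c(1, 2, 3)), matrix(c(4, 5, 6)))
as.numeric(t2)                      # 13.5 = squared pooled two-sample t
t2_pvalue(as.numeric(t2), 3, 3, 1)  # F = 13.5 on (1, 4), p = 0.0213
```

A command-line front end wrapping the full pipeline
(simulate → train → select → benchmark → compare) is at
`inst/cli/t2select.R`:

```sh
Rscript inst/cli/t2select.R all --out runs/demo --seed 1 --epochs 200
```

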