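# fragbb

Fragment-descriptor neural network models of blood-brain barrier
permeability (LogBB) for organic compounds.

## The problem

Whether a drug crosses the blood-brain barrier decides whether it can
treat the central nervous system — or cause central side effects it was
never meant to have. The standard quantitative endpoint is

```
LogBB = log10(C_brain / C_plasma)
```

the log ratio of total compound concentrations in brain and plasma
(experimental error is about 0.3 log units). `fragbb` is for
computational and medicinal chemists who need LogBB estimates with an
applicability warning attached, and interpretable fragment-level reasons
behind each estimate.

## The method

* **Descriptors**: occurrence counts of substructural fragments — linear
  paths, chordless rings and branch points of up to a configurable number
  of heavy atoms (default 8) — under a three-level atom classification
  (element; + bond pattern/aromaticity; + valence state, hydrogen count,
  charge). Fragments present in four or fewer compounds are removed.
* **Selection**: stepwise descriptor selection against partial least
  squares residuals (univariate F / mutual information and recursive
  feature elimination are also available), run locally inside each
  cross-validation training set.
* **Models**: an ensemble of feed-forward SELU networks (one hidden
  layer, optional alpha dropout) trained under NR x NO x NI repeated
  double cross-validation (default 5 outer x 4 inner folds = 20 members),
  with inner-fold early stopping. Validation statistics come only from
  outer-fold predictions:

  ```
  Q2 = 1 - PRESS / SS        RMSEcv = sqrt(PRESS / N)
  ```

* **Guarded prediction**: member predictions outside [-2.5, 2.5] are
  discarded; more than 50% discarded, or an ensemble spread above 30% of
  the [-2, 2] acceptable range, reports a prediction *failure* instead of
  a number.
* **Interpretation**: analytic input gradients x scaled inputs, averaged
  over the ensemble, give per-fragment contributions that can be
  aggregated across the classification hierarchy.

A synthetic compound generator with planted fragment effects
(`generate_dataset()`) makes the entire workflow testable end to end
without any external data.

## Worked example

```r
library(fragbb)

# synthetic benchmark: 150 compounds, planted fragment effects,
# noise sd 0.2 log units
ds <- generate_dataset(synthetic_spec(n_compounds = 150, noise_sd = 0.2,
                                      seed = 7))

dm <- build_descriptor_matrix(ds$compounds, max_atoms = 6, levels = 1:2)
dm <- filter_rare(dm)          # drop fragments seen in < 5 compounds
dm
#> <descriptor_matrix> 150 compounds x 778 fragments

fit <- run_double_cv(dm, ds$compounds$logbb, dcv = dcv_spec(seed = 3),
                     selection = list(method = "stepwise_pls", k = 30,
                                      score = "f_value"))
fit$cv
#> <cv_result> N = 150, Q2 = 0.750, RMSEcv = 0.300 (PRESS = 13.50, SS = 53.96)
```

Q2 is the cross-validated fraction of endpoint variance explained;
RMSEcv = 0.300 sits at the generator's noise floor (0.2 planted noise
plus model error), i.e. the ensemble has learned essentially all the
learnable signal. Prediction with the applicability guard:

```r
# record the featurization the ensemble expects, then predict
fit$ensemble$featurize <- list(max_atoms = 6, levels = 1:2)
predict_one(fit$ensemble, "CCOC(=O)c1ccccc1")
#> # A tibble: 1 x 6
#>   id               status   mean    sd n_valid failure_reason
#>   <chr>            <chr>   <dbl> <dbl>   <int> <chr>
#> 1 CCOC(=O)c1ccccc1 ok     -0.392 0.261      20 none
```

(`train_logbb_model()` wraps curation, featurization and the double CV
in one call and records the featurization automatically.)

`mean` is the ensemble LogBB estimate (log10 units), `sd` the ensemble
spread (a soft applicability warning), `n_valid` the members that passed
the sanity check. Fragment contributions, ranked most
permeability-lowering to most raising:

```r
contrib <- fragment_contributions(fit$ensemble, ds$compounds)
tidy(contrib)
autoplot(contrib)
```

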