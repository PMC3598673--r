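# hqsar — heuristic best-subset QSAR models of BCRP substrate uptake

`hqsar` builds and validates linear quantitative structure–activity
relationship (QSAR) models of substrate uptake by the three BCRP-482
polymorphs (482R wild type, 482G, 482T). The response is the
percent-of-control uptake rate of the probe substrate Mitoxantrone measured
in the presence of a competing substrate; the predictors are named molecular
descriptors tagged with one of six classes (constitutional, topological,
geometrical, electrostatic, thermodynamic, quantum-chemical).

The package implements, as tested and reusable components:

- **Data handling** — delimited descriptor tables with a JSON sidecar for
  classes and train/test roles; the bundled 25-compound × 3-polymorph
  Mitoxantrone uptake dataset with printed-vs-recomputed consistency flags;
  percent-of-control (`percent_uptake()`) and apparent permeability
  (`apparent_permeability()`, `Papp = (dQ/dt)/(A·D0)`) conversions.
- **Preselection** (`preselect()`) — drop descriptors with missing values,
  drop invariant descriptors, collapse near-duplicates (`|r| > 0.99`),
  computed on training compounds only.
- **Heuristic search** (`heuristic_search()`) — incremental best-subset
  multiple linear regression with a beam, a pairwise-intercorrelation cap
  (`|r| ≤ 0.8` within a model), per-term *t* screens, and a final choice by
  the overall *F* statistic among models passing the leave-one-out
  `Q² ≥ 0.5` acceptability gate. Every fitted model reports
  `X`, `DX`, `t = |X|/DX` per term and `N`, `R²`,
  `s² = RSS/(N−k−1)`, `F`, leave-one-out `Q² = 1 − PRESS/TSS`.
- **Validation** (`external_validation()`, `crossvalidate_scheme()`) —
  per-compound absolute relative error `ARE = |y − ŷ|/|y|` on the held-out
  test set with a 10% pass threshold, a median-split odds-ratio descriptor
  screen, and the two-fold scheme that selects the candidate with the
  lowest mean test ARE.
- **Synthetic benchmark** (`synthetic_spec()`, `generate_qsar_data()`,
  `recovery_experiment()`) — a seeded generator of class-labelled
  descriptor matrices with correlated blocks, planted confounders and a
  sparse linear response, plus a support-recovery harness for the whole
  pipeline.

## Worked example

Generate a synthetic dataset at the default study conditions (18 training +
7 test compounds, 40 descriptors, a planted 4-descriptor model, noise at 5%
of signal SD), run the pipeline, and validate on the test set:

```r
library(hqsar)
dat <- generate_qsar_data(synthetic_spec(seed = 42))
sp  <- split_train_test(dat$matrix)
tr  <- dat$matrix$compounds$role == "training"
pre <- preselect(sp$training, dat$y[tr])
pre
#> <preselect_report> 34 survivors | dropped: 2 incomplete, 2 invariant, 2 duplicate

lad <- heuristic_search(pre$matrix, dat$y[tr])
rank_report(lad)[, 1:6]
#>   size     R2     Q2       F      s2 chosen
#> 1    1 0.7853 0.7431   58.52 997.135  FALSE
#> 2    2 0.9030 0.8697   69.82 480.510  FALSE
#> 3    3 0.9768 0.9614  196.48 123.133  FALSE
#> 4    4 0.9976 0.9950 1336.01  13.870   TRUE
#> 5    5 0.9985 0.9965 1583.09   9.373  FALSE
#> 6    6 0.9946 0.9784  334.79  36.789  FALSE

lad$chosen
#> <qsar_model> N=18  R2=0.9976  F=1336  s2=13.87  Q2=0.9950  (4, RANK)
#>                  name       X      DX       t
#> 0           Intercept 200.053 0.89901 222.527
#> 1 quantum_chemical_01  41.716 0.82928  50.304
#> 2   constitutional_01 -25.012 1.03312  24.210
#> 3      topological_01  13.651 1.12976  12.083
#> 4    electrostatic_01  11.864 1.12463  10.549

external_validation(lad$chosen, sp$test[, pre$survivors], dat$y[!tr])
#> <validation_report> n=7  test R2=0.9960  mean ARE=0.0156  pass 7/7 (<= 10%): PASS
```

The preselection report shows the planted confounders being caught (2
incomplete, 2 invariant, 2 near-duplicate descriptors). The ladder lists
the best model of each size: the size-5 model has a higher `R²` (it always
does — best-per-size `R²` can only grow), but its fifth term does not
survive the selection-adjusted significance gate, so the size-4 model with
the highest `F` is chosen — and its terms are exactly the planted support,
with coefficients close to the true `(40, −25, 15, 10)` and intercept 200.
The validation report gives each test compound's absolute relative error;
all are within the 10% threshold.

The bundled uptake dataset drives the same pipeline via
`run_fixture_demo()`, which also prints the percent-of-control consistency
audit of all 75 printed cells (72 consistent, 3 flagged verbatim).

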