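---
title: "Heuristic best-subset QSAR modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic best-subset QSAR modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hqsar)
```

## The modelling problem

BCRP (ABCG2) is an ATP-binding-cassette efflux transporter whose residue-482
polymorphs — 482R (wild type), 482G and 482T — handle substrates differently.
A practical screening index for how strongly a compound engages BCRP is the
uptake rate of the probe substrate Mitoxantrone measured in the compound's
presence: a competing substrate raises Mitoxantrone accumulation inside the
cell. Responses are normalized as percent-of-control,

$$\mathrm{percent} = \mathrm{round}\left(100 \cdot
  \frac{\text{uptake rate with competitor}}{\text{uptake rate of Mitoxantrone alone}}\right),$$

and the package models them as a linear function of named molecular
descriptors (constitutional, topological, geometrical, electrostatic,
thermodynamic, quantum-chemical):

$$y = \beta_0 + \sum_{j \in S} \beta_j x_j + \varepsilon,$$

where the support $S$ is a small subset of the available descriptors, to be
found by search. For each fitted model the package reports the conventional
QSAR statistics: per-term coefficient $X$, standard error $DX$ and
$t = |X|/DX$; and globally $N$, $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$,
$s^2 = \mathrm{RSS}/(N-k-1)$, $F = (R^2/k)\,/\,((1-R^2)/(N-k-1))$ and the
leave-one-out $Q^2$.

The bundled uptake dataset (`load_uptake_fixture()`) carries 25 experimental
sets per polymorph — the Mitoxantrone control plus 17 training substrates,
and 7 test substrates. Three printed percent cells cannot be recomputed from
their raw rates and polymorph controls (fumitremorginc/482R, caffeine/482T,
epinephrine/482T); these are stored verbatim with an `inconsistent` flag and
are never silently corrected. The raw rates are stored unit-agnostically
because the source table's header and the accompanying text disagree about
units, and only ratios are used downstream. Ketoconazole was measured in
both the training and test blocks; the test replicate gets the id
`ketoconazole_test` so ids stay unique.

## Preselection

Three screens run before any model search, on training compounds only so
the test set can never influence selection:

1. `drop_incomplete()` — descriptors not observed for every training
   compound are removed.
2. `drop_invariant()` — descriptors whose value range (max − min) is at
   most `invariant_tol` (default `1e-12`, absolute) are removed.
3. `collapse_duplicates()` — within any group of descriptors with pairwise
   $|r| > $ `r_dup` (default 0.99), only the member most correlated with
   the response is kept. Ties keep the earlier column.

The two correlation thresholds play different roles: $|r| > 0.99$ marks
near-duplicates, which are collapsed here; $|r| \le 0.8$ (`r_pair`) is the
cap on intercorrelation between descriptors *co-occurring in one model*,
enforced during the search. Both are configurable. An alternative reading —
that descriptors with response correlation below 0.8 should be excluded —
was considered and rejected: at 18 training compounds it would eliminate
nearly every descriptor and make multi-descriptor models impossible.

## The heuristic search

`heuristic_search()` grows models incrementally. Stage 1 fits every single
descriptor and keeps the top `beam_width` (default 50) by $R^2$; stage $k$
extends every kept size-$(k{-}1)$ model by every eligible descriptor
(eligibility = $|r| \le$ `r_pair` with each included descriptor), refits,
discards candidates whose entering term fails the stage $t$ screen, and
keeps the top `beam_width` by $R^2$ again. Within a fixed size, ranking by
$R^2$ and by $F$ are the same ordering, so $R^2$ is used and $F$ is
reported. The search stops at `max_size` (default `"auto"` =
$\lfloor N/3 \rfloor$, the convention that a model should carry fewer
descriptors than a third of the number of compounds; 6 at $N = 18$) or when
no candidate survives. All tie-breaks are deterministic (higher $R^2$, then
earlier descriptor order), so identical inputs give byte-identical ladders.

### Significance gates: why there are two tiers

With `t_min = "auto"` the *stage* screen uses the plain two-sided
$\alpha = 0.05$ critical value with $N-k-1$ df. This mild screen is
deliberate: on the way to a good model, genuinely relevant terms often show
only moderate $t$ (their partners are still missing, so omitted-variable
noise inflates their standard errors), and a stricter stage gate would cut
the path to the true model.

The *final acceptability gate* is different. The best model of size $k$ was
selected as the maximum over every candidate the search examined, so the
$t$ value of its weakest term is a maximum of many correlated test
statistics, not a single draw: judged against the uncorrected critical
value it passes far too often, and any term that passes the stage screen
also *raises* $R^2$, $F$ and $Q^2$ mechanically (at these degrees of
freedom the $t$ threshold numerically coincides with the $F$-increase
threshold), so no goodness-of-fit comparison alone can reject an overfit
extension. The gate therefore Bonferroni-corrects $\alpha = 0.05$ for the
cumulative number of candidate-entry tests examined up to that size ($p$
single models, then $p-j+1$ eligible descriptors at each stage $j \le k$) —
a union bound over every $t$-test the search looked at. A numeric `t_min`
bypasses both tiers and is used as-is.

The chosen model is then, among the per-size best models passing the gate
and the leave-one-out acceptability criterion $Q^2 \ge 0.5$, the one with
the highest overall $F$ (ties: smaller size, then earlier descriptor
order). $F$ rather than $R^2$ is used across sizes because best-per-size
$R^2$ is non-decreasing by construction, so it cannot express a preference
for parsimony; the $F$ statistic — fit per parameter against residual per
degree of freedom — can, and "best by $F$ and $t$" is the selection
convention of heuristic-method QSAR. `choose_by = "R2"` restores the pure
$R^2$ choice for sensitivity analysis; the full ladder is always returned
so any other rule can be applied post hoc.

## Regression internals

Fits use QR decomposition (never explicit normal equations, which square
the condition number); the explicit-inversion formula serves only as an
independent oracle in the tests. Standard errors come from the $R$ factor,
honouring any column pivoting. Rank-deficient designs are an error that
names the collinear columns. A response with zero total variance would make
$R^2$ and $Q^2$ equal $0/0$; both are defined as 0 with a warning so a
degenerate branch cannot propagate NaN through a search. $t$ is reported as
$|X|/DX$ — magnitudes only, with the sign carried by $X$ — matching the
convention of printed QSAR model tables.

Leave-one-out $Q^2$ uses the hat-matrix identity
$\mathrm{PRESS} = \sum_i (e_i/(1-h_{ii}))^2$ from one full fit, and falls
back to $n$ explicit refits when any leverage exceeds $1 - 10^{-8}$, where
the identity becomes numerically unstable. Since $h_{ii} \in [0,1)$,
$\mathrm{PRESS} \ge \mathrm{RSS}$ and $Q^2 \le R^2$ always; the test suite
asserts this on every fitted replicate.

## Validation

External validation scores each held-out compound by the absolute relative
error $\mathrm{ARE} = |y - \hat y| / |y|$, a scale-invariant statistic; a
compound passes at the default threshold 0.10 and a model passes overall
when every compound does. `crossvalidate_scheme()` runs the whole two-fold
scheme: role-based split, descriptor-class categorization, a median-split
odds-ratio screen, then search on the training set with every per-size
candidate scored on the test set; the candidate with the lowest mean test
ARE is the scheme's selection, and its training-set overall-$F$ p-value is
reported as the model-consistency check at $p < 0.05$.

Two pieces of the scheme are reconstructions, because no operational
definition exists in the source material, and both are reports that never
gate the search: the odds ratio dichotomizes descriptor and response at
their medians and applies the Haldane–Anscombe $+0.5$ correction (the
minimal deterministic realization), and the "consistency" p-value is the
overall $F$-test of the selected model. Descriptor randomization, described
in the original protocol as a web-based random number service, is replaced
by a seeded generator recorded in every report: reproducibility over
fidelity to a web service.

## The synthetic generator

`generate_qsar_data()` emulates the statistical structure the analysis
assumes, so every stage is testable without the unpublished descriptor
values: standard-normal descriptor columns with equicorrelation
`block_rho` (default 0.3) within each class and independence across
classes; a sparse linear response; and planted confounders for the
preselection screens (2 near-duplicates at $|r| \approx 0.999$, 2
constants, 2 descriptors with a missing training cell — all outside the
support).

The defaults mirror the study conditions: 18 training and 7 test
compounds; 40 descriptors split 8/6/5/6/5/10 over the six classes; a
4-term support placed on four different classes with coefficients
$(40, -25, 15, 10)$ — one dominant positive term and one negative term,
echoing the magnitude ordering of the published best models without
reusing coefficients that are tied to unprinted descriptor units; intercept
200 on the percent-of-control scale; and `noise_sd = NULL` meaning 5% of
the noiseless-signal standard deviation (about 2.5 on a signal SD of
about 50). The optional `scale_mix` multiplies columns by log-uniform
factors in $[10^{-3}, 10^3]$ to exercise scale equivariance, since real
descriptors mix units wildly.

What the generator does *not* emulate: real descriptor marginals (heavy
tails, discreteness of counts), physically structured cross-class
correlation, and any relationship between descriptor values and actual
chemistry. Passing the recovery benchmark therefore shows that the search
machinery is sound under the assumed model, not that a 4-descriptor model
of real BCRP uptake is correct.

`recovery_experiment()` chains the full pipeline over seeded replicates
(replicate $r$ uses seed `spec$seed + r - 1`) and reports the
exact-support recovery rate, coefficient RMSE over recovered fits, mean
test ARE and the mean $R^2 - Q^2$ gap. At the default conditions the rate
is measured at 0.975–0.985 over independent 200-replicate blocks.

## Problem sizes and budgets

The test suite runs the oracle comparisons at small sizes (12–16 compounds,
3–8 descriptors), the exhaustive-enumeration check on a 12×8 instance with
sizes 1–3, the noise-monotonicity property at 40 replicates per noise
level, and the full recovery benchmark at 200 replicates of the default
18×40 condition — about half a minute in total. These sizes were chosen so
the whole suite is quick enough to run on every change; the recovery rate
is stable to within about one percentage point across seed blocks at 200
replicates.

## Known limitations

- The published model coefficients cannot be reproduced: the descriptor
  values behind them were computed with proprietary quantum-chemistry
  software and are not printed. The package reproduces the method —
  statistics, selection, validation — and checks it on synthetic ground
  truth instead.
- The printed overall $F$ values of the published models are inconsistent
  with the standard formula at their own $N$ and $R^2$ (e.g. $R^2=0.9740$,
  $N=18$, $k=4$ gives $F \approx 122$, not 56.17); the package uses the
  standard formula, and printed $F$ values are not used as references.
- Whether the published $s^2$ uses $N-k-1$ or $N$ in the denominator is
  unstated; $N-k-1$ (the unbiased choice) is used.
- One published summary row is labelled "482C"; it is presumed to mean
  482R and left unrenamed in the fixture metadata.
- At $N = 18$ every statistic is volatile; the search's acceptability gate
  controls the family-wise rate of admitting a spurious term at roughly
  0.05 per run, it does not eliminate it.
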