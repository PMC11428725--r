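---
title: "Factorial and neural modelling of wood-chip extraction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial and neural modelling of wood-chip extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakextract)
```

`oakextract` models how three extraction variables — temperature, ethanol
fraction of the solvent, and extraction time — govern the yield and
antioxidant quality of extracts from Turkey oak wood chips, and finds the
settings that jointly maximize several assay responses. This vignette is
the package's account of the underlying statistics: the models, the
parameters that matter, the numerical choices, and what the validation
machinery does and does not demonstrate.

## The factorial design and factor coding

The experiment is a three-level full factorial: every combination of
temperature (20, 50, 80 °C), ethanol (0, 20, 40 %) and time (3, 6, 24 h),
27 runs in all, each response recorded as the mean of triplicate assays.
Regression is carried out on *coded* factors,

$$c = \frac{x - (\mathrm{low}+\mathrm{high})/2}{(\mathrm{high}-\mathrm{low})/2},$$

which maps the extreme levels to ±1 and makes coefficient magnitudes
directly comparable across factors with different units.

One coding subtlety deserves emphasis. The time axis is *asymmetric*: its
middle level (6 h) is not the midpoint of 3 h and 24 h, so it codes to
$(6-13.5)/10.5 = -5/7 \approx -0.714$, not to 0, and the time column of
the 27-run design has mean $-5/21$ rather than 0. Run sheets
conventionally label the middle level "0", but treating 6 h as coded 0
is *inconsistent with the fitted models*: only midpoint/half-range coding
reproduces the published regression intercepts and every published
prediction (the package's tests verify this). `code_value()` therefore
always uses the transform above, stores coded settings at full floating
precision, and treats level labels as nominal. A consequence worth
knowing: the intercept $b_0$ is not the response grand mean but
$\bar y - b_3 \cdot (-5/21)$, an identity asserted in the test suite on
every fit of the packaged data.

A second data note: the packaged dataset reconciles the source report's
run-level table with its higher-precision model-comparison table (three
cells differ in the last digit); the reconciled values are the ones that
reproduce the published grand means and error metrics exactly.

## The response model and its diagnostics

Each response is fitted by ordinary least squares to the full-interaction
linear model

$$Y = b_0 + b_1X_1 + b_2X_2 + b_3X_3 + b_{12}X_1X_2 + b_{13}X_1X_3 +
  b_{23}X_2X_3 + b_{123}X_1X_2X_3,$$

eight terms, leaving 19 residual degrees of freedom on the 27-run design.
No quadratic terms are included — a three-level factorial could in
principle estimate curvature, but the study's model family is linear with
interactions, and no data transformation is applied. The fit itself is
delegated to R's QR-based `lm()`; the surrounding diagnostics are computed
in the package:

* $R^2 = 1 - SSE/SST$ and $R^2_{adj} = 1 - (1-R^2)\frac{n-1}{n-p}$;
* PRESS by the exact leave-one-out shortcut
  $\sum_i (e_i/(1-h_{ii}))^2$ with $h_{ii}$ the leverages (no refitting
  loop; exact for OLS), and $R^2_{pred} = 1 - \mathrm{PRESS}/SST$;
* adequate precision, the signal-to-noise diagnostic
  $(\max\hat y - \min\hat y)/\sqrt{p\,\mathrm{MSE}/n}$ — the
  response-surface-software convention, which reproduces the published
  values; ratios above 4 indicate a model usable for navigating the
  design space;
* the coefficient of variation $100\,\hat\sigma/\bar y$.

A fit is flagged *inadequate* when $R^2_{pred} \le 0$, i.e. when the model
predicts held-out runs worse than the grand mean. On the packaged data
this happens for condensed tannins (CTC), which is accordingly excluded
from optimization — matching the study's own exclusion.

Predictions at new settings return the standard error of the fitted mean,
$\sqrt{x^\top(X^\top X)^{-1}x\,\mathrm{MSE}}$, and a **new-observation**
95 % prediction interval,
$\hat y \pm t_{0.975,19}\sqrt{\mathrm{MSE}(1 + x^\top(X^\top X)^{-1}x)}$.
The new-observation form (not the mean-response form) is what reproduces
the published interval half-widths. Settings outside the design cube are
permitted but flagged, since the linear model's validity there is
unverifiable.

## Desirability optimization

Multi-response optimization uses the Derringer–Suich larger-is-better
desirability. Each response's prediction is mapped to

$$d = \begin{cases} 0 & y \le L \\ \left(\frac{y-L}{T-L}\right)^w & L < y < T \\ 1 & y \ge T \end{cases}$$

and the composite desirability is the geometric mean
$D = (\prod_i d_i)^{1/m}$, zero as soon as any response is fully
undesirable. The study never states its $L$ and $T$; the package defaults
them to each response's **observed minimum and maximum** with weight 1,
the choice that uniquely reproduces the published composite desirabilities
(0.95 for the three-response optimum, 1.000 for the single-response ones).
$d$ is capped at 1 above $T$: a model extrapolating past the best observed
response is credited fully, not infinitely.

The optimizer is deliberately boring: composite desirability is evaluated
on an 11-per-axis grid of the coded cube (1331 points for three factors),
the best 20 grid points seed Nelder–Mead refinements with coordinates
clamped to the cube, and the best refined point wins, with exact ties
broken towards lexicographically smallest coded coordinates. Every step is
deterministic, so the function exposes no random seed — there is nothing
to seed — and repeated calls are bit-identical. The refined optimum is
never allowed to fall below the best grid seed. If desirability is zero
everywhere (infeasible goals), the function warns and returns the first
grid point with $D = 0$.

Two cautions from the study's own geometry. First, time is nearly flat for
the antioxidant responses (its DPPH coefficient is −0.22 on a response
spanning ~324 units), so single-response optima along time are
ridge artefacts: different optimizers will report different interior time
settings with essentially identical desirability. `D` is reported to 4
decimals so such flat directions are visible; the package makes no attempt
to match any particular vendor optimizer's interior coordinates. Second,
the published multi-response settings are printed to 0.1 h, and that
display rounding alone moves predictions by ±0.2 units — tolerances in the
tests account for it.

## The neural model

The network is a feed-forward multilayer perceptron with 3 inputs, one
hidden layer of $H$ units (default 10, searched over 8–12) and 3 outputs,
with the logistic sigmoid as transfer function in *both* layers, as the
study specifies. A sigmoid output forces bounded outputs, so targets are
min–max scaled to $[0.1, 0.9]$ — inside the sigmoid's range, away from
saturation — and inputs to $[-1, 1]$. Scaling is invertible exactly;
predictions are returned in assay units.

Training is Levenberg–Marquardt on the training subset: with $J$ the
backpropagation Jacobian of the outputs with respect to all 73 weights and
biases (for $H = 10$) and $e$ the residual vector, each epoch solves

$$(J^\top J + \mu I)\,\delta = J^\top e,$$

accepting the step and shrinking $\mu$ (×0.1) if the training SSE
improves, otherwise growing $\mu$ (×10) and retrying; $\mu$ starts at
$10^{-3}$, standard defaults of the algorithm's reference implementation.
If $\mu$ overflows its ceiling ($10^{10}$) after at least one accepted
epoch, training simply stops (recorded in the history); an error is raised
only if no step is ever accepted. The Jacobian is exact backpropagation,
verified against central finite differences to $10^{-6}$ in the tests; with
identity activations the trainer provably lands on the least-squares
solution, and the tests confirm agreement with `lm()` fits to $10^{-6}$.

The 27 runs are split 19/4/4 (train/validation/test) uniformly at random
by the training seed — the study's actual membership is unpublished, so
every stochastic claim about the network is made across seeds, never for
one split. Early stopping returns the weights of the epoch with minimum
validation MSE, stopping after `patience = 6` epochs without improvement
(patience 0 stops at the first increase). Performance is summarized by
pooled Pearson correlations between observed and predicted responses per
subset. With 73 parameters against 19 training triples the network is
overparameterized; LM drives the training correlation above 0.95 for the
best of 20 seeds within a few dozen epochs, while validation behaviour
varies strongly with the split — exactly the regime where early stopping
matters.

The study's own trained weights are not published, so its per-run network
predictions cannot be regenerated; they are shipped verbatim as
`oak_model_predictions()` and every published comparison metric is
recomputed from them exactly.

## Model comparison

`model_comparison()` scores factorial and neural predictions per response
by MAE, RMSE and

$$R^2 = 1 - \frac{\sum_i (Y_{pre,i}-Y_{exp,i})^2}{\sum_i (Y_m-Y_{exp,i})^2},$$

with $Y_m$ the mean of the *experimental* values — agreement relative to
the grand-mean predictor, not a regression of predictions on observations,
and therefore negative for models worse than the mean. MAE ≤ RMSE always
(Jensen); both are in assay units.

## The synthetic generator

`simulate_runs()` draws factorial tables from
$y = Xb + q\,(x_1^2 - \overline{x_1^2}) + \varepsilon$ with
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. It emulates exactly the
statistical structure the factorial model assumes — a
linear-plus-interaction surface over the coded cube with homoscedastic
Gaussian noise on *run means* (triplicate-level replication can be
emulated with $\sigma/\sqrt 3$) — plus one controlled violation: a centred
quadratic term in the first factor ($q \ne 0$) placing the truth outside
the model family. Curvature on a single factor is the minimal
nonlinearity needed for the factorial-vs-neural contrast; it is centred so
the intercept stays interpretable. Defaults for validation studies use the
published DPPH surface (coefficients from the fitted equation, noise equal
to its residual standard deviation, 48.41 mg TE/g).

What passing simulation tests do show: the fitter recovers a linear truth
exactly at zero noise; nominal 95 % confidence intervals cover at 0.95
(±0.03 at 2000 replicates); unmodelled curvature degrades predicted R²
and is the regime where the network outperforms the factorial model for
most seeds. What they do not show: anything about heteroscedastic or
correlated assay noise, systematic measurement drift, or behaviour off
the factorial lattice — real assay data can violate all three.

## Problem sizes and determinism

All deterministic analyses run on the 27-run design in milliseconds. The
stochastic validation studies use sizes chosen to hold Monte Carlo error
comfortably below the tolerances asserted: 2000 replicates for CI
coverage (binomial s.e. ≈ 0.005), 100 seeds for the noisy-surface R²
distribution, 20 seeds for best-of-seeds network training, 10 seeds for
the factorial-vs-neural contrast. Every random quantity (splits, weight
initialization, simulated noise) flows from an explicit integer seed via
isolated RNG scopes, so no call disturbs the caller's RNG state and all
results are reproducible bit for bit.

## Interfaces

The package is a set of data-frame-first functions returning tibbles, with
`tidy()`/`glance()`/`augment()`/`autoplot()` methods on every result type;
pipelines are composed in R (or driven by `scripts/acceptance.R` for the
end-to-end reproduction) rather than through a shell executable —
orchestration needs no more than a short script here. CSV is the interchange
format throughout: `read_response_table()` validates external run tables,
and all result tibbles write cleanly with `readr::write_csv()`.

## Known limitations

* The linear-with-interactions family cannot represent curvature;
  three-level designs hint at it (and the synthetic machinery quantifies
  the damage) but the package deliberately offers no second-order model.
* Desirability supports larger-is-better goals only — the only kind the
  study uses; smaller-is-better and target-is-best variants are out of
  scope.
* Correlations and fits operate on run means; replicate-level inference
  (e.g. post-hoc grouping of runs) would need the unpublished raw
  triplicates.
* The network trainer is plain LM with early stopping: no Bayesian
  regularization, no alternative optimizers, CPU only — appropriate at
  27 × 3 scale, not a general deep-learning tool.
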