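---
title: "Discrete-time survival networks: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time survival networks: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plannsurv)
```

## The model

For right-censored data $(t_i, d_i, x_i)$, follow-up is partitioned into
$k$ half-open intervals $I_j = (\tau_{j-1}, \tau_j]$ with $\tau_0 = 0$.
Each training subject becomes one *person-period* row per interval they
were observed in; the binary target of a row is 1 exactly when the event
fell in that row's interval. A feed-forward network with inputs
$(x, \mathbf{1}[I_1], \dots, \mathbf{1}[I_k])$ — the $k$ intervals are
*separate indicator variables*, not a single numeric time input — and a
single sigmoid output node then estimates the discrete conditional hazard

$$h_j(x) = P(T \in I_j \mid T > \tau_{j-1}, x),$$

and survival follows from the product-limit identity
$S(\tau_m \mid x) = \prod_{j \le m} (1 - h_j(x))$, which is monotone
non-increasing by construction. Fitting the network on person-period rows
with (class-weighted) binary cross-entropy maximizes exactly the
discrete-time survival likelihood, because each subject contributes one
Bernoulli factor per interval at risk.

Treating the intervals as indicator inputs has two consequences worth
making explicit. First, the hazard can vary freely across intervals and
interact with covariates through the hidden layer, so no proportionality
of hazards is assumed. Second, time becomes a feature like any other, so
the connection-weight importance partition (below) attributes a share of
importance to each interval, which is a useful diagnostic of how much the
model leans on the time axis.

### Censoring convention in the long format

A subject censored strictly inside interval $m$ was genuinely observed
(for part of) that interval. `to_long_train()` therefore keeps row $m$
with target 0 by default. The alternative — dropping the partially
observed interval — is available via `censored_partial = "drop"`, since
the partial row biases the interval-$m$ hazard slightly downward while
dropping it discards information; at yearly resolution the difference is
small, and both behaviors are tested. Events lying exactly on a boundary
$\tau_j$ belong to interval $j$ (right-closed intervals), and exact zero
times are rejected rather than silently shifted.

## Training: what is fixed and what is tunable

`plann_config()` exposes the knobs that matter:

* `n_hidden_layers` (1 or 2; both hidden layers share `node_size` and the
  activation) and `activation` (`sigmoid`, `relu`, `tanh`) for the
  input–hidden transition(s); the output activation is always sigmoid so
  the output is a probability.
* `learning_rate` and `momentum` — plain SGD with classical momentum
  ($v \leftarrow \mu v - \eta g$, $w \leftarrow w + v$). Defaults 0.2 and
  0.9, values that behave well across the package's synthetic regimes.
* `dropout_rate` — inverted dropout on hidden activations only (inputs are
  never dropped); masks are applied during training and disabled at
  prediction, so no rescaling is needed at inference.
* `event_class_weight` — multiplies the loss of event rows ($y = 1$),
  which are the minority class in person-period data; 1 means unweighted.
* `n_epochs` (default 50) and `batch_size` (default 256, or `"full"`).
  There is no early stopping; the per-epoch loss trace is stored on the
  model so the user can judge convergence.

Numerical choices: weights are initialized uniformly in
$\pm\sqrt{6/(\text{fan-in} + \text{fan-out})}$ (Glorot), a standard choice
for sigmoid/tanh units, with biases at zero; predictions are clipped to
$[10^{-7}, 1 - 10^{-7}]$ *inside the loss only* (the gradient uses the
exact sigmoid–cross-entropy form, which needs no clipping); continuous
covariate columns are standardized with training-set mean/sd (stored on
the model, re-applied at prediction) while 0/1 columns pass through.
Everything downstream of the config seed — initialization, shuffling,
dropout masks — is deterministic, and the test suite asserts bitwise
reproducibility of the loss trace. Analytic gradients are verified against
central finite differences to $10^{-6}$ relative error.

A note on scale: the two reference architectures carry
$(129 + 1)\cdot 85 + 86 = 11136$ and
$(129+1)\cdot 110 + 111\cdot 110 + 111 = 26621$ trainable weights
(`count_weights()`), which is why the 2-hidden-layer variant is the one
prone to unstable importance rankings — many more weights per observed
event.

## Interpretation: connection-weight importance

For one hidden layer, Garson's partition attributes to input $i$ the share
$\sum_j |w_{ij}| |v_j| / \sum_{i'} |w_{i'j}|$, normalized to sum to 1;
biases are excluded, as in standard practice. For two hidden layers the
package chains the per-layer shares:

$$c_{ijl} = \frac{|w_{ij}|}{\sum_{i'} |w_{i'j}|}
            \cdot \frac{|u_{jl}|}{\sum_{j'} |u_{j'l}|} \cdot |v_l|,
  \qquad \text{imp}_i = \textstyle\sum_{j,l} c_{ijl} \;/\; \text{total}.$$

The normalization order (per layer, joint at the end) is a design choice;
its consistency check, asserted in the tests, is the collapse identity: a
pass-through second layer (one node, unit weights) reproduces the
one-layer partition exactly. The partition is sign-blind — it ranks
strength of signal transfer, not direction of effect — and invariant to
rescaling the output weights. Dummy levels are pooled to parent variables
via the dataset's `group_map`, and the $k$ interval indicators pool into a
single `time` entry reported separately, with the per-interval breakdown
kept as an attribute. Ranking ties break alphabetically so reports are
reproducible.

## Evaluation stack

*Discrimination.* Harrell's C-index over comparable pairs
($t_i < t_j$, $d_i = 1$), tied scores counting $1/2$, tied times excluded.
It needs one scalar risk score per subject — the Cox prognostic index
qualifies; a discrete hazard vector does not (subject orderings can cross
between time points), so `compare_models()` deliberately reports no
C-index for the networks.

*Prediction error.* The IPCW Brier score at $t_0$ weights uncensored
residuals by the inverse of the censoring survival $\hat C$, estimated by
reverse Kaplan–Meier (events and censorings swap roles): events before
$t_0$ get weight $1/\hat C(t_i{-})$ — the left limit, so the weight is
predictable — and survivors $1/\hat C(t_0)$; subjects censored before
$t_0$ contribute zero while still counting in the denominator $n$. The
Integrated Brier Score averages the yearly curve over $[0, t_{hor}]$
(default horizon 10 years). The default quadrature is the trapezoid rule
anchored at $\mathrm{Err}(0) = 0$ (no prediction can be wrong at $t = 0$)
divided by $t_{hor}$; `method = "mean"`, the plain average of the curve
values on their grid, is provided as the configurable alternative — the
two differ only in how the first year is weighted, and the package's
tests pin both conventions down separately.

*Calibration.* Subjects are cut into 10 equal-sized groups (sizes within
one) by the deciles of predicted survival at $t$, with ties assigned
stably by subject order, and each group's mean prediction is compared to
its Kaplan–Meier estimate with 95% confidence intervals from the
Greenwood variance under the complementary log-log transform — the
transform keeps the interval inside $[0,1]$ and is the standard choice.

## Cox baselines

The unpenalized fit is maximum partial likelihood with Breslow tie
handling (the tie convention that keeps the partial-likelihood product
literal), with the Breslow step-function baseline at the mean-centered
prognostic index. Backward selection is the numerically stable group-wise
variant: each parent variable's multi-degree-of-freedom Wald statistic
$\beta_g' V_{gg}^{-1} \beta_g$ is computed from the current fit's
covariance (no per-candidate refits), the worst group above
`alpha_stay = 0.05` is dropped whole, and the model refitted. The default
stay level is the conventional 0.05; it is a parameter, not a claim about
any particular dataset.

The LASSO fit minimizes $-\ell(\beta) + \lambda \sum_j |\beta_j|$ by
coordinate descent (glmnet) on internally standardized covariates,
returning coefficients on the original scale; a short Newton refinement
on the fixed active set then drives the stationarity conditions
$\nabla\ell(\hat\beta)_A = \lambda\,\mathrm{sign}(\hat\beta_A)$ to near
machine precision, which the KKT tests verify relative to $\lambda$.
$\lambda$ is chosen on a grid by the cross-validated partial likelihood
in its fold-wise (Verweij–van Houwelingen) form,
$\sum_f [\ell(\hat\beta_{-f}) - \ell_{-f}(\hat\beta_{-f})]$, with folds
stratified by event status and exact ties resolved toward the larger
(sparser) penalty.

## The synthetic cohorts

The generator stands in for a private transplant registry cohort and
emulates its gross structure, not its schema: mixed Bernoulli(0.5) dummy
and standard-normal covariates, administrative censoring at 10 years,
independent exponential censoring, and roughly a 31% event fraction at
the horizon. The default rates (exponential baseline 0.042, censoring
0.078) were fixed once by bisection of the censoring rate against the
30.9% target event fraction at $n = 50000$ (`calibrate_censoring()`
exposes the procedure). Three regimes cover the methods' assumption
space: `ph_linear` (Cox's home turf), `nonlinear` (adds an interaction
and a threshold term to the log-hazard — still closed-form, since it is
PH in transformed features), and `discrete_logistic` (interval hazards
logit-linear in the inputs: the network's well-specified case, with the
event time uniform within its interval so that boundary survival
probabilities are exact).

What passing tests on these cohorts shows — and does not. They establish
correctness of the machinery: likelihood equivalence of the long format,
gradient exactness, recovery of known parameters and hazards, agreement
of every estimator with independent small-sample oracles, and calibration
of the true model within its own Kaplan–Meier bands. They do not show
that a network will beat a Cox model on any real registry: real cohorts
have correlated covariates, informative censoring, measurement error and
far more predictors, none of which the generator emulates.

## Problem sizes used by the test suite

The suite favors a few deep, seeded checks over breadth: exhaustive-pair
concordance at $n = 200$; Cox coefficient recovery at $n = 2000$; network
hazard recovery on ~4800 person-period rows (800 subjects, 10 intervals);
the network-vs-true-model prediction-error gap and decile calibration at
$n = 5000$; toys of 3–8 subjects wherever a hand computation is the
oracle. These sizes were chosen so that stochastic checks have comfortable
margins while the whole suite stays quick to run end to end.

## Known limitations

* Time-dependent covariates are not supported, although the person-period
  format extends to them naturally; the expansion currently repeats the
  baseline covariate vector.
* The C-index is intentionally absent for networks; comparisons across
  model families should lean on the IBS and calibration.
* The two-hidden-layer importance partition is *a* consistent extension
  (the collapse identity pins it down), not a canonical one; rankings
  from heavily over-parameterized 2-layer networks should be treated with
  the same caution as any unstable importance measure.
* Random survival forests are not implemented; the evaluation stack is
  model-agnostic (`evaluate_model()` takes any survival matrix), so an
  external implementation can be compared through that interface.
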