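---
title: "Descriptor selection by genetic algorithms and learning automata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor selection by genetic algorithms and learning automata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarfs)
```

## The problem

A QSAR (quantitative structure–activity relationship) model predicts a
biological activity — here pIC50, the negative log of the half-maximal
inhibitory concentration — from numeric molecular descriptors. Descriptor
generators emit hundreds of columns for a few dozen compounds, so a model
fitted on everything is hopelessly overdetermined. Wrapper feature selection
searches for a small descriptor subset whose *refitted* model predicts well;
the subset size is fixed at 20 % of the training-set size
(`feature_budget()`), which keeps the conventional 5:1 ratio of samples to
fitted parameters.

The search objective is the training RMSE of a multiple linear regression
(MLR) refit on the candidate subset,

$$F = \sqrt{\tfrac{1}{M}\sum_{i=1}^{M}\bigl(y_i - \hat y_i\bigr)^2},$$

minimized over all subsets of exactly $k$ descriptors. This is an NP-hard
subset-selection problem; the package provides four seeded stochastic
searches over it.

## The four selectors

**GA** (`run_ga()`). Chromosomes are binary gene vectors with exactly $k$
ones. Each elitist generation applies binary-tournament selection,
single-point crossover (uniform random cut), order-based mutation (swap two
random gene values — weight preserving), and a budget repair that randomly
adds/removes genes until the weight is exactly $k$ again.

**LA** (`run_la()`). Each candidate subset is an object-migration
(Tsetlin-style) automaton: every gene is an *action* carrying a value bit
and a memory depth in $1..N$ (default $N = 3$). Depth 1 is the *frontier*;
deeper states encode confidence. Per epoch one action per automaton is
probed: the fitness of the current subset ($S_1$) is compared with the
fitness of a trial in which the probed action is flipped ($S_2$). If
$S_1 \le S_2$ the action is *rewarded* (moves one state inward, saturating
at $N$); otherwise it is *penalized* — an internal action retreats one
state, a frontier action has its value flipped. The environment is a
P-model with a deterministic binary signal ($\beta = 0$ reward, $1$
penalty).

**SGALA** (`run_sgala()`). GA phase (default 60 generations) whose final
population seeds the LA phase (default 40 epochs, depths reset to the
frontier, since chromosomes carry no confidence state).

**MGALA** (`run_mgala()`). The automata update is embedded *inside* every
GA generation: the population consists of automata throughout, GA operators
act on whole action states (crossover and mutation carry depths along;
repair resets the depth of any gene it changes), and each generation ends
with one probe/reward/penalize pass over every individual. Generation and
epoch counters coincide.

## Numerical and design choices

* **Budget-preserving flips.** A frontier penalty flips a value bit, which
  would change the subset size — yet every reported subset has exactly $k$
  members. The package therefore pairs each flip with a *compensating*
  flip of one opposite-valued action, chosen uniformly among frontier
  (depth 1) actions, falling back to minimum depth; both actions reset to
  depth 1. The probe's trial uses the same compensation, so $S_2$ is
  always measured on a feasible weight-$k$ subset — comparing subsets of
  different sizes would bias toward larger ones, because OLS RMSE is
  monotone non-increasing in added columns.
* **Probe side effects.** Probing never mutates the automaton; only
  reward/penalize transitions do. When a frontier-flip penalty fires, the
  adopted state *is* the probed trial (strictly better RMSE), so an LA
  update never worsens an automaton's fitness and cached fitness values
  stay exact.
* **Selection scheme.** Binary tournament, chosen because it is scale-free
  for an error-minimizing fitness (roulette wheel would need an inversion).
  Elitism of one preserves the best individual, making best-so-far curves
  monotone.
* **Rates.** Crossover 0.7 is the probability a selected parent pair
  recombines; mutation 0.3 the probability a child undergoes one swap.
* **Degenerate designs.** Subsets that are transiently rank-deficient
  (e.g. two near-duplicate descriptors) are fitted by the minimum-norm
  least-squares solution instead of erroring out of the search.
* **Fitness mode.** The optimizers default to the same-set training RMSE;
  leave-one-out RMSE (`evaluate_subset(..., mode = "loocv_rmse")`,
  computed exactly via the hat-matrix identity $e_{loo} = e/(1-h)$) is a
  configuration option for users who want the selection criterion itself
  cross-validated.

## Preprocessing and splitting

Constant descriptor columns are dropped; then descriptor pairs with
$|r| > 0.80$ (strict, Pearson) are reduced to one member, scanning columns
left-to-right and keeping the first of each offending pair — deterministic
and order-reproducible. The train/test split ranks compounds by activity
and assigns every $m$-th ($m = \mathrm{round}(1/f)$, offset
$\lceil m/2 \rceil$) to the test set, so both sets span the activity range;
the method is conventionally called Y-ranking and its unspecified starting
offset is fixed at the centered value here. 55 compounds at $f = 0.2$ give
the canonical 44/11 split.

## Downstream modelling and validation

The selected subset feeds a least-squares SVR with RBF kernel
$K(x, x') = \exp(-\lVert x-x'\rVert^2/\sigma^2)$ (the exponent convention of
the LS-SVMlab toolbox). Training solves one linear system
$[[0, \mathbf{1}^\top], [\mathbf{1}, K + I/\gamma]]\,[b;\alpha] = [0;y]$;
$\gamma$ (regularization) and $\sigma^2$ (kernel width) come from a grid
search minimizing exact leave-one-out RMSE (closed form via the bordered
inverse, verified against per-fold refits in the tests). Default grids span
$\gamma \in 10^{0..4}$, $\sigma^2 \in 10^{-1..4}$, wide enough to bracket
reported QSAR fits. Ties break toward smaller $\gamma$, then smaller
$\sigma^2$ (less flexibility on equal evidence).

External predictivity is scored by the Golbraikh–Tropsha/Roy criteria
(`tropsha_roy_stats()`): $Q^2 > 0.5$ (leave-one-out, $1 - PRESS/SS$, on the
training set — its standard definition, even though summary tables often
list it among external statistics), $r_p^2 > 0.6$, through-origin
determination coefficients and slopes $k, k'$, and $r_m^2 = r_p^2(1 -
\sqrt{r_p^2 - r_0^2})$ with a clamped-and-flagged radicand when
$r_0^2 > r_p^2$. The through-origin $r_0^2$ uses the regressand's own mean
in the denominator, which makes swapping observed/predicted exactly swap
the primed and unprimed statistics.

The applicability domain (`applicability_domain()`) uses leverages
$h_i = x_i (X^\top X)^{-1} x_i^\top$ over the $p$ selected descriptors
(no intercept column — $p$ counts descriptors, matching $p = 8$ for a
44-compound training set and $h^* = 3p/n = 0.54$), standardized residuals
scaled by the training residual SD, and the Williams-plot box
$|r_{std}| \le 3$, $h \le h^*$.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_table()` produces standard-normal descriptors with a
planted linear signal on a known subset ($y = b_0 + X_S\beta +
\varepsilon$), optional constant columns, and near-duplicate pairs
(population $r \approx 0.99$, enforced $\ge 0.95$) at known indices; the
intercept defaults to 6.68 so activities sit in a realistic pIC50 window
(≈ 4.7–8.5). That gives every selector and cleaner a checkable ground
truth: the planted subset is the exhaustive-search optimum when noise is
zero, and remains so with mild noise at the fixture scales (verified by
enumeration under the frozen fixture seeds).

It does **not** imitate real descriptor matrices: genuine Dragon-style
blocks are heavy-tailed, discretized, and collinear in structured ways, and
real activity is not exactly linear in any descriptor subset. A green test
therefore establishes that the search machinery finds planted optima and
preserves its invariants — not that any particular chemistry dataset will
yield a predictive model.

Benchmark-shape fixtures are deliberately reduced (55×40, 79×48, 45×24
instead of 55×221, 79×320, 45×115) so exhaustive enumeration of all
$\binom{p}{3}$ subsets stays cheap enough to use as an oracle in the test
suite.

## Known limitations

* One probe per automaton per epoch, sampled with replacement — actions
  can go unprobed for long stretches at large $n$.
* The convergence-rate ordering of the hybrids is a statistical property
  over paired seeds, not a per-seed guarantee; at easy (quickly converged)
  instances the final-RMSE comparison degenerates to ties.
* No regularized or weighted regression in the fitness; no
  variable-structure (probability-updating) automata; PSO/ACO baselines
  are out of scope.
* Wall-clock timings are recorded in results but never asserted on — they
  are hardware-bound.
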