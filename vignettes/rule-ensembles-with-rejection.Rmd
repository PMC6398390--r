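---
title: "Sparse interval-rule ensembles with a reject option: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse interval-rule ensembles with a reject option: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulereject)
```

## The model

`rulereject` fits binary classifiers of the form

$$ f(x) = \sum_{j} a_j \, h_j(x) + b, $$

where each $h_j$ is a *conjunction rule*: a product of one-dimensional
closed-interval indicators such as
$I(1.0 \le x_3 \le 2.0)\, I(x_5 \ge 0.5)\, I(x_6 \le 0.8)$.
The rule space is built by discretising every feature at its interior
empirical quantiles; every cut $c$ on feature $j$ yields the two items
$x_j \le c$ and $x_j \ge c$, and a rule is any conjunction of up to
`max_rule_order` items (reduced to at most one interval per feature).
Ties at a cut satisfy both directions, matching the closed-interval rule
form. This rule space is finite but combinatorially large; the model is
kept sparse by an L1 penalty on the weights $a_j$.

Compared with a decision tree, which explains a prediction by one long
conjunction, the ensemble explains it as a weighted sum of short rules —
each readable on its own — and the exact score decomposition
$f(x) = b + \sum_{j \,\text{active}} a_j$ is what `explain_subject()` and
the intersection-matrix figure display.

## Training objective and the linear program

Training minimises

$$ \sum_j |a_j| \;+\; C^+ \sum_{y_i = +1} \phi(f(x_i))
   \;+\; C^- \sum_{y_i = -1} \phi(-f(x_i)), $$

with the *double-hinge* surrogate loss of the per-sample margin
$z_i = y_i f(x_i)$:

$$ \phi(z) = \max\!\big(0,\; 1 - z,\; 1 - \tfrac{1-d}{d} z\big),
   \qquad 0 < d \le \tfrac12 . $$

Here $d$ is the cost of abstaining relative to a unit misclassification
cost. At $d = 1/2$ the loss is the ordinary hinge; as $d$ decreases the
negative-margin slope $\tfrac{1-d}{d}$ steepens, punishing confident
mistakes more. The class costs default to inverse class-frequency
balancing, $C^\pm = C\,n / (2 n^\pm)$, leaving one knob `C`.

Because $\phi$ is piecewise linear, the problem is an exact linear
program. Splitting $a_j = a_j^+ - a_j^-$ and introducing slacks
$\xi_i \ge \max(0,\, 1 - z_i,\, 1 - k z_i)$ with $k = (1-d)/d$ gives

$$ \min \sum_j (a_j^+ + a_j^-) + \sum_i C_{y_i}\,\xi_i
   \quad\text{s.t.}\quad
   \xi_i \ge 1 - z_i,\;\; \xi_i \ge 1 - k z_i,\;\; \xi_i, a_j^\pm \ge 0, $$

with $b$ free and unregularised (the usual LP-boosting convention). With
dual multipliers $\alpha_{i,1}, \alpha_{i,2}$ on the two constraints of
sample $i$, the dual constraint of a rule column reads
$|\sum_i y_i u_i h_j(x_i)| \le 1$ with the *effective mining weight*
$u_i = \alpha_{i,1} + k\,\alpha_{i,2}$, alongside
$\sum_i y_i u_i = 0$ (bias) and $\alpha_{i,1} + \alpha_{i,2} \le C_{y_i}$
(so $u_i \le k\, C_{y_i}$). The test suite checks these conditions —
strong duality, dual feasibility, the bias constraint and the box bound —
on random instances, which certifies optimality of the solver
independently of its implementation.

### Column generation

Materialising every rule column is impossible, so fitting starts from the
bias-only LP and alternates two steps:

1. **Master solve.** A dense-tableau primal simplex (in C++) solves the
   restricted LP over the columns generated so far. The tableau persists
   across rounds, so each new column warm-starts from the previous basis
   and re-solves in a handful of pivots. Degenerate pivot runs switch the
   pivoting rule to Bland's rule, which precludes cycling.
2. **Pricing.** A depth-first branch-and-bound search over interval
   itemsets finds the rule maximising the dual violation
   $g(S) = |\sum_{i \in \mathrm{cover}(S)} y_i u_i|$. The prune bound
   $\max(\sum_{w_i > 0} w_i,\, -\sum_{w_i < 0} w_i)$ over the current
   cover dominates $g$ on every superset (covers only shrink), so the
   search is exact — the suite verifies it against exhaustive enumeration.
   Itemsets repeating a (feature, direction) pair already in the branch
   are skipped: their cover is reachable from a smaller itemset.

Fitting stops when the best gain is at most $1 + \varepsilon$
(`pricing_tolerance`, default $10^{-6}$): then no dual constraint is
violated and the restricted optimum is the optimum of the full rule
space. On exhaustively enumerable instances the final objective matches
the full-enumeration LP to $10^{-6}$, which is the package's
global-optimality check.

Two guards bound the loop: `max_iterations` (default 100) caps the number
of generated columns, and a *stall* detector stops after 15 consecutive
rounds in which the objective improved by less than `lp_tolerance`. The
latter matters under dual degeneracy: the dual solution is then not
unique, and pricing can keep returning marginally violated columns that
do not improve the primal. Models record `converged` and `stalled` flags.

## Rejection: calibration and the decision rule

The raw score is mapped to a posterior $\eta(x) = P(y = +1 \mid x)$ by
isotonic regression: out-of-fold scores (default 5 stratified folds,
refitting the ensemble on each complement) are pooled and fitted by
pool-adjacent-violators. Out-of-fold scores are used because training
scores are optimistically biased. Tied scores are pooled first so the map
is a function of the score; the fitted step points are interpolated
piecewise-linearly, extended by constants, and clipped to
$[10^{-6}, 1 - 10^{-6}]$. PAV depends only on score ranks, so any
strictly increasing transform of the scores leaves the map's values
unchanged.

Given $\eta$ and rejection cost $d$, the decision minimising expected
cost is

$$ +1 \text{ if } \eta > 1 - d, \qquad
   -1 \text{ if } \eta < d, \qquad
   \text{reject if } d \le \eta \le 1 - d, $$

with boundaries rejecting. The bands nest: every sample rejected at some
$d$ is rejected at any smaller $d$, and the band collapses to
$\{1/2\}$ at $d = 1/2$.

Empirical operating points are often stated as a *rejection rate* (RR)
rather than a cost. `decide_at_rejection_rate()` rejects the
`round(RR * n)` samples whose posterior is nearest 1/2 (ties by sample
order) — the symmetric-band analogue of the cost rule — which makes the
classified subsets nested along any RR grid, the property
`accuracy_rejection_curve()` relies on. Both knobs are exposed: $d$
shapes the loss at training time, the RR sweep probes the fitted model.

## Two-stage screening costs

`evaluate_policy()` accounts for a triage design with a cheap first assay
for everyone and an expensive second assay only for first-stage rejects:
the two-stage cost is $n\,c_1 + n_{\text{rejected}}\, c_2$, and
single-stage designs are the special case with no referral. Final-stage
rejections count as not correct and are flagged separately.
`compare_policies()` ranks designs by correct count, then cost. Costs are
abstract units; with 47 subjects, unit costs 1 and 10 and 12 referrals,
the cheap-first design costs $47 + 120 = 167$ against $470$ for
expensive-first — the package's worked example.

## The synthetic generator

Real biomarker panels with clinical labels are access-restricted, so
validation runs on synthetic data whose ground truth is known. The
generator draws features iid (uniform or Gaussian) and labels by planted
conjunction rules: clean label $\mathrm{sign}(\sum_k w_k r_k(x) + b_0)$
(sign(0) mapped to $-1$), then iid label flips with probability $\rho$.
The default profile mirrors a plasma biomarker panel's shape — 14
continuous features, 151 subjects, about 64% positives — so class
imbalance is exercised at realistic scale.

What the generator does *not* emulate: correlated analytes (real protein
panels are strongly correlated), heavy-tailed or batch-shifted
concentration distributions, and covariate-dependent label noise.
Passing the recovery tests therefore shows the optimisation and the
pipeline are correct, not that any clinical accuracy transfers.

### The recovery experiment

`recovery_experiment()` is the standard validation run: two planted
order-2 rules, $n = 500$ training and 500 test samples, $\rho = 0.05$,
$B = 8$ bins, five seeds; it reports item-level Jaccard overlap between
planted and fitted rules (planted boundaries snapped to the learner's cut
grid, since discretisation bounds resolution to one bin width) and
held-out AUC. Two design choices are deliberate:

- **Balanced planted classes.** The two rules jointly cover about half
  the samples. With $\rho = 0.05$, the *ideal* model's tie-adjusted AUC
  is about $1 - \rho = 0.95$ under balance but degrades toward 0.9 under
  strong imbalance (ties at the coarse score levels cost half-credit), so
  a balanced design is what makes an AUC benchmark of 0.9 a meaningful
  bar for the fitted model rather than an unreachable one.
- **`C = 10 / n`.** The loss term scales with $n$ while the L1 penalty
  does not; fixing $C \cdot n$ keeps the total misclassification budget
  of the same order as the planted weights, which is the regime where the
  fit returns a handful of rules rather than dozens of small corrections.

## Numerical choices

- Quantile discretisation (`bins` default 10, type-7 quantiles,
  duplicates removed; constant features yield no items). Robust to skewed
  biomarker distributions; a supervised discretisation is out of scope.
- `max_rule_order` default 3; order-3 interactions match the intended
  interpretability scale, and deeper rules rarely survive the L1 penalty.
- `d` default 0.4: mildly rejection-aware training without collapsing to
  the hinge; `d = 0.5` recovers a plain L1 hinge boosting fit.
- Simplex tolerances $10^{-9}$ for pivots and reduced costs;
  `lp_tolerance` ($10^{-6}$) is the user-facing optimality slack.
  Tie-breaks everywhere follow the item catalogue order (feature, then
  LEQ before GEQ, then threshold), so identical inputs give identical
  models; there is no randomised component in the solver.
- Pricing keeps the first strictly best itemset found in DFS order over
  the catalogue, so ties resolve deterministically.
- Degenerate inputs fail fast: single-class labels and all-constant
  feature matrices are unfittable; missing values are rejected at load
  time (imputation is the caller's responsibility).
- Model files are JSON with numbers at 17 significant digits, so a
  reloaded model reproduces scores bitwise.

## Problem sizes used in validation

The suite validates exactness where enumeration is feasible and behaviour
at moderate scale elsewhere: pricing exactness on 200 random instances
($n \le 30$, $p \le 4$, $B = 3$), column-generation optimality on 50
instances ($n \le 25$, $p \le 3$), and the recovery experiment at
$n = 500$ across five seeds. These sizes were chosen so the whole suite
runs in well under an hour on one CPU while still exercising every code
path; the algorithms themselves have no intrinsic limits near these
sizes (the fit at $n = 500$, $p = 14$, $B = 8$ takes seconds).

## Known limitations

- Continuous features only; categorical inputs need prior encoding.
- Binary classification only; no multiclass extension.
- The dense-tableau simplex is sized for cohort-scale data (hundreds to a
  few thousand samples), not for $n \gg 10^4$.
- Two-stage cost policies only; no per-patient variable costs.
- Isotonic calibration needs enough out-of-fold scores to be stable;
  with very small cohorts the posterior map is coarse and the rejection
  band correspondingly blunt.
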