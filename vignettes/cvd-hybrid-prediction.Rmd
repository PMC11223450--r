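---
title: "Hybrid LSTM-QNN heart-disease classification with Aquila feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid LSTM-QNN heart-disease classification with Aquila feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquilaheart)
```

## The problem and the model

Small clinical risk tables — a few hundred patients, a dozen mixed
continuous/ordinal attributes, a binary disease label — are the bread and
butter of cardiovascular risk work (the UCI Cleveland and Statlog heart
tables are the canonical examples, and `read_heart_data()` reads both
dialects natively). The workflow implemented here attacks them in four
stages:

1. **Preprocessing.** Rows with missing values and exact duplicate rows are
   deleted, and multi-level severity labels are binarized at `label > 0`
   (presence/absence). We deliberately delete rather than impute: deletion
   is a testable contract and avoids inventing values in a package whose
   point is the downstream modelling.
2. **Feature extraction.** Each sample's normalized attribute vector is
   summarized by three descriptor families — central tendency (12
   statistics, from the arithmetic mean to the trimean and winsorized
   mean), dispersion (9 statistics, from the IQR to the Gini coefficient
   and the Shannon entropy of a 4-level discretization), and
   qualitative-variation indices (8 indices on the 4-level distribution,
   ModVR to Shannon–Wiener). These are appended to the original attributes
   to form the augmented matrix. Separately, each attribute's **symmetric
   uncertainty** `SU = 2 I(Q;P) / (H(Q) + H(P))` against the class is
   computed as a relevance score.
3. **Feature selection.** A Self-Improved Aquila Optimizer (SIAO) searches
   the unit hypercube over augmented columns; positions binarize at 0.5.
   The wrapper fitness combines the validation error of a quickly trained
   hybrid, a cardinality penalty, and a mean-SU reward
   (weights 0.94 / 0.05 / 0.01).
4. **Classification.** An LSTM (each sample's selected features presented
   as a univariate sequence in fixed column order) and a quantum neural
   network (QNN; a one-hidden-layer network whose units average `n_s`
   shifted sigmoids with learned "quantum intervals") are trained by
   gradient descent; SIAO then fine-tunes the LSTM forget-gate weights on a
   validation fold; the hybrid predicts with the arithmetic mean of the two
   probabilities, ties at the threshold going to the positive class.

### Why row-wise descriptors and column-wise SU

Which axis the descriptor families run over is genuinely open: computed
column-wise they would be constants across samples and useless as
classifier input. We therefore compute CT/dispersion/QV **per sample**
(row-wise), where they act as learned-free nonlinear summaries of a
patient's profile, and SU **per attribute** (column-wise), where it is the
natural relevance filter feeding the selection fitness. This is the only
reading under which every family is simultaneously well defined and
informative, and it is flagged here because the alternative is a silent
way to build a useless pipeline.

## The Self-Improved Aquila Optimizer

The base optimizer cycles a population of `N` candidate solutions through
four eagle-hunting search phases: in the first two thirds of the `T`
iterations a fair coin picks *expanded exploration*
(`X1 = x_best (1 - t/T) + (x_mean - x_best rand)`) or *narrowed
exploration* (`X2 = x_best Levy + x_R + (y - x) rand`, with a Mantegna
Levy flight of stability `K = 1.5`, scale `s = 0.01`, and a spiral term of
cycle number `r1` drawn in `[1, 20]`, angle rate `omega = 0.005`);
afterwards it picks *expanded exploitation*
(`X3 = (x_best - x_mean) alpha - rand + ((ub - lb) c + lb) delta`,
`alpha = delta = 0.1`) or *narrowed exploitation*
(`X4 = QF x_best - g1 x rand - g2 Levy + rand g1`). Acceptance is strictly
greedy against both the individual and the global best, which is what makes
the best-so-far trace non-increasing — an invariant the tests assert on
every run.

The *self-improved* variant changes two things: the random number scaled
into the bounds inside `X3` comes from a logistic chaotic map
(`v' = mu v (1 - v)`, `mu = 4`), and after each `X3` acceptance test an
arithmetic crossover of two random distinct solutions
(`lambda a + (1 - lambda) b` and its mirror, `lambda ~ U(0,1)`) greedily
replaces the parents when fitter. Setting `chaos = FALSE, crossover =
FALSE` in `siao_params()` recovers the baseline optimizer exactly — the
test suite checks that both variants produce identical histories over the
exploration phase under a shared seed.

### Bound handling

Out-of-bounds coordinates are repaired by **uniform resampling inside the
bounds**, not by clamping. The spiral term alone has magnitude at least
`r1 >= 1`; on the unit box used for feature selection, clamping would pin
entire candidates to the box corners, and instrumented runs showed the
search then evaluates *fewer distinct subsets than equal-budget random
search* (random positions binarize to any fixed subset with probability
`2^-C` per draw, which greedy elitism can only improve on if candidates
remain diverse). Uniform resampling preserves the all-positions-in-bounds
invariant, leaves near-optimum behaviour unchanged (small steps are never
repaired), quarters the sphere-benchmark error in our runs, and restores
the planted-subset recovery the wrapper is designed for.

## Classifier details and numerical choices

* **LSTM.** Single layer, hidden size 8 by default (small enough for
  desk-scale tables of 13–44 features), zero initial state, sigmoid
  readout of the final hidden state. Training is full-batch gradient
  descent on mean cross-entropy with analytic backpropagation-through-time
  gradients, verified against central finite differences to `1e-4`
  relative error. Learning rate 0.5 — large, but stable for full-batch
  updates on unit-scaled features; divergence raises an error suggesting a
  lower rate rather than returning garbage.
* **QNN.** Hidden unit `r` computes
  `b_r = (1/n_s) sum_s sigmoid(beta (W_r x - theta_rs))` — with `n_s = 1`
  and `theta = 0` this is exactly a standard sigmoid unit, an equivalence
  the tests check to `1e-12` against an independently coded MLP. Defaults
  `n_hidden = 8`, `n_s = 3`, `beta = 1`. The intervals `theta` are trained
  by gradient descent along with everything else and each row is re-sorted
  ascending after every update so that the multi-level staircase
  interpretation stays valid.
* **Weight tuning.** The workflow singles out the forget-gate weights as
  the tuning target, so `scope = "forget_gate"` is the default
  (with an `all_gates` option). The scoped weights are searched in
  `[-2, 2]`; the first individual of the initial population is the trained
  vector itself, so greedy elitism guarantees the tuned model never scores
  worse than the trained one on the validation fold. The tuning fitness is
  the validation **cross-entropy** — "validation error" made smooth — so
  the no-degradation guarantee is stated in that metric.
* **Hybrid averaging.** Probabilities, not hard labels, are averaged:
  label voting would collapse the hybrid's probability to three values and
  make threshold-sensitive metrics degenerate.
* **Quartiles** use `stats::quantile(type = 7)` (linear interpolation on
  order statistics, the "inclusive" scheme) everywhere — the interquartile
  mean, midhinge, trimean and quartile coefficient of dispersion all
  depend on this single documented convention.
* **Interquartile mean** is implemented in its summation form
  `(2/n) sum` over sorted indices `floor(n/4)+1 .. floor(3n/4)`, which is
  the exact mean of the middle half when `n` is divisible by 4; it sits in
  the central-tendency family, while the dispersion family carries the
  conventional `IQR = P3 - P1`.
* **Discretization** of unit-interval values uses upper-inclusive
  boundaries (`[0, .25] -> 1`, `(.25, .5] -> 2`, `(.5, .75] -> 3`,
  `(.75, 1] -> 4`); printed level tables with overlapping endpoints force
  *some* deterministic tie rule, and this one keeps 0 in level 1.
* **Undefined descriptors** (geometric/harmonic means on nonpositive
  data, CV at zero mean, QCD at `P1 + P3 = 0`, quartile statistics below
  `n = 4`) are `NA` in the per-vector API and encoded as 0 in the
  assembled matrix so classifiers receive complete input.
* **Standard deviation** is the sample SD (divisor `n - 1`), also used by
  the run summaries (`summarize_accuracy()`).
* **Normalization statistics** (per-attribute min/max) are computed on the
  training fold only and reused, with clamping, on held-out data — the
  leakage-free choice is the only defensible one when nothing else is
  specified.

## What the synthetic generator emulates

`generate_heart_data()` produces tables of the UCI-heart shape: 13
attributes, binary labels, three attributes rendered ordinal by quartile
binning (`cp`/`slope`/`thal`-style), plus injected `NA` markers and
verbatim duplicate rows to exercise the preprocessing rules. Informative
attributes are class-conditional Gaussians with means `±effect_size/2`
and unit variance, so the per-attribute standardized effect, the Bayes
error, and the expected SU ordering are all analytically controlled. The
defaults (effect size 1, 2% missing rows, 2% duplicates, balanced
classes) are the package's realistic operating point; the validation
benchmarks use effect size 2 with 5 informative attributes of 13 at
`n = 1000`, and a null generator (`effect_size = 0`) for chance-level and
type-I checks.

What it does **not** emulate: the marginal distributions, attribute
correlations, or missingness mechanisms of real clinical data (UCI
missingness is not at random; real attributes are correlated). Passing the
planted-recovery and chance-level suites therefore demonstrates that the
machinery works — preprocessing counts what it drops, selection finds
signal that is present and ignores signal that is absent, the hybrid
reaches near-Bayes accuracy on controlled separations — not that any
particular accuracy will be attained on a particular hospital's data.

## Problem sizes used by the validation suites

The acceptance-style checks run at deliberately desk-scale sizes chosen
once: sphere benchmark `D = 5, N = 20, T = 300` over 5 seeds;
planted-subset recovery with 8 columns, `N = 20, T = 100`, 5 seeds; the
full pipeline benchmark at `n = 1000` with 5 repeats, wrapper budget
`N = 10, T = 20`, inner evaluator capped at 250 training samples and 10
epochs, final training 120 epochs; null checks at `n = 1000` (accuracy)
and `n = 5000` (SU); the entropy scale law at `n = 1e5`. The inner/outer
epoch split exists because scoring every candidate subset with the fully
trained hybrid would make wrapper selection quadratic in training cost;
the reduced inner budget is a configuration key (`fs$inner_epochs`), not a
hard-wired constant.

## Known limitations and documented discrepancies

* The ten-metric report treats *recall* as the synonym of sensitivity
  that it is, and carries one column for the quantity. Published reports
  in this problem family sometimes print "sensitivity" and "recall" as
  different numbers, or F1 values inconsistent with their own printed
  precision and sensitivity; `classification_metrics()` always returns the
  identity-consistent values (`f1 = 2PR/(P+R)` to machine precision, which
  the oracle tests assert).
* The QV family implements the eight indices with standard closed-form
  definitions on 4-level distributions. Ecology-style diversity indices
  (rarefaction, Fisher's alpha, taxonomic distinctness and the rest of the
  long catalogue) are out of scope: they are undefined or meaningless on
  4-level discretized clinical attributes.
* "Distance standard deviation" is not implemented; no usable definition
  survives in the source material for this family.
* The optimizer is a stochastic metaheuristic: only the elitism invariant
  is deterministic; benchmark assertions are therefore made on medians
  over fixed seed sets.
* LSTM input is a univariate sequence in fixed column order; the forward
  pass is order-sensitive (tested), so column order is part of the model
  specification and is held fixed throughout a run.
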