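---
title: "The scoring card method: model, estimation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scoring card method: model, estimation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmseq)
```

## The model

The scoring card method (SCM) is a linear, fully interpretable binary
classifier for protein sequences. Its only parameters are 400 *propensity
scores* $s_i \in [0, 1000]$, one per ordered dipeptide, plus a decision
threshold. A sequence $P$ of length $L$ is represented by its dipeptide
composition $w$ — the fractions of the 400 ordered adjacent residue pairs,
counted over overlapping windows and normalized by $L - 1$ — and scored by

$$S(P) = \sum_{i=1}^{400} w_i\, s_i .$$

Because $w$ is a probability vector, $S(P)$ is a weighted mean of card
scores and always lies between the smallest and the largest $s_i$; with
scores on $[0, 1000]$ the sequence score shares that scale. $P$ is called
positive iff $S(P)$ is *strictly* greater than the threshold.

The modeling assumption is deliberately minimal: class membership is
detectable from the marginal frequencies of adjacent residue pairs. Nothing
positional, structural or evolutionary enters the model; that is what makes
the card readable and also what bounds its accuracy.

## Estimation

**Initial card.** For each dipeptide the raw propensity is the difference
between its mean composition in the positive and negative training classes,
$d_i = p_i - n_i$. The 400 differences are mapped affinely onto
$[0, 1000]$, so the most enriched pair scores exactly 1000 and the most
depleted exactly 0. The map is invariant to any common positive scaling of
the inputs (fractions vs percentages give the same card). If every $d_i$ is
equal — possible only for degenerate inputs — all scores are set to the
midpoint 500 and a warning is raised.

Class mean compositions average *per-sequence* composition vectors with
equal weight by default, so long sequences do not dominate the card; a
`weighting = "pooled"` option pools windowed pair counts instead
(length-weighted) for sensitivity analysis. Printed reference compositions
derived from pooled residue totals are reproduced by the pooled mode.

**Amino-acid scores.** The score of residue $O$ is the mean of the 40
dipeptide scores $\{s(O,X)\} \cup \{s(X,O)\}$, $X$ ranging over all 20
residues. The homo-dipeptide $(O,O)$ belongs to both lists and therefore
contributes twice; the divisor is 40, not 39. These 20 values are the
quantities correlated with physicochemical property scales in the analysis
layer.

**Refinement.** A real-coded genetic algorithm evolves the 400 scores to
maximize

$$\text{fitness} = w_1 \cdot \mathrm{AUC}_{cv} + w_2 \cdot R,
\qquad w_1 = 0.9,\ w_2 = 0.1,$$

where $\mathrm{AUC}_{cv}$ is the mean AUC of the *fixed* candidate card on
the held-out part of `cv_folds` stratified folds of the training data
(fold assignment fixed per run by the seed), and $R$ is the Pearson
correlation between the candidate's and the initial card's 20 amino-acid
scores. The $R$ term is the method's own regularizer: it anchors the
refined card to the composition-difference estimate and preserves
interpretability.

The original method cites an orthogonal-array-crossover genetic algorithm
but specifies neither population size, generation count nor operator
internals. This package implements a standard, seeded real-coded GA —
size-2 tournament selection, BLX-0.5 blend crossover, per-gene Gaussian
mutation, clipping to the $[0, 1000]$ box, elitism — because the parts of
the procedure that are actually specified (the fitness function, the search
space, the box constraints) are preserved exactly by any such optimizer,
and a simple seeded GA is fully reproducible. The orthogonal-array variant
is an optional extension point, not a requirement of the model.

**Threshold.** Candidate thresholds are the midpoints between adjacent
distinct values of the pooled training scores, plus one candidate below the
minimum and one above the maximum; accuracy is piecewise constant between
observed scores, so these candidates realize every achievable confusion
table. Ties are broken toward the smallest qualifying threshold, which
favors sensitivity. Scores exactly equal to the threshold classify as
negative (the decision rule is strict).

## Tunable parameters

| parameter | default | units / range | notes |
|---|---|---|---|
| `w1`, `w2` | 0.9, 0.1 | sum to 1 | weight of AUC vs interpretability anchor |
| `population_size` | 50 | chromosomes | each a 400-vector of scores |
| `generations` | 100 | — | 0 returns the initial card, threshold refreshed |
| `crossover_rate` | 0.9 | probability | BLX-0.5 blend vs copy of parent 1 |
| `mutation_rate` | 0.05 | per gene | Gaussian perturbation |
| `mutation_sigma` | 50 | score units | also the initial population spread |
| `elitism` | 1 | chromosomes | makes the best-fitness trace non-decreasing |
| `cv_folds` | 10 | folds | stratified, inside the fitness function |
| `auc_mode` | `"cv"` | — | `"resubstitution"` scores the whole training set |

The GA operator settings (crossover and mutation rates, `mutation_sigma`)
are unspecified by the method itself; the defaults here are conventional
real-coded-GA values chosen once — a high crossover rate, a per-gene
mutation rate of a few percent, and a mutation scale of 5% of the score
range — and are exposed rather than hidden.

## Two cross-validation protocols

Two different quantities are both naturally called "10-CV" here, and they
differ enormously:

* **Inside the fitness function**, the candidate card is *not refit per
  fold* — it is a fixed parameter vector evaluated on folds of the very
  training set from which it was (directly or ancestrally) derived. This
  quantity drives the search but is resubstitution-leaky: on label-free
  noise it can approach 1 simply because the initial card memorizes the
  sampled class difference.
* **`cross_validate()`** implements the honest protocol: for each fold the
  *entire* pipeline — class compositions, initial card, GA refinement,
  threshold — is re-derived on the other folds, and the held-out fold is
  scored by a card that has never seen it. All generalization claims in
  this package (and its null-model control) use this protocol.

The null control makes the distinction concrete: on data with identically
distributed classes the honest held-out AUC sits near 0.5, while the
in-fitness AUC of an initial card derived from the full dataset is far
above it. Reports therefore always state which protocol produced them.

## The synthetic generator

`generate_dataset()` draws the negative class from a first-order Markov
chain with uniform initial distribution and uniform transition rows (each
residue has probability 1/20 in every context) and the positive class from
the same chain with a chosen set of ordered pairs $(a, b)$ boosted to
transition probability $1/20 + \delta$ in row $a$, the remaining entries of
that row renormalized. The planted signal therefore lives *exactly* in the
feature space the card measures — adjacent-pair composition — which gives a
clean parameter-recovery surface: `recovery_check()` asks how many planted
pairs reach the initial card's top-20 scores and what the honest
cross-validated accuracy is.

The fixed benchmark configuration is 200+200 sequences of length 200 with
ten planted pairs (one per first-residue row) at $\delta = 0.015$, data
seeds 0–4. Its signal is deliberately subtle: the per-pair composition
difference is $\pi(a)\,\delta \approx 7.5\times10^{-4}$ against a
two-sample estimation noise of $\approx 3.5\times10^{-4}$ per dipeptide
(z ≈ 2 per planted pair), and a likelihood-ratio classifier using the
*true* generator parameters reaches only about AUC 0.66 on these
conditions. Any measured accuracy must be read against that ceiling: the
benchmark exercises the machinery (recovery ranking, fold bookkeeping,
GA reproducibility), not a regime where near-perfect classification is
attainable. The no-signal control ($\delta = 0$) checks the other side —
that the pipeline does not hallucinate accuracy that is not there.

What the generator does *not* emulate: real amino-acid background
frequencies, sequence length distributions of curated protein families,
domain structure, or homology between sequences. Passing the synthetic
tests therefore demonstrates correctness of the estimation machinery, not
biological performance; the analysis layer is instead checked against the
published per-residue reference tables shipped under `inst/extdata/`.

## Numerical choices and degenerate inputs

* All compositions are computed as fractions summing to 1 internally;
  percent is a presentation-layer choice. This keeps $S(P)$ on the card's
  $[0, 1000]$ scale.
* The min–max normalization clamps floating-point overshoot so the box
  invariant (min 0, max 1000) holds exactly; GA genes are clipped to the
  same box after every crossover and mutation.
* AUC is computed by the exact Mann–Whitney rank formulation (ties count
  one half), not trapezoidal integration — it is oracle-checkable by pair
  counting.
* Correlations with zero-variance inputs are reported as missing (`NA`),
  never coerced to 0; `pearson()` errors informatively, and table builders
  exclude such rows from ranking with a warning.
* Non-standard residues (B, J, O, U, X, Z, gaps) are dropped by default
  before composition counting — composition features are defined only over
  the 20 standard letters — with a strict mode that rejects such records.
  Records emptied by sanitization are skipped with a warning.
* Threshold candidates one unit outside the observed score range are
  clamped back into $[0, 1000]$ when stored; the decision rule is
  unaffected.
* Every stochastic component (generator, fold assignment, GA) is a
  deterministic function of its seed; identical seed, configuration and
  data reproduce cards and score tables byte-for-byte.

## Problem sizes used in the checks

The automated checks run the full pipeline at desk scale: the
characterization correlations on the 20-row reference tables; exhaustive
AUC oracle comparisons up to 6+6 scores; the planted-signal benchmark at
its fixed 200+200 × length-200 configuration with 10-fold cross-validation
and per-fold GA refinement over seeds 0–4; and a 100-generation GA run for
the monotonicity property. These sizes were chosen as the smallest
configurations that exercise every code path at the benchmark's stated
conditions.

## Known limitations

* The model sees only adjacent-pair composition; permuting a sequence
  while preserving its dipeptide counts leaves its score unchanged. Signals
  carried by position, gapped pairs or profiles are invisible by design.
* The published headline accuracies for the bioluminescent-protein and
  luciferase/FP tasks depend on the original curated datasets and on an
  optimizer configuration that is not fully specified; they are reference
  points, not quantities this package can recompute. What is reproduced
  instead are the published per-residue characterization correlations and
  the method-level properties above.
* The GA fitness is leaky by construction (see the protocol section);
  model selection based on it alone will overstate accuracy. Use
  `cross_validate()` for any generalization estimate.
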