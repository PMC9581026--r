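---
title: "Differential interactome analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential interactome analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffint)
```

## The model

The differential interactome asks, for every protein–protein interaction
(A, B), whether the *joint* co-expression behaviour of the two encoding
genes differs between two phenotypes. It deliberately works on a coarse,
robust representation:

1. Each gene is discretized per sample into three levels relative to its
   own average expression: −1 (below), 0 (near), +1 (above).
2. An interaction places each sample into one of the nine joint states
   $[\ell_A\,\ell_B]$, $\ell \in \{-1, 0, +1\}$.
3. Per state, occurrence counts $N_0$ (normal, out of $N_N$ samples) and
   $N_1$ (tumor, out of $N_T$) are normalized to frequencies
   $f_0 = N_0/N_N$, $f_1 = N_1/N_T$, which makes unequal cohort sizes
   comparable, and summarized by
   $$q = \frac{N_1/N_T}{N_0/N_N + N_1/N_T},$$
   the estimated probability that the state belongs to the tumor
   phenotype. $q$ is undefined when a state is observed in neither group;
   such states are excluded rather than imputed.
4. A state *supports* a differential call when it is common enough to
   trust ($\max(f_0, f_1) > f_{\min}$) and extreme enough to matter:
   $q > q_{high}$ (activated in tumor) or $q < q_{low}$ (repressed in
   tumor). The interaction inherits the calls of its supporting states.

The approach assumes nothing about the marginal distributions beyond the
per-gene centring, and it detects coordinated shifts that per-gene
differential expression can miss (two genes may each straddle their means
in both phenotypes while their *joint* occupancy of $[1\,1]$ is
phenotype-specific).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `band_width_sd` | 0.5 | half-width of the 0 level, in per-gene sd units |
| `reference` | `"all"` | samples used for the per-gene mean/sd |
| `f_min` | 0.20 | minimum observation frequency in either phenotype |
| `q_low`, `q_high` | 0.10, 0.90 | q bounds for repressed/activated calls |
| `min_edges` | 5 | differential edges a protein needs to become a hub |
| `split_quantile` | 0.5 | prognostic-index cut point for risk groups |

The literal three-level rule ("below the average −1, above +1, otherwise
0") leaves the 0 level unreachable for continuous data: a value is almost
surely not *exactly* the mean. `band_width_sd` makes the 0 level an
explicit tolerance band of ±0.5 gene standard deviations around the mean;
setting it to 0 reproduces the literal rule. The per-gene statistics pool
both phenotypes by default — there is a single average per gene — and
`reference = "normal"` is available when the normal group should define
"baseline" expression.

Frequencies are tested as `max(f0, f1) > f_min`: the state must be common
*in either the normal or tumor phenotype*. All three threshold
comparisons are strict.

Thresholds on q are applied in cross-multiplied integer form
($N_1 N_N (D - P) > P N_0 N_T$ with the threshold taken as the rational
$P/D$, $D = 10^6$), which is exact for any realistic cohort size. The
floating-point quotient $f_1/(f_0+f_1)$ can land one ulp on the wrong
side of the bound right at a boundary such as $f_1 = 9 f_0$, and — worse
— can disagree with its own mirror image under a phenotype-label swap.
Exact arithmetic preserves the structural antisymmetry: swapping the
labels maps every defined q to 1 − q and exchanges the activated and
repressed call sets exactly.

## Module construction and intersection

A differentially interacting protein (DIP) is a protein incident to at
least `min_edges` (default 5) *distinct* differential edges; an edge
called in both directions counts once and carries the annotation
`"both"`. The module is the DIP's star of differential edges, named
`m<HUB>`. No community detection is attempted — the star definition keeps
the hub semantics of the method.

Cross-cohort intersection keeps a hub when it is a hub in both
catalogues and the two modules share interactions; the common module
keeps exactly the shared edge set (not the union). By default an edge
must agree in direction across cohorts to count as shared — an
interaction activated in one cohort and repressed in the other is not a
common signature — with `require_direction_agreement = FALSE` available
since the opposite convention is also defensible. The `min_edges` filter
is applied per cohort *before* intersection, so a common module may
legitimately retain fewer than `min_edges` shared edges.

## Enrichment and drug repositioning

Over-representation uses the inclusive upper tail
$p = P[X \ge k]$, $X \sim \mathrm{Hypergeom}(N, K, n)$ (the standard ORA
convention), with z-scores from the inverse normal CDF at $1 - p$. For
drug repositioning the universe is the set of all genes occurring in the
drug–gene table — the only universe reconstructible from the table itself
— and drugs pass at p < 10⁻³. For pathway ORA the universe is
user-supplied (typically all genes of the expression dataset) with
p < 0.05. Raw p-value cutoffs are the method's convention; a
Benjamini–Hochberg option exists but is off by default, and results
should be read accordingly.

## Prognosis

The prognostic index is the linear predictor of a multivariate Cox fit on
the module genes, $PI = \sum_p \beta_p x_p$ (partial likelihood, Efron
tie handling, no shrinkage or gene pre-filtering). Patients are split at
the median PI (ties to the low-risk group); the quantile is configurable
because median-split is a convention, not a theorem. Group separation is
quantified by the log-rank test and by
$HR = (O_{high}/E_{high})/(O_{low}/E_{low})$ from the log-rank
observed/expected decomposition — an estimator that is attenuated
relative to the Cox partial-likelihood HR for large effects, but is the
one defined directly by the O/E accounting. `standardize = TRUE` rescales
genes to unit variance before fitting, which makes coefficients
comparable across genes and matches the synthetic survival generator's
standardized linear predictor.

## What the synthetic generator emulates — and what it does not

`simulate_expression()` draws i.i.d. log-normal backgrounds per gene
(location uniform in `meanlog_range`, common `sdlog`), a plausible shape
for intensity/FPKM scales. Differential structure is planted as hub
stars: per star and per sample of the enriched phenotype (tumor for
activated edges, normal for repressed edges), with probability
`tumor_rate` the hub *and* all partners are pushed into the high tail of
their distributions, realizing the joint state $[1\,1]$ on every edge of
the star; the other phenotype leaks at `normal_rate`. Pushing manipulates
raw values — never discretized levels — so the discretization stage is
genuinely exercised end to end.

Two generator choices deserve explanation:

* **Push geometry.** Pushed values are drawn at
  `meanlog + push_shift_sd·sdlog` (default +6 gene log-sds) with small
  jitter `push_sdlog` (0.05). When ~40% of all samples carry the signal,
  the pushed cluster dominates the pooled mean and standard deviation;
  the analytical condition for a pushed value to clear the
  $\mu + 0.5\sigma$ threshold is that the cluster be far *and* tight,
  which these defaults satisfy with margin (the fraction of pushed
  samples discretized to +1 exceeds 0.99 at occupancies up to ~0.65).
* **Clean nulls.** Planted genes belong to exactly one star and decoy
  edges connect only unplanted genes. A decoy edge touching a planted
  (hence genuinely differentially expressed) gene would be a
  half-planted signal, polluting false-call accounting.

`simulate_survival()` uses exponential event times with hazard
$h_0 \exp(\sum_p \beta_p \tilde{x}_p)$ on standardized expression;
censoring marks a sample censored with probability `censoring_rate` at a
uniform fraction of its event time, giving the target censoring fraction
in expectation. `simulate_drug_table()` seeds one drug with exactly the
target genes among decoys with random gene sets.

The generator does **not** emulate RNA-seq count noise, batch effects,
probe-level artefacts, correlated background co-expression, or
copy-number confounding. Passing tests therefore demonstrate that the
pipeline recovers the structure it defines under clean two-phenotype
mixtures — not that any particular biological dataset satisfies those
assumptions.

## Numerical and degenerate-input choices

* Per-gene sd uses the sample (n−1) denominator; a constant gene
  (σ = 0) discretizes to 0 everywhere.
* States with $N_0 = N_1 = 0$ have undefined q and never support calls.
* Median-split ties go to the low-risk group; an all-equal PI is an
  error (degenerate split), as is a cohort with zero events.
* Genes with any missing expression value are dropped at read time with
  a warning: the joint-state model needs complete columns, and silent
  imputation would manufacture states.
* Cox non-convergence (including separation warnings from the fitter) is
  surfaced as an error advising a smaller gene list, never as silently
  unstable coefficients.
* Edge canonicalization is lexicographic; joint states are ordered by
  the canonical gene order of their edge.

## Problem sizes used in validation

The shipped validation suite runs at desk scale, chosen to exercise the
statistical properties rather than production volume: oracle recounts on
≤ 10 edges × ≤ 12 samples, label-swap checks on 20 simulated cohorts,
planted-recovery runs at 500 genes × 100 samples × 300 edges over 20
seeds, exhaustive hypergeometric enumeration up to 12-gene universes,
two-group survival simulations with 400 patients over 50 seeds and 200
null replicates, and a full end-to-end closure run at the default
configuration. The same conditions are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

Symbol-level gene identity (no alias resolution); hub-star modules only;
no multiple-testing correction in the default calling and enrichment
paths, matching the method's fixed probability bounds — the q thresholds
are decision bounds on an estimated probability, not p-values; the O/E
hazard ratio is attenuated for strong effects; and cross-cohort
intersection assumes both cohorts were analysed at the same thresholds.
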