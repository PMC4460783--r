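---
title: "Detecting miRNA regulatory activity with a weighted target running sum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA regulatory activity with a weighted target running sum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTRS)
```

## The problem and the model

A miRNA that is active in a tissue destabilizes many of its target mRNAs at
once, but each individual effect is modest. Case–control designs with strong
perturbations (knockdown, overexpression) can see per-gene effects directly;
in observational cohorts of patient tissue they are buried under cell-type
composition, co-regulation and measurement noise. The statistic implemented
here borrows the central idea of gene-set enrichment analysis — detect
*coordinated* shifts of a predefined gene set in a ranked list — and adapts
it to miRNA regulation in two ways: the ranking variable is the Spearman
correlation of each gene with one miRNA's expression across the same
samples, and the set membership is *weighted* by the confidence of the
sequence-based target prediction.

Per miRNA $m$, with measured genes $G = \{g_1,\dots,g_N\}$ ranked into
$G_m$ by decreasing correlation $r_{mj}$, target set $S_m \subset G$ and
weights $s_{mj} \in (0,1]$, the running sum after position $i$ is

$$ P_i \;=\; \sum_{j \le i} \left( w_j\,|r_{mj}|^{\alpha} - b \right),
\qquad w_j = \begin{cases} s_{mj} & g_{mj} \in S_m \\ 0 &
\text{otherwise}\end{cases}, \qquad
b = \frac{1}{N}\sum_{j \in S_m} s_{mj}\,|r_{mj}|^{\alpha}, $$

and the enrichment score $ES(S_m)$ is the signed value of $P$ at its
maximal absolute deviation from zero. Destabilized target sets crowd the
anticorrelated end of the list and give negative scores; sets co-transcribed
with their miRNA give positive scores. Both are treated as evidence of
regulation.

Assumptions worth keeping in mind: the Spearman ranking needs complete
expression vectors (the loaders refuse missing values rather than impute);
monotone but nonlinear miRNA–target relationships are handled for free by
the rank correlation; the method sees *sets*, so a miRNA with very few
measured targets is excluded (default floor: 10) rather than scored
unstably.

## Significance: permutation null and FDR

The null hypothesis is "a target set of this size and weight profile,
placed at random in this ranked list". Each permutation round shuffles the
gene identities along the list while the sorted correlations stay fixed —
equivalently, the weighted memberships are reassigned to uniformly random
rank positions — and the score is recomputed (1000 rounds per miRNA by
default). Sample-label permutation is deliberately *not* offered: it would
break the miRNA–mRNA pairing that the statistic measures.

The empirical p-value refers a positive observation to the positive region
of the null and a negative one to the negative region. Two denominator
conventions exist and they differ materially:

- **`signed`** (the default): the tail count is divided by the number of
  same-signed null scores. Each region is its own test, the null p-value is
  uniform, and the nominal type-I rate is attained (the package's
  calibration tests verify a ~5% rate at the 0.05 level on fully null
  simulations). This is the convention classic GSEA implementations use.
- **`all`**: the tail count is divided by the total number of permutations.
  Because the null mass splits between the two signs, p-values concentrate
  below ~0.5 and the realized null rate at any nominal level roughly
  doubles. The convention is retained (`p_denominator = "all"`) for
  comparability with pipelines that report the literal one-sided
  proportion, but downstream FDR control is only calibrated under
  `signed`.

Raw proportions are reported by default, so a score beyond every
permutation gives $p = 0$ (as seen in published result tables); a
$(k+1)/(n+1)$ correction is available via `smooth = TRUE` for users who
need strictly positive p-values. P-values of exactly zero are no obstacle
to the Benjamini–Hochberg step-up, which is applied jointly across all
analyzed miRNAs (positive and negative scores together); detection uses
adjusted $p < 0.1$ by default.

Each miRNA's permutation stream is seeded by `mirna_perm_seed(master_seed,
mirna_id)`, so results are independent of processing order and of which
other miRNAs are in the run — adding a miRNA never changes another's
p-value, and parallel execution cannot break reproducibility.

## Parameters that matter

| Parameter | Default | Meaning and guidance |
|---|---|---|
| `alpha` | 1 | Exponent on \|correlation\|. 0 reduces to a weighted hit/miss walk; 2 emphasizes strongly correlated targets. 1 keeps contributions linear. |
| `n_perm` | 1000 | Permutation rounds per miRNA; p-value resolution is 1/`n_perm` per region. |
| `fdr_threshold` | 0.1 | Detection cutoff on BH-adjusted p. |
| `min_targets` | 10 | Minimum measured targets; smaller sets give unstable nulls. |
| `baseline` | `"universe"` | Denominator of the average weighted correlation $b$ (see below). |
| `p_denominator` | `"signed"` | Empirical p-value convention (see above). |
| `seed` | 1 | Master seed; everything stochastic derives from it. |

## Numerical and convention choices

**Baseline denominator.** "The average of prediction-confidence-weighted
correlations for the set" is ambiguous between dividing by $|S_m|$ and by
$N$. Dividing by $N$ is the unique choice that makes the walk end exactly
at zero, so positive and negative excursions are symmetric and comparable —
without it, the walk drifts by $(1 - N/|S_m|)\sum s|r|$, a strongly
negative trend that swamps any signal and makes positive scores nearly
impossible. The literal small-set average is kept as
`baseline = "set_size"` for auditing only.

**Weights from context scores.** TargetScan total context scores live in
$[-1, 0]$ with more-negative meaning more-confident; the running sum needs
larger-is-stronger. On that interval $|x| = -x$, so the absolute value and
the sign flip coincide and only one convention needs to exist. Per
(miRNA, gene) pair the longest 3'UTR isoform is used, ties broken by the
most negative score and then the isoform id, making aggregation independent
of input row order.

**Tie handling in the extremum.** With the zero-sum baseline, segments of
the walk before the first target and after the last are exact integer
multiples of $b$, so *exactly opposite* positive and negative extremes
occur structurally (not just on a null set). Ties in $|P_i|$ resolve to the
earliest position, and tie detection uses a relative tolerance of $10^{-9}$
so that floating-point summation order cannot flip the reported sign
between equivalent computation routes.

**Degenerate inputs.** Constant gene rows get correlation 0 with a warning
(they can never enter a leading edge since $|r| = 0$); a constant miRNA
vector is an error; an observed score of exactly 0 gets $p = 1$ and an
empty leading edge. Exact correlation ties rank by gene id in C-locale, so
rankings are platform-independent.

**Leading edge for negative scores.** "Targets before the extremum" is
only meaningful for positive scores; for negative ones the mirror
convention (targets after the extremum, through the end of the list) is
used, as in GSEA.

**Preprocessing order.** For raw miRNA arrays the pipeline applies
filter → asinh+quantile normalization → batch correction → replicate
averaging. Filtering first avoids letting discarded probes shape the
reference distribution; averaging last means batch effects are estimated on
the replicates that actually hybridized in each series. Each step is
opt-in and the order is documented rather than configurable-by-accident:
users needing a different order can call the step functions directly.
Batch correction is additive on the transformed scale with no interaction
terms, preserves each feature's grand mean exactly, and requires at least
two samples per batch (a singleton batch effect is inestimable without
shrinkage, which this package does not do). Outlier samples are removed via
an explicit exclusion list, not by automated PCA screening.

## What the simulator emulates — and what it does not

`generate_planted_dataset()` draws all profiles as standard Gaussians, then
rewrites a fraction of each planted regulator's targets as
$\text{target} = \beta \cdot \text{regulator} + \mathcal{N}(0, \sigma)$.
Because the statistic is rank-based, only the copula matters, and the
linear-Gaussian model is the simplest faithful signal generator: with the
default $\beta = -1, \sigma = 1$ the population Spearman correlation of a
responsive target is $(6/\pi)\arcsin(\rho/2) \approx -0.69$ (where $\rho =
\beta/\sqrt{\beta^2+\sigma^2} = -1/\sqrt 2$) — strong coordinated
destabilization against a backdrop where 40% of "predicted" targets are
false predictions with no response. Defaults: 1000 genes, 30 miRNAs, 50
samples, 50 targets per miRNA, 10 planted regulators, 60% responsive.

The simulator does **not** emulate: count noise or probe-level intensity
distributions (profiles are already "normalized"), batch structure,
inter-gene correlation beyond the planted effects, cell-type mixture, or
competing-endogenous-RNA (sponge) dynamics. Passing tests on simulated data
therefore demonstrate the statistic's correctness and calibration under
exchangeable noise, not robustness to confounded real-world covariance —
the latter is exactly why subtype-restricted analyses are a first-class
option in the pipeline.

## Validation performed by the test suite

The suite validates the score against an independent brute-force prefix-sum
oracle on 500 random instances ($N \le 50$, up to 10 targets,
$\alpha \in \{0.5, 1, 2\}$), checks the zero-sum and reversal-antisymmetry
properties, compares the permutation null with exhaustive enumeration of
all placements for small lists ($N \le 8$, up to 3 targets, 10000 rounds,
chi-square goodness of fit), verifies type-I calibration on 25 null cohorts
of 20 miRNAs each (200 genes, 50 samples, 1000 permutations), and verifies
planted-regulator recovery (all 10 planted found at FDR < 0.1 with realized
false-discovery proportion ≤ 0.2) across 20 replicate seeds of the default
simulation. Hypergeometric tails are checked against exhaustive counting up
to universe size 12, and end-to-end determinism is checked byte-for-byte on
written result tables. These problem sizes keep the full suite under a
minute of single-core time while leaving every statistical check
well-powered.

## Known limitations

- Target predictions are trusted as given; no conservation re-scoring or
  alternative prediction algorithms beyond a generic (miRNA, gene, weight)
  table.
- The permutation null treats genes as exchangeable along the ranked list;
  correlated gene modules can make it anti-conservative in real data.
- FDR is controlled across miRNAs within one run; combining runs (e.g.
  across subtypes) needs the user's own multiplicity strategy.
- Very small target sets (< `min_targets`) are excluded rather than scored.

## Session info

```{r}
sessionInfo()
```
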