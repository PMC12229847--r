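---
title: "Discovering signed metabolic signatures by network random-walk prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering signed metabolic signatures by network random-walk prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabhub)
```

## The problem

Tumor cohorts with expression, methylation and clinical annotations admit a
recurring discovery pattern: quantify each patient's tumor aggressiveness
from a transcriptional program, find the genes of a candidate catalog (here,
metabolic enzymes) whose expression tracks that aggressiveness and predicts
survival, and compress the surviving candidates into a small signed gene
signature by prioritizing hubs of their interaction network. `metabhub`
implements that pattern as a single fitting function,
`discover_signature()`, over exchangeable inputs (expression TSV, clinical
TSV, gene sets in GMT, STRING-style edge lists), plus a synthetic cohort
generator that plants known structure so every stage can be validated
against ground truth.

## The model, stage by stage

**Aggressiveness score.** Every gene row is Z-scored across samples (mean 0,
SD 1 with denominator $n-1$, the usual cohort convention; zero-variance rows
carry no information and are dropped). A patient's epithelial-to-mesenchymal
transition (EMT) score is the *sum* of Z-scores over the EMT program — a sum
rather than a mean, so genes missing from a platform reduce the score; the
coverage is reported instead of silently imputed. Patients are ranked and
split into low / intermediate / high tertiles whose sizes differ by at most
one; remainders go to the lower groups first and score ties are broken by
sample id, so the stratification is deterministic.

**Three-criteria filter.** A catalog gene becomes a differential metabolic
target iff

1. its tertile group means are *strictly* monotone (up or down) and the
   one-way ANOVA across tertiles passes a Benjamini–Hochberg q < 0.05;
2. the early- vs advanced-stage Student's t-test passes BH q < 0.05 with a
   direction concordant with the tertile trend; and
3. the optimal-cutpoint log-rank test on the gene's expression has p < 0.05.

"Consistent pattern across increasing aggressiveness" is operationalized as
strict monotonicity of the three group means plus ANOVA significance; no
quantitative definition is standard, and monotonicity is the weakest reading
that still excludes U-shaped profiles. FDR is applied separately to the
ANOVA and the stage families. Tukey's post hoc comparisons are available
(`tukey_posthoc()`) as a report, not a gate. Stage-direction concordance is
required so that a gene cannot be selected "up" on the tertile axis while
being lower in advanced tumors.

**Optimal cutpoint.** For a per-sample score, `optimal_cutoff()` evaluates
the two-group log-rank statistic at every midpoint between consecutive
distinct sorted values for which both groups keep at least
`floor(min_frac * n)` samples (default `min_frac = 0.1`), and returns the
minimum-p split. This is the classical maximally selected statistic
*without* a selection correction: on a pure-noise score at $n = 300$ the
empirical rejection rate at nominal 0.05 is roughly 0.3–0.5. The package
reports the raw minimum p deliberately — it mirrors how such thresholds are
chosen in practice — and both the test suite and the acceptance script
quantify the inflation so users cannot mistake the per-gene survival p for a
calibrated error rate. The scan is vectorized over cutpoints (one
$O(nT)$ pass per gene, $T$ = number of distinct event times), which is what
makes the per-gene scan over a full catalog affordable. Ties on p are broken
toward the more balanced split, then the smaller cutpoint. The worse-survival
side is the group with the smaller Kaplan–Meier median; when a median is
undefined the sign of observed-minus-expected events decides.

**Network random walk.** The selected targets induce a subgraph of the
interaction network (isolated genes are removed and reported, mirroring how
a connected core emerges from a candidate list). Every node starts with one
unit of energy; each iteration a node keeps half its energy (laziness 0.5)
and distributes the rest equally among its neighbours, until the L1 change
drops below `tol` (default 1e-10). The converged energy is the node's RW
score. Because the update is the lazy random walk, on every connected
component the limit is exactly degree-proportional:
$$e_\infty(v) = |C| \cdot \frac{\deg(v)}{\sum_{u \in C} \deg(u)},$$
which `stationary_walk_scores()` exposes and the tests verify to 1e-8 on
random graphs. The laziness term is required for convergence on bipartite
components and does not change the limit; total energy is conserved at every
iteration to 1e-10. Initial energy is fixed at 1 per node so that the hub
cutoff "RW score ≥ 2" (inclusive) reads as *twice the network-average
energy*; any other uniform initialization would only rescale the scores and
silently change the meaning of the threshold. There is no restart/teleport
term — this is free diffusion, not PageRank. The transition rule itself
(degree-normalized splitting) is this package's definition: equal-energy
initialization and redistribution to equilibrium admit several readings, and
the degree-normalized one is the canonical meaning of a random walk; its
degree-proportional limit is stated openly rather than hidden behind the
iteration.

**Signed signature.** Hubs with an up trend are oncogenic candidates, hubs
with a down trend suppressor candidates (polarity comes from the discovery
trend). The signature score per sample is
$\sum_{g \in \text{up}} z_g - \sum_{g \in \text{down}} z_g$. The signature
is then associated with survival via the optimal-cutpoint log-rank split,
with gene-set enrichment between the low/high signature groups, and — when
methylation is available — with the methylation–expression correlation
classifier.

**GSEA engine.** Genes are ranked by a two-group metric (signal-to-noise by
default, with each group SD floored at $0.2 |\mu|$ to avoid division
blow-ups — the floor is configurable and documented; a pooled-variance t
statistic is the alternative). The enrichment score is the extremum of the
standard weighted Kolmogorov–Smirnov running sum (weight 1, the GSEA
convention). Significance comes from permutations: phenotype permutation by
default (the groups being compared are patient groups), gene-set permutation
for tiny cohorts. The normalized enrichment score divides the observed ES
by the mean |null ES| of matching sign, and the nominal p is two-sided on
|ES| with the $(1 + \#\{\,|ES_{null}| \ge |ES|\,\})/(n_{perm}+1)$ estimator
— a valid permutation p, uniform under the null, which the calibration test
confirms at the 0.05 level. No across-set FDR is attempted.

**Methylation classifier.** Per gene, the Pearson correlation between
methylation score and expression over pairwise-complete samples; genes with
$r < -0.50$ are flagged as candidates for methylation-driven silencing. The
threshold is the conventional "high inverse correlation" cutoff; the sign
convention is explicit: flagging requires a *negative* correlation of
magnitude above 0.50.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code — it defines the study
conditions under which the pipeline's operating characteristics are
measured. A latent aggressiveness axis $L \sim N(0,1)$ per sample drives
everything:

* **EMT program** (200 genes): expression $= 0.8 L + N(0, 1)$ per gene.
* **Planted hubs**: 5 oncogenic genes at $+0.8 L$, 2 suppressors at
  $-0.8 L$ (plus unit noise).
* **Weak co-regulated tier** (40 genes, half up at $+0.6L$, half down):
  the analog of the broader differential-target list that real discovery
  produces. This tier exists because of an arithmetic fact: RW scores
  average 1 over a network, so a network containing *only* hubs can never
  have all its nodes at score ≥ 2 — hub prioritization needs non-hub
  selected genes to stand against, exactly as a real candidate list funnels
  ~100 targets into a handful of hubs.
* **Stage**: advanced above the median of $L$, with 10% label flips so the
  stage comparison is realistically noisy rather than degenerate.
* **Grade**: the same construction at the tertile boundary.
* **Survival**: exponential with hazard $\propto \exp(0.7 L)$ (about a
  two-fold hazard ratio per latent SD — a strongly prognostic axis, as
  aggressiveness axes in real tumor cohorts tend to be) and a baseline
  median of 36 months; independent censoring at an expected 30% rate.
* **Methylation**: suppressor genes at $0.5 + 0.15 L + N(0, 0.05)$, clamped
  to $[0,1]$ — methylation rises as suppressor expression falls, giving a
  population correlation near $-0.6$; all other genes are uncorrelated noise
  around 0.5.
* **Network**: Erdős–Rényi with edge probability 0.01 over the 500-gene
  metabolic catalog, plus 10 edges from each planted hub to distinct
  weak-tier genes (with high interaction scores). In the subgraph induced on
  the selected targets, planted genes hold degree ≈ 10 against a weak-tier
  average of ≈ 2–3, placing them above twice the average energy.

Defaults: 300 samples, 500 catalog genes. Identical configurations produce
identical cohorts (a single seeded RNG stream; the generator restores the
caller's RNG state).

What the generator does *not* emulate: probe-level methylation (the
"methylation score" is generated directly at the gene level, since no
aggregation rule from probes is standard), batch effects, copy-number or
mutation events, correlated noise between genes, and non-proportional
hazards. Passing the recovery tests therefore shows the pipeline correctly
inverts its own generative assumptions — it does not show robustness to the
messiness of real cohorts.

## Numerical choices and degenerate inputs

* Z-scores use the $n-1$ SD; zero-variance rows are dropped with a warning,
  and an all-constant matrix is an error.
* Duplicate gene rows in input files collapse by mean (deterministic and
  symmetric); duplicate undirected edges keep the maximum score (STRING
  exports both orientations); self-loops are dropped; the edge score
  threshold is inclusive.
* `NA` is the missing-value sentinel everywhere; correlations use pairwise
  complete pairs and genes with fewer than 3 pairs are skipped with a
  warning.
* Log-rank handles tied event times with the hypergeometric variance; a
  split with zero variance (no informative event times) yields chi2 = 0,
  p = 1 rather than NaN. Genes admitting no valid cutpoint (constant rows)
  are flagged and skipped by the per-gene scan, not fatal.
* Tertile and cutpoint ties break deterministically (sample-id order;
  more-balanced-then-smaller cutpoint), so reruns are byte-identical.
* The walk's convergence tolerance is an L1 bound on the update change;
  for auditing against the closed form the tests tighten it to 1e-12.

## Problem sizes used by the tests

The test suite and `scripts/acceptance.R` exercise: 20 cohorts of 300
samples × 700 genes for end-to-end recovery (and 10–20 null cohorts), 50
random connected graphs up to 200 nodes for the walk-vs-closed-form audit,
100 random 30-sample instances for the exhaustive cutpoint check, 200
replicates at 200 permutations for GSEA calibration, and a 10,000-draw
permutation null for the log-rank p. These sizes give Monte-Carlo error
comfortably below the margins being asserted while keeping a full run in
the minutes range.

## Known limitations

* The minimum-p cutpoint scan is optimistic (quantified above); survival
  criteria based on it are screening tools, not calibrated tests.
* No multiple-testing correction is applied across genes for the survival
  criterion, matching the screening character of the filter.
* The GSEA engine reports nominal p and NES only; no across-set FDR.
* Validation (`validate_signature()`) never re-derives the signature — it
  scores a fixed gene list on a new cohort, so a failed validation indicates
  the signature, not the pipeline.
* The random-walk limit is degree-proportional within components; with the
  uniform initialization used here, hub selection is equivalent to a degree
  threshold *relative to the component's average degree*. The iterative
  implementation is retained both as the definition and so that non-uniform
  initializations remain possible.
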