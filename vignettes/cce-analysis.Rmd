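---
title: "Detecting and comparing cell–cell interaction events across disease states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing cell-cell interaction events across disease states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cceflow)
```

# The model

Intercellular signalling is read out of single-cell expression data as
*cell–cell interaction events* (CCEs): a ligand–receptor pair evaluated
between an ordered pair of annotated cell types within one condition
("pathological state", e.g. normal bone marrow through overt myeloma). The
partner annotated as the `True` receptor in the pair table defines the
receiving, *regulated* side; the other partner is the ligand on the sending,
*regulatory* side. Self-interactions (source type = target type) are
included, since within-type signalling is biologically meaningful.

## Interaction score and permutation null

For state $s$, source type $a$, target type $b$ and pair $(\ell, r)$ the
observed score is

$$ T = \tfrac{1}{2}\left( \bar{x}_{\ell, a} + \bar{x}_{r, b} \right), $$

where $\bar{x}_{g,c}$ is the mean normalized expression of gene $g$ over the
cells of type $c$ in state $s$, *gated to zero* when at most a fraction
`min_expr_fraction` (default 0.10) of those cells express the gene. Gating
prevents a handful of outlier cells from manufacturing an interaction; it is
the main guard against dropout-driven artefacts and can be disabled by
setting the fraction to 0.

The null distribution shuffles the cell-type labels among **all cells of the
same state** (expression profiles and state membership fixed) and recomputes
$T$ with identical gating. This conditions on the state's type composition
and per-cell expression, and destroys only the association between profile
and type label — the convention of permutation-based interaction tools for
10X-style data. The Monte Carlo p-value uses the add-one estimator

$$ p = \frac{1 + \#\{T^{\text{null}} \ge T\}}{1 + n_{\text{perm}}}, $$

which cannot return 0 and has floor $1/(1+n_{\text{perm}})$. An exhaustive
mode enumerates every distinct label assignment (feasible for tens of cells)
and returns the exact tail proportion; the Monte Carlo mode converges to it.
A zero observed score is assigned $p = 1$ outright: no expressed interaction
means no event. Events with raw $p < \alpha$ (default 0.05) are
*significant*; no multiple-testing correction is applied, because downstream
stages consume the per-state significant-event *counts* and a common raw
threshold keeps those counts comparable across states.

Assumptions worth stating: cells are treated as exchangeable within a state
under the null (no sample-level blocking — a deliberate simplification;
sample effects inflate type-I error if samples differ wildly in composition),
and cell-type labels are taken as given, upstream errors included.

## Dysregulation between states

The event expression is $\mathrm{EXP} = \mathrm{mean}(\bar{x}_r, \bar{x}_\ell)$
and the between-state fold change is

$$ \mathrm{FC} = \frac{\mathrm{EXP}_1 - \mathrm{EXP}_2}
                     {\min(\mathrm{EXP}_1, \mathrm{EXP}_2)}. $$

The event is **up-regulated in State1** when $\mathrm{FC} > 0.25$ *or*
$\mathrm{EXP}_2 = 0$, **down-regulated in State1** when $\mathrm{FC} < -0.25$
*or* $\mathrm{EXP}_1 = 0$, otherwise unchanged. When both expressions are
zero the two zero rules would fire simultaneously; we classify the event
unchanged, since no interaction exists in either state. When exactly one side
is zero the division is undefined and the zero rule subsumes it; the written
fold change is the signed sentinel `+inf`/`-inf`. The threshold 0.25 is
the conventional default and is exposed as a parameter; note this denominator
makes FC symmetric in magnitude (a doubling gives +1, a halving −1), unlike a
ratio.

Which events enter the comparison is genuinely open: reports of dysregulated
events sometimes require significance in both states, sometimes in either.
We expose this as `scope` with default `significant_either`, where a side
that is not significant contributes expression 0 (the event is absent from
that state's significant table). `significant_both` and `all` implement the
alternatives; the default is the most inclusive reading that still restricts
attention to detected events.

## Count enrichment

Whether a cell type (or a directed type pair) gains or loses interaction
events between two states is tested on the 2×2 table
[events involving the focus vs all others] × [state A, state B] with a
two-sided Fisher's exact test (minimum-likelihood two-sided p: the sum of
hypergeometric probabilities of all tables, margins fixed, at most as
probable as observed). Two-sidedness is required because both enrichment and
depletion are of interest. A self-interaction counts once for its type —
counting it twice would double-weight a single event. The sample odds ratio
is reported, with the Haldane–Anscombe $+0.5$ correction applied to all
cells *only when a zero cell exists* so that log2 odds-ratio heatmaps stay
finite; a zero margin yields an undefined odds ratio and $p = 1$.
Significance is flagged at both 0.05 and 0.1, the two levels conventionally
annotated on such heatmaps. No correction across the matrix is applied, for
the same reason as in detection.

## State-specific networks

Ligand/receptor genes of each state's significant events are collected with
their roles; a gene whose presence (union over roles) is confined to exactly
one state is *state-specific* to it — a set-difference reading of "uniquely
identified", the simplest formal rule. Each state's network contains its
ligand/receptor genes plus their direct PPI neighbours within the
ligand/receptor gene universe (first-neighbour closure keeps the networks
interpretable; deeper closures pull in genes with no interaction evidence),
with PPI edges kept at combined score ≥ 0.7 (the standard high-confidence
cut) and, optionally, the state's own ligand–receptor pair edges tagged by
provenance. Hubs are the maximum-degree nodes; ties are reported as a list
rather than broken arbitrarily.

## Risk score and survival

The prognostic signature is linear: $\mathrm{RiskScore} = \sum_i \beta_i
\cdot \mathrm{Gene}_i$ over sample-level expression (for single-cell input,
the per-sample pseudo-bulk mean of normalized expression). Coefficients are
consumed from a table — fitting them (Cox regression with stepwise
selection) is routine survival machinery outside this package's scope; a
seven-gene template ships in `inst/extdata/` with placeholder β values.
Samples are split at score tertiles into low/moderate/high groups. Tertiles
are symmetric and the split rule is not otherwise determined; the quantile
pair is a parameter. The split uses half-open intervals (low $< q_1$,
moderate $[q_1, q_2)$, high $\ge q_2$), which is deterministic under ties;
all-identical scores go to `moderate` with a warning rather than an
arbitrary three-way split. The $k$-sample log-rank test is implemented
directly from the observed-minus-expected event counts over distinct event
times with the full covariance quadratic form ($k-1$ df), so it can be
verified against hand tabulation on toy data and cross-checked against
standard survival software.

# The synthetic data generator

`generateDataset` emulates the structure such a study needs: several states
× cell types × samples, negative-binomial counts (variance
$\mu + \phi\mu^2$; default $\mu = 2$, $\phi = 0.5$, typical of the sparse
count depths of droplet data), optional logistic dropout (off by default —
NB sparsity already yields realistic zero fractions at these means), planted
multiplicative effects on the ligand gene in (source type, state) cells and
the receptor gene in (target type, state) cells, a random PPI graph over the
ligand/receptor gene universe with scores Uniform(0.4, 1) so the 0.7 filter
bites, and exponential survival with log-hazard equal to a configured linear
predictor over pseudo-bulk expression (baseline hazard $\log 2 / 24$: a
24-month median at the centred predictor, the scale of overall-survival
medians in myeloma cohorts). Censoring replaces a sample's time with a
uniform fraction of it.

All non-planted genes share one baseline mean, which makes ground truth
exact but is deliberately unrealistic: no gene-level mean heterogeneity,
batch effects, clonal structure, cell-type marker programs, or compositional
shifts between states. Passing tests therefore demonstrate the statistical
machinery (calibration, power against planted effects, exactness of the
deterministic stages), not robustness to the full messiness of real tissue
data. Cell-type label noise in particular is absent.

# Numerical and design choices

* **Normalization.** Counts are scaled to 10,000 per cell and
  log1p-transformed before any interaction statistic — the convention of the
  upstream single-cell toolchain; already-normalized input is accepted
  as-is. Because the fold-change stage operates on log-scale means, planted
  count-level folds compress; the zero rule (an event absent from the other
  state's significant table) is what typically drives classification of
  state-specific events.
* **QC order.** Cells are filtered first (mitochondrial fraction < 20%,
  detected genes strictly between 200 and 2500), then genes detected in
  fewer than 3 *remaining* cells are dropped; the gene pass is recomputed
  after the cell pass, making the operation idempotent. The mitochondrial
  fraction is computed from a configurable gene-name prefix (default
  `MT-`).
* **Permutation ties.** Cluster means are computed by matrix products;
  permuted scores that are mathematically equal to the observed score can
  differ by a few ulps. Tail counting uses a relative tolerance of $10^{-9}$
  so genuine ties count as "at least as extreme" — errs toward conservative
  p-values and makes exhaustive mode match exact enumeration.
* **Shared permutations.** Within a state, all pairs are scored against one
  set of label permutations (a handful of matrix products per permutation).
  P-values of distinct pairs remain essentially independent because they
  use disjoint genes.
* **Ambiguous receptor flags.** Pairs with no `True` (or two `True`)
  receptor flags get partner_b as receptor, are flagged `ambiguous`, and a
  warning is emitted — deterministic and auditable.
* **Multi-subunit complexes** are not modelled; pairs are gene–gene, as the
  event-expression formula operates on one receptor and one ligand value.
* **Seed fan-out.** The pipeline derives fixed per-stage child seeds from
  one seed, so stages are independently reproducible and two runs with the
  same config are byte-identical (numbers are written at 15 significant
  digits; a write/read round trip preserves at least 12).

# Problem sizes used in validation

The test-suite and the acceptance script validate at desk scale, chosen so
each property is measured with adequate precision while the whole suite
runs in minutes: exhaustive-vs-Monte-Carlo agreement on all two-type splits
of up to 8 cells (10,000 permutations); type-I calibration on a null
dataset with ~1,040 candidate events (2 states × 2 types × 130 pairs, 150
cells per type, 1,000 permutations), where the significant fraction must
lie in [0.03, 0.07]; power and classification on planted events of effect
size 3 with 100 cells per stratum across 20 seeds (≥ 90% recovery
required); the fold-change classifier against a brute-force oracle on
10,000 value pairs including the zero boundaries; Fisher's exact p against
integer hypergeometric enumeration on every 2×2 table with total ≤ 30
(agreement to 1e-12); exact recovery of the generator's linear predictor by
the risk score; and end-to-end byte-identical pipeline reruns.

# Known limitations

* The permutation null ignores sample-level structure within a state;
  strongly unbalanced multi-sample designs would need a stratified or
  sample-blocked null.
* Detection power and the fold-change statistic both depend on the gating
  fraction and the normalization; the defaults are sensible for droplet
  data but should be revisited for full-length protocols.
* The enrichment stage treats significant-event counts as the unit and
  inherits any miscalibration of the detection stage.
* Network extraction stops at first PPI neighbours and reports degree hubs
  only; no community structure or edge weighting beyond the score filter.
* The risk stage assumes the supplied coefficients were fit elsewhere;
  tertile boundaries are estimated on the scored cohort itself, so groups
  are relative, not transportable thresholds.
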