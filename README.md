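# cceflow

Cell–cell interaction event (CCE) analysis for single-cell transcriptomics of
disease progression, built around the bone-marrow immune microenvironment of
multiple myeloma and its precursor states (NBM → MGUS → SMM → MM), but
applicable to any annotated cell-by-gene expression matrix with cell types,
samples and condition labels.

A CCE is one ligand–receptor pair scored between an ordered pair of cell
types (ligand-expressing *source/regulatory* type → receptor-expressing
*target/regulated* type) within one pathological state. The package covers
five stages:

1. **Detection** (`detectAll`, `permutationTest`): for every
   (state, source type → target type, pair), the interaction score is the
   mean of the ligand's cluster mean in the source type and the receptor's
   cluster mean in the target type, with a minimum expressing-cell-fraction
   gate (default 10%). Its null distribution is built by shuffling cell-type
   labels among the state's cells; the Monte Carlo p-value uses the add-one
   estimator *p* = (1 + #{null ≥ observed}) / (1 + n_perm), with an
   exhaustive enumeration mode for small instances. Events with raw
   *p* < 0.05 are significant.
2. **Dysregulation** (`dysregulatedCCEs`): the event expression is
   EXP = mean(receptor mean, ligand mean); between two states,
   FC = (EXP₁ − EXP₂) / min(EXP₁, EXP₂). The event is up-regulated in
   State1 when FC > 0.25 or EXP₂ = 0, down-regulated when FC < −0.25 or
   EXP₁ = 0, otherwise unchanged.
3. **Enrichment** (`enrichmentMatrix`, `fisherExactTest`): 2×2 contingency
   tables of [events involving a focus cell type (or a directed type pair)
   vs all other events] × [two states], tested with a two-sided Fisher's
   exact test and summarized as log2 odds ratios.
4. **Networks** (`collectLRGenes`, `buildStateNetwork`): state-specific
   ligand/receptor gene sets (genes confined to one state's significant
   events) embedded in a protein–protein interaction network filtered at
   combined score ≥ 0.7, with hub (maximum-degree) genes reported.
5. **Risk stratification** (`riskScore`, `assignRiskGroups`,
   `logrankTest`): a linear signature RiskScore = Σᵢ βᵢ·Geneᵢ over
   sample-level expression, tertile split into low/moderate/high groups, and
   a k-sample log-rank comparison of overall survival.

A seeded synthetic-data generator (`synthConfig`, `generateDataset`)
produces negative-binomial counts with planted ligand–receptor effects in
chosen (source type, target type, state) triples and exponential survival
times with a known linear log-hazard, so every stage can be validated
against ground truth. `inst/extdata/` ships a small demo ligand–receptor
pair table and a seven-gene coefficient template
(CD38/ALOX5/TGFBR3/ICAM3/ANXA1/ALCAM/PECAM1) whose β values must be supplied
by the user.

## Worked example

```r
library(cceflow)

# two states, three cell types, one interaction planted in MM only
pe <- data.frame(pair_id = "P2", source_type = "EarlyB", target_type = "CD8T",
                 state = "MM", effect_size = 4)
cfg <- synthConfig(n_states = 2, n_cell_types = 3, n_samples_per_state = 2,
                   n_cells_per_type_per_sample = 80, n_genes = 120,
                   n_lr_pairs = 10, planted_events = pe,
                   state_names = c("NBM", "MM"), seed = 4)
ds <- generateDataset(cfg)

res <- detectAll(ds$sce, ds$pairs, n_perm = 1000, seed = 8)
res
#> CCEResult with 180 candidate interaction events
#>   states: NBM, MM
#>   cell types: CD8T, EarlyB, Monocyte
#>   significant (p < 0.05 ): 18
#>   n_perm: 1000  min_expr_fraction: 0.1

dys <- dysregulatedCCEs(res, state1 = "MM", state2 = "NBM")
subset(dys, dysregulated & pair_id == "P2" & source_type == "EarlyB")
#>   source_type target_type pair_id ligand receptor state1 state2 exp_state1
#> 3      EarlyB        CD8T      P2  G0003    G0004     MM    NBM   5.342470
#>   exp_state2 fold_change    direction dysregulated
#> 3   3.523655   0.5161726 up_in_state1         TRUE
```

The planted EarlyB→CD8T event is detected in MM (180 candidate events = 2
states × 9 ordered type pairs × 10 pairs) and classified up-regulated in MM
with fold change 0.52 > 0.25.

Survival stratification on a cohort with a known two-gene hazard signature:

```r
ds <- generateDataset(synthConfig(
  n_states = 1, n_cell_types = 2, n_samples_per_state = 120,
  n_cells_per_type_per_sample = 10, n_genes = 40, n_lr_pairs = 4,
  risk_genes = data.frame(gene = c("G0001", "G0003"), beta = c(2, -1.5)),
  censor_rate = 0.15, seed = 21))
model <- loadRiskCoefficients(ds$coefficients)
groups <- assignRiskGroups(riskScore(pseudoBulk(ds$sce), model))
table(groups$group)
#>      low moderate     high
#>       40       40       40
lr <- logrankTest(groups, ds$survival)
round(c(chi_square = lr$chi_square, df = lr$df, p_value = lr$p_value), 4)
#> chi_square         df    p_value
#>    87.1851     2.0000     0.0000
```

The tertile split is exact (40/40/40 of 120 samples) and the log-rank test
separates the three risk groups decisively because the risk score equals the
generator's true linear predictor.

The full chain can also be driven by one YAML config through `runPipeline()`
or the thin CLI at `inst/scripts/cceflow.R`
(`cceflow.R run --config config.yaml`), which writes every stage's TSV
outputs plus a manifest with checksums; reruns with the same seed are
byte-identical.

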