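# coatrophy

Consensus co-atrophy network analysis of regional brain morphometry.

## What it does, and for whom

In Alzheimer's disease and its prodromal stage (mild cognitive impairment,
MCI), atrophy does not strike regions independently: anatomically and
pathologically connected regions lose volume and cortical thickness in a
coordinated way, and the set of regions whose coordinated atrophy tracks
clinical decline appears to widen as the disease progresses. `coatrophy` is
an R package for neuroimaging groups who want to detect such **co-atrophy
modules** — clusters of regions whose atrophy measures are highly
inter-correlated across subjects — from FreeSurfer-style regional
morphometry, and to ask which modules' severity correlates with clinical
progression (conversion to dementia, cognitive decline speed).

The method is weighted correlation network analysis (WGCNA-style) applied
to structural covariance, with a consensus step that keeps only module
structure preserved in *both* a baseline and a longitudinal dataset:

1. **Normalization.** Volumes are expressed as a percentage of
   intracranial volume (ICV); thickness is left in mm. Every feature is
   then converted to a robust Z score against the cognitively normal (CN)
   cohort of the same timepoint:
   `Z = (raw − median_CN) × 1.3489 / IQR_CN`,
   where 1.3489 is the 25–75% quantile spread of the standard normal, so
   IQR scaling matches SD units under normality. A *subtracted* dataset
   (36-month Z minus baseline Z, per subject) captures net longitudinal
   change.
2. **Signed network.** Pairwise Spearman correlations `s_ij` between
   features become a signed soft-thresholded adjacency
   `a_ij = ((1 + s_ij)/2)^β`, with β chosen as the lowest power whose
   scale-free topology fit index reaches 0.80 in both datasets.
3. **Topological overlap and consensus.** Each adjacency becomes a
   topological overlap matrix,
   `TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
   `ℓ_ij = Σ_u a_iu a_uj`; the per-dataset TOMs are quantile-scaled to a
   common q95 and combined by elementwise minimum — the consensus TOM.
4. **Modules.** Average-linkage clustering of `1 − TOM_consensus`, a static
   branch cut with minimum module size 2, merging of modules whose
   eigengenes correlate ≥ 0.8 in every dataset, and the standard color
   labels (grey = unassigned). Each module is summarized per dataset by its
   **eigengene** (first principal component of the member submatrix) and
   correlated (Spearman) with clinical traits.

Because the motivating cohort data are access-restricted, the package
ships a seeded synthetic-cohort generator with planted co-atrophy modules
and trait links, in the exact fixture formats the parser reads, so the
whole pipeline is testable end to end.

## Worked example

```r
library(coatrophy)

run <- runConsensusAnalysis(seed = 1)   # default synthetic study conditions
run$modules
#> ModuleSet: 164 features, 2 modules (+141 grey)
#>    turquoise(12) blue(11)

networkPower(run$network)
#> [1] 8

recoveryScore(moduleAssignment(run$modules), run$sim$truth)
#> [1] 0.9061868

subset(traitTables(run$modules, "baseline"),  trait == "converted" & !is_grey)
#>      module     trait         rho           p   n is_grey  dataset
#>        blue converted -0.48942154 1.92161e-13 200   FALSE baseline
#>   turquoise converted -0.01584926 8.23729e-01 200   FALSE baseline

subset(traitTables(run$modules, "subtracted"), trait == "converted" & !is_grey)
#>      module     trait         rho            p   n is_grey    dataset
#>        blue converted -0.59317787 2.143758e-20 200   FALSE subtracted
#>   turquoise converted -0.65293736 1.104268e-25 200   FALSE subtracted
```

The run simulates 140 CN and 200 MCI subjects at two timepoints with two
planted bilateral 10-feature modules (temporal and parietal), normalizes,
builds the consensus network (soft power 8 selected by the scale-free
criterion), and recovers both planted modules (adjusted Rand index 0.906
against the generating labels; the extra members are noise features
absorbed at the cut). The trait tables show the planted design re-emerging:
the temporal module ("blue") correlates with conversion already at baseline
(rho = −0.49 — more atrophy, lower eigengene, higher conversion risk),
while the parietal module ("turquoise") is unrelated to conversion at
baseline (p = 0.82) but strongly related in the subtracted dataset
(rho = −0.65): conversion-linked co-atrophy extends from the temporal to
the parietal module over follow-up.

`writeResults(run$modules, "out/")` writes the assignment table, per-dataset
eigengene matrices, module–trait tables, the dendrogram (Newick) and a JSON
run manifest. A YAML config (paths or a `simulate:` block, plus network and
module parameters) drives `runConsensusAnalysis("cfg.yaml")`; a thin CLI
lives in `inst/scripts/coatrophy.R`.

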