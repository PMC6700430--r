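---
title: "Consensus co-atrophy networks: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus co-atrophy networks: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: what is being
modelled, which knobs matter, what the synthetic generator does and does
not emulate, and where the design was genuinely open and why we chose as
we did.

## The model

The object of study is *structural covariance*: across a cohort, regions
whose atrophy is driven by a shared process show correlated deviations
from a normative reference. We represent each subject by 164 regional
features — bilateral mean cortical thickness of the 34 Desikan–Killiany
regions (mm), the corresponding white-matter parcellation volumes, the two
unsegmented white-matter volumes, and 26 further subcortical
structures/parcellations (mm³) — and ask whether groups of features
co-vary as modules, and whether module severity tracks clinical
progression. Cerebellar volumes are catalogued but excluded, since the
pathology of interest is not expected to drive cerebellar atrophy.

The analysis pipeline:

1. **Robust Z against a CN reference.** Volumes are first expressed as a
   percentage of intracranial volume (head-size removal); thickness is not
   rescaled. Each feature of each MCI subject becomes
   $Z = (x - \mathrm{median}_{CN}) \cdot 1.3489 / \mathrm{IQR}_{CN}$,
   with the reference computed from the CN cohort *of the same timepoint*.
   The constant is the 25–75% spread of the standard normal
   ($q_{0.75}-q_{0.25} = 1.34898\ldots$), fixed at the truncated literal
   1.3489 for reproducibility; under normality the score coincides with a
   conventional Z, while median/IQR make it robust to outliers and mild
   non-normality. The *subtracted* dataset is the per-subject difference
   of 36-month and baseline Z over subjects present at both timepoints —
   net longitudinal change in reference units.
2. **Signed weighted network.** Feature–feature Spearman correlations
   $s_{ij}$ map to adjacency $a_{ij} = ((1+s_{ij})/2)^\beta$. The signed
   map keeps anti-correlated features *apart* (adjacency near 0) instead
   of conflating them, and the soft power $\beta$ suppresses weak
   correlations continuously rather than thresholding.
3. **Topological overlap, scaling, consensus.** The unsigned TOM formula
   is applied to the (already non-negative) signed adjacency. Per-dataset
   TOMs are brought onto a common scale by an elementwise power transform
   matching their 95th percentiles, and the consensus TOM is the
   elementwise minimum: an edge is only as strong as its weakest dataset,
   so modules cut from the consensus dendrogram are preserved in both the
   baseline and the subtracted network.
4. **Modules and eigengenes.** Average-linkage clustering of
   $1-\mathrm{TOM}$, a static cut, a minimum module size of 2, then
   iterative merging of module pairs whose eigengenes correlate at 0.8 or
   better in *every* dataset (consensus dissimilarity
   $\max_d (1-\mathrm{cor})$ below the merge cut 0.2). The eigengene is
   the first principal component of the column-standardized member
   submatrix, sign-anchored to correlate non-negatively with the member
   mean, so "lower eigengene = more atrophy" for atrophy-dominated
   modules. Consensus is computed between the **baseline and subtracted**
   datasets: the pairing asks which co-atrophy structure present at entry
   is still coordinated in its longitudinal progression.

Assumptions worth keeping in mind: monotone (not necessarily linear)
feature–feature dependence, enough subjects for rank correlations to
stabilize (the pipeline refuses fewer than 3, and is sensible from a few
dozen), a CN cohort large enough for median/IQR estimates, and features
measured on a common subject set per timepoint.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| soft power grid | 1..20 | – | candidate $\beta$; chosen as the lowest power with scale-free fit ≥ 0.80 in both datasets, falling back (with a warning) to the argmax of the min-across-dataset fit |
| scale-free fit threshold | 0.80 | $R^2$ | saturation criterion for the log–log degree regression |
| connectivity bins | 10 | – | equal-width bins of $k$ for the fit index |
| scaling quantile | 0.95 | – | upper-tail anchor for cross-dataset TOM comparability |
| cut height | 0.99 × max merge height | dissimilarity | static branch cut just under the root |
| minimum module size | 2 | features | smallest meaningful "coordinated" unit (a bilateral pair) |
| merge cut | 0.2 | 1 − cor | merge modules with ≥ 0.8 eigengene similarity in every dataset |
| robust-Z constant | 1.3489 | – | fixed literal; `iqrNormalConstant()` re-derives it |
| max missing fraction | 0.2 | – | subjects missing more are dropped with a warning |

## The synthetic generator

The generator exists because the motivating cohort data are
access-restricted; it emulates the *statistical structure* the pipeline
consumes, not anatomy. Per MCI subject, each planted module $m$ has a
severity factor $f_m \sim N(0,1)$; member features take
$\mu_j - \lambda f_m \sigma_j + N(0, \texttt{noise\_sd}\,\sigma_j)$
(atrophy subtracts — that is what makes member Z scores positively
co-vary), non-members and all CN subjects are reference noise
$\mu_j + N(0,\sigma_j)$. Volumes are drawn on the %ICV scale and
multiplied by a log-normal ICV, so ICV scaling removes the head-size
confound exactly. Conversion is Bernoulli with logit
$\alpha + \sum_m \beta_m f_m$ over baseline-trait-active modules; ADAS
progression speed is a linear combination of the same factors plus noise.
At 36 months every factor gains an $N(0, \texttt{progression\_sd})$
innovation, and converters additionally gain `converter_shift` on modules
active at m36.

Defaults are the package's study conditions, chosen once as plausible for
a degenerative-cohort simulation: 140 CN + 200 MCI subjects, two planted
bilateral 10-feature thickness modules (temporal, parietal),
$\lambda = 0.8$, `noise_sd` 0.5 (within-module Z correlation
$\lambda^2/(\lambda^2+0.5^2) \approx 0.72$), conversion effect 1.5
log-odds/SD on the temporal factor with intercept 0 (conversion rate near
one half), ADAS effect 0.12 points/month/SD around a mean MCI decline of
0.18, `progression_sd` 1.0 and `converter_shift` 1.5. Thickness references
are 2.5 ± 0.15 mm; volume references are per-tissue %ICV scales
(ventricles 1.0%, white matter 0.45%, subcortical 0.30%, other 0.08%,
each with 10% relative SD) around an ICV of 1.5 × 10⁶ mm³ (log-SD 0.08).

Two generator choices depart from a literal reading of the design sketch
and deserve their rationale:

* **`timepoint_active` governs the trait link, not the structural
  loading.** All planted modules are co-atrophic (loading $\lambda$) at
  both timepoints; a module "active at m36" is trait-independent at
  baseline and becomes conversion-linked through the converter increment.
  Had the second module carried *no* baseline correlation at all, it
  could not appear in a consensus built as an elementwise minimum with
  the baseline network — whereas the phenomenon being emulated is a
  module that exists throughout and whose *clinical association* extends
  over follow-up.
* **`progression_sd` (per-subject progression heterogeneity).** Without
  it, the subtracted dataset's within-module correlation would rest
  solely on the binary converter shift, an unrealistically impoverished
  longitudinal signal; atrophy progression rates vary continuously across
  subjects. Set to 1.0 (comparable to the baseline factor scale) a
  priori.

What passing tests on this generator do **not** show about real data:
there is no spatial smoothness, no scanner or site effects, no heavy-tail
measurement artefacts, no age/sex structure in the morphometry, Gaussian
factors and noise throughout, and the planted modules are disjoint and
block-uniform. Recovery of planted modules demonstrates the pipeline's
correctness, not field performance.

## Numerical choices

* **Quantiles.** Reference median/IQR use linear-interpolation quantiles
  (R type 7) — the mainstream default, recorded in the manifest. The TOM
  *scaling* quantile uses the order-statistic convention (type 1), because
  a monotone power transform maps an order statistic exactly: after
  scaling, all TOMs share the matched quantile to machine precision,
  which an interpolated quantile cannot guarantee.
* **Symmetric TOM scaling.** Scaling to the *first* dataset's quantile
  makes the consensus depend on dataset order; we instead match all TOMs
  to the geometric mean of their quantiles, which preserves [0,1] and
  ranks, and makes the pipeline exactly invariant to dataset order
  (asserted in the tests). Reference-based scaling remains available via
  `scaleTOMs(reference=)`.
* **Static cut.** The branch-cutting algorithm was an open choice; we cut
  at a fixed height (default 0.99 × the maximum merge height) because it
  is deterministic and fully specified, and let the minimum-size rule and
  the eigengene merge do the cleanup. The height is a config knob. A
  degenerate all-identical input (zero-height tree) yields one module.
* **Ties and determinism.** Spearman uses midranks; AUC uses the
  U-statistic with half-credit ties; `hclust` average linkage is
  deterministic for the continuous inputs at hand; module colors are
  assigned by descending size with first-member-index tie-break. With a
  fixed seed the whole pipeline is bit-reproducible, and assignments are
  invariant under feature permutation.
* **Degenerate inputs.** Zero-IQR reference features are dropped (an
  undefined score, not an infinite one) and logged; constant features at
  correlation time are an error (they should have been dropped upstream);
  all-tied connectivity returns a zero fit index with a warning;
  eigengene members without variance are dropped with a warning; missing
  cells are mean-imputed (logged) only inside eigengene computation,
  while correlations use pairwise-complete observations.
* **Multiple testing.** One BH family per trait column across the 164
  features (matching per-column heatmap correction); raw p is always
  reported alongside. Exact zero p-values from perfect monotone relations
  are clamped to the smallest positive double before adjustment.
* **Continuous-trait importance** is the squared Pearson correlation per
  feature rather than a tuned, model-mediated $R^2$; a `predictor` hook
  accepts any per-feature alternative. Binary importance is the folded
  AUC, $\max(\mathrm{AUC}, 1-\mathrm{AUC})$, since either atrophy
  direction may discriminate.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
default study conditions (340 subjects × 164 features × two timepoints,
soft-power search over 1..20), which completes in a few seconds on one
CPU; brute-force oracle checks use 6–10-node networks and 30-subject
tables, where exhaustive computation is exact and fast.

## Known limitations

* The scale-free criterion often has no qualifying power on small or
  weakly modular data; the fallback (argmax of the min-across-dataset
  fit) keeps the pipeline total but the warning should be taken
  seriously.
* A static cut near the root can absorb a few noise features into strong
  modules (visible as planted-module recovery slightly below ARI 1 at
  some seeds); a dynamic branch cut could sharpen boundaries at the cost
  of extra tuning surface.
* The consensus-by-minimum construction is conservative by design:
  structure present in only one dataset is invisible to it.
* Robust Z requires a genuinely normal-for-reference CN sample per
  timepoint; with very small CN cohorts the median/IQR estimates dominate
  the score's noise.
* Module–trait p-values are reported raw (with BH available behind a
  flag for the univariate tables); module counts are small enough that
  readers can apply their preferred correction.
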