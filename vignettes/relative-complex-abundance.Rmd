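---
title: "Relative complex abundance from untargeted proteomics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative complex abundance from untargeted proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoRCA)
```

## The problem and the model

OXPHOS complexes and the mitoribosome are obligate stoichiometric
assemblies: a subunit that cannot be made, or cannot be stably incorporated,
is degraded together with much of its complex. Untargeted DIA proteomics on
patient fibroblasts, PBMCs or muscle therefore carries a readable signature
of many pathogenic variants — a coordinated depression of all subunits of
the affected complex — without requiring an antibody or a targeted assay.

`mitoRCA` quantifies that signature. For a complex $C$ with subunits $p$,
control samples $K$ and proband replicates $Q$ (typically one patient run in
several technical/biological replicates):

$$
\mathrm{RCA}(C) \;=\; 100 \times \frac{1}{|C|}\sum_{p \in C}
10^{\,\log_{10}\bar q_p - \log_{10}\bar c_p},
$$

where $\bar c_p$ and $\bar q_p$ are arithmetic group means of the
linear-scale abundances over values present. The log10-then-unlog form
follows the published procedure the package reimplements; it is identical to
the direct ratio $\bar q_p/\bar c_p$ to $10^{-12}$ relative precision, and
the package asserts this equivalence in its tests.

Key assumptions:

* **Linear-scale input.** Search engines export linear quantities; any
  log-scale file must be declared in the reader dialect (`log_base`), which
  unlogs on ingest. Means are taken before any log transform.
* **Stoichiometric co-regulation.** The complex mean is informative because
  subunit ratios of a destabilised complex move together. Catalytic defects
  that leave assembly intact (several mtDNA missense variants) do not move
  abundance and are out of reach of this statistic by design.
* **Mitochondrial content is a nuisance parameter.** Patient cells often
  have globally altered mitochondrial mass; enzymology normalises activities
  to citrate synthase for the same reason. Here, each sample's mean over all
  mitochondrial proteins plays the role of citrate synthase.

## Mitochondrial-content correction

Per sample, the mean over mitochondrial proteins (values present) is
computed; per group, those per-sample means are averaged; every proband
sample is then multiplied by `control mean / proband mean`. After this,
the two group means over mitochondrial proteins agree exactly, and any
global scaling of the proband samples is absorbed exactly — a property the
test suite checks to $10^{-9}$.

The correction is applied as **one factor per group** by default. The
alternative — scaling each proband sample to the control mean individually
(`perSample = TRUE`) — also removes per-sample content variation, but it
shrinks the within-group replicate variance that the downstream t-test
relies on; group-level scaling preserves it. Both are offered because the
choice is genuinely open; group-level is the default for the statistical
reason above.

One caveat worth knowing: the affected complex's subunits are themselves
part of the mitochondrial mean, so a large single-complex defect drags the
proband mito mean down slightly and the correction pushes the RCA of the
affected complex up by a few percent (about +3% for a complex I knockdown
to 43% in the default simulation, where complex I is 44 of 1136
mitochondrial proteins). This is inherent to citrate-synthase-style
normalisation, not an implementation artefact.

## The t-test population

Figure-legend prose for this kind of analysis ("between the individual
protein means") is ambiguous: a test between the per-subunit *ratio* means
gives the control group identically 1 for every subunit — zero variance and
a degenerate test. The package therefore tests the **pooled per-sample,
per-subunit relative values** $x_{ps}/\bar c_p$, probands against controls,
with Welch's unequal-variance form by default (`varEqual = TRUE` for the
pooled-variance form); with 3-vs-5 group sizes Welch is the safer default.
The choice is recorded in the result object (the pooled vectors are carried
in the `RcaResult` slots). The dispersion band on the plot-facing result is
a t-based 95% confidence interval by default, with an SD band available
(`dispersion = "sd"`), matching the two conventions seen in practice.

## Filtering policies

Four cohort presets are built in (`presetPolicy()`):

| preset | peptide rule | valid values |
|--------|-------------|--------------|
| VC | max count per group ≥ 2 | ≥ 3 controls, ≥ 2 probands |
| KC | same | ≥ 2 in each group |
| UDP | same | ≥ 70% in each group |
| SC | same | ≥ 70% in each group |

Two readings of the peptide rule circulate ("filtered out if identified by
a single peptide in all control or proband samples" vs "> 2 peptides in
both groups"); the single-peptide exclusion — pass iff the maximum peptide
count within *each* group is at least 2 — is taken as the operative rule,
and `minPeptides` is an explicit policy field so the stricter ≥ 3 reading is
one configuration change. Fraction thresholds use ceiling semantics: "at
least 70%" of 5 controls means ≥ 4 valid values. Subunits are eligible for
RCA exactly when they survive the active policy; no additional peptide
re-check happens inside the RCA computation.

## Defect classification

`classifyRCA()` is total and deterministic, with inclusive boundaries:
major at RCA ≤ 65% of controls; major at ≤ 75% when the protein of interest
is absent in the proband with more than 2 peptides in at least one control
(`detectAbsentProtein()`); minor at ≤ 75%; otherwise none. The companion
enzymology classifier (`classifyRCE()`) uses strict inequalities: definite
below 30% residual activity (the established major criterion), probable
below 40%. The 40% minor threshold is not universal in the clinical
criteria literature, so it is an explicit argument; no headline quantity of
this package depends on it.

## Protein range scores

`proteinRange()` reports the proband median as a percent of the control
median and the distance of the proband median from the control median in
SD units on the log2 scale, rounded to one decimal. The SD is the root mean
squared deviation of the log2 control values **about the log2 control
median** with the population divisor — the phrasing that ties the variance
to the median is taken literally; dispersion about the mean
(`sdAbout = "mean"`) and the sample divisor (`sdDivisor = "sample"`) are
config alternatives, and the difference is small in practice.

## What the simulator emulates — and what it does not

`simulateProteome()` generates the study conditions the analysis assumes,
so every stage is testable without downloading data:

* **Cohort**: 5 controls vs 3 proband replicates (the validation-style
  design; both configurable).
* **Proteome**: 2000 non-mitochondrial background proteins, 959
  mitochondrial background proteins, and the canonical 177 OXPHOS +
  mitoribosome subunits under their real gene symbols (so annotation and
  panel joins behave as in production). The 1136-gene mitochondrial
  proteome matches the scale of curated mitochondrial inventories; the size
  matters because the affected complex's share of the mitochondrial mean
  sets the correction caveat above.
* **Abundance**: per-protein baselines $10^{N(6,\,0.8)}$ — a wide
  log-normal spanning roughly four decades, the standard stylisation of
  label-free DIA dynamic range — times log-normal biological noise at 20%
  CV (configurable).
* **Defects**: proband subunits of a defective complex are scaled by the
  residual fraction; structural-module residuals (e.g. an N-module-specific
  loss) override the complex residual for their genes; a mitochondrial
  content shift scales all proband mitochondrial proteins.
* **Missingness**: logistic dropout in log10 abundance (threshold 4.5,
  about 1.5 decades below the median protein; steepness 2), i.e.
  missing-not-at-random by abundance, the dominant DIA mechanism. This
  yields roughly 5–10% missingness overall, typical of post-search DIA
  matrices. Dropout monotonicity in abundance is a tested property.
* **Peptide evidence**: Poisson counts with rate 4 per decade above the
  detection threshold, minimum 1 where detected, 0 where not.

Not emulated: peptide/spectrum-level structure, retention-time effects,
batch effects between acquisition blocks, correlated noise across proteins
beyond complex membership, isoform/protein-group ambiguity, and
heteroplasmy-dependent kinetics. Passing tests on simulated data therefore
validate the *arithmetic and the decision rules*, not instrument-level
robustness; mtDNA missense cases that alter activity without abundance will
look normal here as they do in real data.

## Numerical choices and degenerate inputs

* Group means, medians and mito means are computed on values present;
  a subunit lacking either group mean is excluded from the complex mean and
  recorded in the result (`excludedSubunits`) rather than imputed.
* Zero/negative quantities on ingest are set missing with a logged count
  (quantities are positive where present); unparseable cells are hard
  errors naming row and column.
* When both pooled relative-value vectors are constant the t-test is
  defined by convention: p = 1 when the means agree, 0 otherwise.
* Pearson correlations (fold-change correlation and the enzymology
  benchmark share one implementation) report `NA` with a reason on
  constant input instead of erroring.
* Duplicate protein groups per gene are collapsed to the group with the
  highest summed abundance on ingest — a pragmatic rule for gene-keyed
  joins; it is logged, and disabled with `collapseGenes = FALSE`.

## Problem sizes used in validation

The packaged checks run the full pipeline on 100 simulated knockdown
cohorts (complex I at residual 0.43; recovery within ±5 percentage points
and a major call expected in at least 95 of them), 72 null cohorts (504
complex evaluations; major-call rate under 1%), and 20 label-permuted
cohorts for the volcano false-positive rate (expected near the nominal 5%).
These sizes give stable rates at desk scale; all were chosen as part of the
package's own validation design. Small complexes (CII has 4 subunits) have
ratio-mean standard deviations around 7% even under the null, so per-cohort
bounds are only asserted for rates and for well-populated complexes —
a real limitation of complex-mean statistics on tiny complexes.

## Known limitations

* RCA is blind to catalytic defects and can be muted for some mtDNA
  variants; it reports abundance, not activity.
* The correction caveat above biases single-complex knockdowns slightly
  upward; with the default layout this stays within a few percent.
* The benchmark pairing against enzymology (one point per line per
  genetically expected complex among CI, CIII, CIV) is a reconstruction of
  common practice and is overridable with an explicit pairs table.
* No multiple-testing correction is applied to volcano p-values by design
  (the workflow thresholds raw p at 0.05); a Benjamini–Hochberg column is
  emitted alongside, clearly labelled as an extension.
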