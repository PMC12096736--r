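# mitoRCA

Quantitative proteomics as functional evidence for suspected mitochondrial
disease. Many variants found by genomic sequencing in OXPHOS-related genes
remain variants of uncertain significance; a destabilising variant, however,
typically depresses the abundance of the *whole* complex the protein belongs
to in patient cells. `mitoRCA` turns an untargeted label-free (DIA) protein
quantity matrix from patient and control samples into that evidence:
per-complex **Relative Complex Abundance (RCA)** with defect calls,
single-protein range scores, volcano statistics, gene-panel coverage, and a
benchmark against clinical **respiratory chain enzymology (RCE)**. It is
aimed at analysts in diagnostic and research labs who receive searched
protein matrices (e.g. Spectronaut protein pivot reports) and need a
reproducible downstream pipeline.

## The statistic

For a complex *C* with annotated subunits *p* surviving cohort-specific
clean-up, with control samples *s ∈ K* and proband replicates *s ∈ Q*:

1. **Mitochondrial-content correction.** Let *m(s)* be the mean over all
   mitochondrial proteins of sample *s*. Every proband sample is scaled by
   `f = mean_{s∈K} m(s) / mean_{s∈Q} m(s)`, the proteomic analogue of the
   citrate-synthase ratio used in enzymology, so complex changes are not
   confounded by mitochondrial mass.
2. **Subunit ratios.** With group means `c_p` (controls) and `q_p`
   (probands) over values present, the subunit ratio is
   `r_p = 10^(log10 q_p − log10 c_p)` (identical to `q_p/c_p` to numerical
   precision; the log10 path mirrors the published procedure).
3. **RCA.** `RCA(C) = 100 × mean_p r_p`, with an unpaired two-sided t-test
   (Welch by default) between the pooled per-sample relative values
   `x[p,s]/c_p` of the two groups, and a 95% confidence band on the proband
   pool.
4. **Defect call.** `major` if RCA ≤ 65% of controls — or ≤ 75% when the
   protein of interest is undetected in the proband despite > 2 peptides in
   a control (`detectAbsentProtein()`); `minor` if RCA ≤ 75%; otherwise
   `none`.

RCE results consumed for benchmarking are classified Bernier-style:
`definite` below 30% residual activity, `probable` below 40% (configurable).

## Worked example

Every stage can be exercised without any external data through the built-in
simulator, which generates a fibroblast-style cohort (5 controls vs 3
proband replicates, 2000 background plus 1136 mitochondrial proteins,
20% biological CV, abundance-dependent dropout) with a complex I knockdown
at 43% residual:

```r
library(mitoRCA)

cfg <- simulationConfig(defects = c(CI = 0.43), seed = 7)
sim <- simulateProteome(cfg)

filtered  <- applyFilter(sim$experiment, presetPolicy("VC"))
corrected <- mitoCorrect(filtered, sim$annotation)
computeRCA(corrected, sim$annotation, "CI")
#> RCA CI: 45.0% of control (ci95 43.1-46.9), p = 1.39e-102, n = 35 subunits, call: major

proteinRange(corrected, "NDUFS8")
#> NDUFS8: 49.7% of control median, -6.8 SD

rcaTable(corrected, sim$annotation)[, c("complex", "rca_pct", "defect_call")]
#>   complex rca_pct defect_call
#> 1      CI    45.0       major
#> 2     CII   125.5        none
#> 3    CIII   104.2        none
#> 4     CIV   108.0        none
#> 5      CV    99.5        none
#> 6   mtLSU   105.0        none
#> 7   mtSSU   106.8        none
```

The injected complex I defect is recovered at 45% and called `major`
(threshold 65%), while the untouched complexes sit near 100% — note the
wider scatter of tiny complexes such as CII (4 subunits). The filter report
(`filterReport(filtered)`) shows 3136 proteins in, 241 removed by the
peptide-evidence rule, 101 by the valid-value rule, 2794 out.

A thin CLI over the same functions ships with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "rcatool.R", package = "mitoRCA"))') \
  simulate --out-dir cohort --seed 7 --defects CI=0.43
```

with subcommands `filter`, `rca`, `range`, `volcano`, `coverage` and
`benchmark` (see the header of `inst/cli/rcatool.R`).

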