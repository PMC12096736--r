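#' Mitochondrial content correction
#'
#' Computes each sample's mean over mitochondrial proteins (values present),
#' averages those per group, and rescales every proband sample's abundances
#' (all proteins) by `control mean / proband mean`, so that after correction
#' the two groups' mitochondrial means are equal. This is the proteomic
#' analogue of the citrate synthase ratio used in enzymology: it absorbs
#' global shifts in mitochondrial content so complex-level comparisons
#' reflect complex stoichiometry, not mitochondrial mass. By default one
#' factor is applied per group (preserving within-group replicate variance
#' for the downstream t-test); `perSample = TRUE` instead scales each
#' proband sample to the control mitochondrial mean individually.
#'
#' @param x a filtered [ProteinExperiment-class] with a design attached.
#' @param annot annotation `data.frame` (see [readAnnotation()]); genes with
#'   `is_mito` define the mitochondrial mean.
#' @param perSample scale each proband sample individually (default FALSE).
#' @return the corrected [ProteinExperiment-class]; the correction record
#'   (control/proband mitochondrial means and factor) is available via
#'   [mitoCorrection()].
#' @examples
#' sim <- simulateProteome(simulationConfig(seed = 1))
#' corrected <- mitoCorrect(applyFilter(sim$experiment), sim$annotation)
#' mitoCorrection(corrected)$factor
#' @export
mitoCorrect <- function(x, annot, perSample = FALSE) {
  stopifnot(is(x, "ProteinExperiment"))
  annot <- .validateAnnotation(annot)
  .requireDesign(x)
  mito_genes <- annot$gene[annot$is_mito]
  idx <- geneSymbols(x) %in% mito_genes
  if (!any(idx))
    stop("no mitochondrial proteins present in the matrix")
  if (sum(idx) < 10)
    warning("only ", sum(idx), " mitochondrial proteins present; ",
            "the correction factor will be unstable")
  ab <- abundances(x)
  ctl <- controlSamples(x)
  pro <- probandSamples(x)
  per_sample_mean <- colMeans(ab[idx, , drop = FALSE], na.rm = TRUE)
  ctl_mean <- mean(per_sample_mean[ctl])
  pro_mean <- mean(per_sample_mean[pro])
  if (!is.finite(ctl_mean) || ctl_mean <= 0 ||
      !is.finite(pro_mean) || pro_mean <= 0)
    stop("zero or undefined group mitochondrial mean")
  if (perSample) {
    factors <- ctl_mean / per_sample_mean[pro]
    ab[, pro] <- sweep(ab[, pro, drop = FALSE], 2L, factors, `*`)
    factor <- ctl_mean / pro_mean
  } else {
    factor <- ctl_mean / pro_mean
    factors <- setNames(rep(factor, length(pro)), pro)
    ab[, pro] <- ab[, pro, drop = FALSE] * factor
  }
  SummarizedExperiment::assay(x, "abundance") <- ab
  S4Vectors::metadata(x)$mito_correction <- list(
    control_mito_mean = ctl_mean, proband_mito_mean = pro_mean,
    factor = factor, per_sample = perSample, sample_factors = factors,
    n_mito_proteins = sum(idx))
  x
}

#' Relative Complex Abundance of an annotated complex
#'
#' For each annotated subunit surviving upstream filtering, the control mean
#' and proband mean are taken over values present; the subunit ratio is
#' computed on the log10 scale and unlogged
#' (`10^(log10(proband) - log10(control))`, identical to the direct ratio to
#' numerical precision), and the complex RCA is 100 x the mean subunit
#' ratio. Significance is an unpaired two-sided t-test (Welch by default)
#' between the pooled per-sample per-subunit relative values (each value
#' divided by its subunit's control mean) of the two groups; the dispersion
#' band is a 95% confidence interval (default) or SD band on the proband
#' group's pooled relative values. Subunits lacking a control or proband
#' mean are excluded and recorded. The defect call applies `criteria` to the
#' RCA percentage, optionally upgraded by absent-protein evidence.
#'
#' @param x a mito-corrected [ProteinExperiment-class].
#' @param annot annotation `data.frame` with complex membership.
#' @param complex one of `"CI"`, `"CII"`, `"CIII"`, `"CIV"`, `"CV"`,
#'   `"mtLSU"`, `"mtSSU"`.
#' @param dispersion `"ci95"` (default) or `"sd"`.
#' @param criteria a [DefectCriteria-class].
#' @param targetAbsent logical: the protein of interest is undetected in the
#'   proband with peptide evidence in controls (see
#'   [detectAbsentProtein()]); upgrades the call at RCA <= 75%.
#' @param varEqual use Student's pooled-variance t-test instead of Welch.
#' @return an [RcaResult-class].
#' @examples
#' sim <- simulateProteome(simulationConfig(defects = c(CI = 0.43), seed = 1))
#' pe <- mitoCorrect(applyFilter(sim$experiment), sim$annotation)
#' computeRCA(pe, sim$annotation, "CI")
#' @export
computeRCA <- function(x, annot, complex, dispersion = c("ci95", "sd"),
                       criteria = defectCriteria(), targetAbsent = FALSE,
                       varEqual = FALSE) {
  stopifnot(is(x, "ProteinExperiment"), is(criteria, "DefectCriteria"))
  dispersion <- match.arg(dispersion)
  annot <- .validateAnnotation(annot)
  if (length(complex) != 1L ||
      !complex %in% setdiff(.COMPLEX_LEVELS, "none"))
    stop("'complex' must be one of ",
         paste(setdiff(.COMPLEX_LEVELS, "none"), collapse = ", "))
  .requireDesign(x)
  genes <- annot$gene[annot$complex == complex]
  idx <- which(geneSymbols(x) %in% genes)
  if (!length(idx))
    stop("no subunits of ", complex, " present after filtering")
  ab <- abundances(x)[idx, , drop = FALSE]
  sub_genes <- geneSymbols(x)[idx]
  ctl <- controlSamples(x)
  pro <- probandSamples(x)
  c_mean <- rowMeans(ab[, ctl, drop = FALSE], na.rm = TRUE)
  q_mean <- rowMeans(ab[, pro, drop = FALSE], na.rm = TRUE)
  ok <- is.finite(c_mean) & c_mean > 0 & is.finite(q_mean) & q_mean > 0
  excluded <- sub_genes[!ok]
  if (length(excluded))
    message("excluding ", length(excluded), " subunit(s) of ", complex,
            " without both group means: ", paste(excluded, collapse = ", "))
  if (!any(ok))
    stop("no subunits of ", complex, " with both group means")
  # the published procedure: difference of log10 group means, unlogged
  ratios <- setNames(10^(log10(q_mean[ok]) - log10(c_mean[ok])),
                     sub_genes[ok])
  rca_pct <- 100 * mean(ratios)

  rel <- ab[ok, , drop = FALSE] / c_mean[ok]
  ctl_rel <- as.vector(rel[, ctl, drop = FALSE])
  pro_rel <- as.vector(rel[, pro, drop = FALSE])
  ctl_rel <- ctl_rel[!is.na(ctl_rel)]
  pro_rel <- pro_rel[!is.na(pro_rel)]
  p_value <- .safeTTest(pro_rel, ctl_rel, varEqual)

  band <- .dispersionBand(pro_rel, dispersion)
  call <- classifyRCA(rca_pct, targetAbsent = targetAbsent,
                      criteria = criteria)
  new("RcaResult", complex = complex, rcaPct = rca_pct,
      dispersionLow = 100 * band[1], dispersionHigh = 100 * band[2],
      dispersionType = dispersion, pValue = p_value,
      nSubunits = sum(ok), subunitRatios = ratios,
      excludedSubunits = as.character(excluded), defectCall = call,
      controlRelValues = ctl_rel, probandRelValues = pro_rel)
}

.safeTTest <- function(a, b, varEqual = FALSE) {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  t.test(a, b, var.equal = varEqual)$p.value
}

.dispersionBand <- function(values, type) {
  m <- mean(values)
  n <- length(values)
  if (type == "sd") {
    s <- sd(values)
    c(m - s, m + s)
  } else {
    se <- sd(values) / sqrt(n)
    half <- qt(0.975, df = n - 1L) * se
    c(m - half, m + half)
  }
}

#' RCA across several complexes
#'
#' Convenience wrapper running [computeRCA()] per complex and binding the
#' one-row summaries; complexes with no usable subunit are reported with
#' `NA` values rather than an error.
#'
#' @inheritParams computeRCA
#' @param complexes complexes to evaluate (default: all present in `annot`).
#' @return a `data.frame`, one row per complex.
#' @export
rcaTable <- function(x, annot, complexes = NULL,
                     dispersion = c("ci95", "sd"),
                     criteria = defectCriteria(), varEqual = FALSE) {
  annot <- .validateAnnotation(annot)
  if (is.null(complexes))
    complexes <- intersect(setdiff(.COMPLEX_LEVELS, "none"),
                           unique(annot$complex))
  rows <- lapply(complexes, function(cx) {
    res <- tryCatch(
      computeRCA(x, annot, cx, dispersion = dispersion,
                 criteria = criteria, varEqual = varEqual),
      error = function(e) NULL)
    if (is.null(res))
      data.frame(complex = cx, rca_pct = NA_real_,
                 dispersion_low = NA_real_, dispersion_high = NA_real_,
                 dispersion_type = match.arg(dispersion),
                 p_value = NA_real_, n_subunits = 0L,
                 defect_call = NA_character_, stringsAsFactors = FALSE)
    else as.data.frame(res)
  })
  do.call(rbind, rows)
}

#' Classify an RCA percentage as a major, minor or no defect
#'
#' Major: RCA at or below `majorMaxPct` (default 65% of controls), or at or
#' below `majorWithAbsentMaxPct` (default 75%) when the protein of interest
#' is absent in the proband with control peptide evidence. Minor: RCA at or
#' below `minorMaxPct` (default 75%). Boundaries inclusive; the function is
#' total and deterministic.
#'
#' @param rcaPct numeric vector of RCA percentages (must be >= 0).
#' @param targetAbsent logical (recycled): absent-protein evidence.
#' @param criteria a [DefectCriteria-class].
#' @return character vector: `"major"`, `"minor"` or `"none"`.
#' @examples
#' classifyRCA(c(43, 71, 104))
#' classifyRCA(70, targetAbsent = TRUE)
#' @export
classifyRCA <- function(rcaPct, targetAbsent = FALSE,
                        criteria = defectCriteria()) {
  stopifnot(is(criteria, "DefectCriteria"))
  validObject(criteria)
  if (any(is.na(rcaPct)) || any(rcaPct < 0))
    stop("rcaPct must be non-negative")
  targetAbsent <- rep_len(as.logical(targetAbsent), length(rcaPct))
  ifelse(rcaPct <= criteria@majorMaxPct |
           (targetAbsent & rcaPct <= criteria@majorWithAbsentMaxPct),
         "major",
         ifelse(rcaPct <= criteria@minorMaxPct, "minor", "none"))
}

#' Absent-protein evidence for a gene
#'
#' `TRUE` when the gene's abundance is missing in every proband sample while
#' its peptide count exceeds `minControlPeptides` in at least one control
#' sample — the situation where a protein is confidently seen in controls
#' but not detected in the patient. A gene absent from the matrix entirely
#' yields `FALSE` (no control evidence) with a message.
#'
#' @param x a [ProteinExperiment-class] with a design.
#' @param gene gene symbol.
#' @param minControlPeptides evidence threshold; counts must be strictly
#'   greater (default 2).
#' @return logical scalar.
#' @export
detectAbsentProtein <- function(x, gene, minControlPeptides = 2) {
  stopifnot(is(x, "ProteinExperiment"), length(gene) == 1L)
  .requireDesign(x)
  idx <- which(geneSymbols(x) == gene)
  if (!length(idx)) {
    message("gene ", gene, " not present in the matrix")
    return(FALSE)
  }
  ab <- abundances(x)[idx, , drop = FALSE]
  pep <- peptideCounts(x)[idx, , drop = FALSE]
  pro <- probandSamples(x)
  ctl <- controlSamples(x)
  all(is.na(ab[, pro])) && any(pep[, ctl] > minControlPeptides)
}
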