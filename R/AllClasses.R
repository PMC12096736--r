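#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median qt rnorm rpois runif sd t.test plogis cor.test p.adjust
#' @importFrom utils read.delim write.table
NULL

.COMPLEX_LEVELS <- c("CI", "CII", "CIII", "CIV", "CV", "mtLSU", "mtSSU", "none")
.GROUP_LEVELS <- c("control", "proband")

#' ProteinExperiment: protein x sample quantities with peptide evidence
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' two parallel assays: `"abundance"` (linear-scale protein quantities,
#' strictly positive where present, `NA` for missing) and `"peptides"`
#' (non-negative integer peptide counts, complete, zeros allowed).
#' `rowData()$gene` carries the gene symbol for every protein group;
#' `colData()` carries the sample design (`group`, `batch`, `replicate_of`),
#' where `group` is `"control"`, `"proband"`, or `NA` until a design is
#' attached with [setSampleDesign()].
#'
#' @seealso [ProteinExperiment()], [readProteinMatrix()], [applyFilter()]
#' @export
setClass("ProteinExperiment",
         contains = "SummarizedExperiment")

setValidity("ProteinExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("abundance", "peptides") %in% an))
    return("assays must contain 'abundance' and 'peptides'")
  ab <- SummarizedExperiment::assay(object, "abundance")
  pep <- SummarizedExperiment::assay(object, "peptides")
  if (!is.numeric(ab))
    msg <- c(msg, "abundance assay must be numeric")
  else if (any(ab[!is.na(ab)] <= 0))
    msg <- c(msg, "abundance values must be > 0 wherever present")
  if (anyNA(pep))
    msg <- c(msg, "peptide counts must be present for every cell (0 allowed)")
  else if (any(pep < 0) || any(pep != round(pep)))
    msg <- c(msg, "peptide counts must be non-negative integers")
  cn <- colnames(object)
  if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
    msg <- c(msg, "sample ids must be unique, non-empty column names")
  rd <- SummarizedExperiment::rowData(object)
  if (!"gene" %in% colnames(rd))
    msg <- c(msg, "rowData must contain a 'gene' column")
  else if (any(is.na(rd$gene) | !nzchar(rd$gene)))
    msg <- c(msg, "gene symbols must be non-empty")
  cd <- SummarizedExperiment::colData(object)
  if ("group" %in% colnames(cd)) {
    g <- cd$group
    if (!all(is.na(g) | g %in% .GROUP_LEVELS))
      msg <- c(msg, "group must be 'control', 'proband' or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinExperiment
#'
#' @param abundance numeric matrix, proteins x samples, linear scale,
#'   positive where present, `NA` for missing. Row names are protein group
#'   ids; column names are sample ids.
#' @param peptides integer matrix of the same dimensions with per-cell
#'   peptide counts; if `NULL`, a detection indicator (1 where quantified,
#'   0 where missing) is used and a warning is emitted, since real peptide
#'   evidence is needed for peptide-based filtering.
#' @param gene character vector of gene symbols, one per protein row.
#' @param design optional sample design `data.frame` (see
#'   [setSampleDesign()]); when omitted the group assignment is left `NA`.
#' @return a validated [ProteinExperiment-class] object.
#' @examples
#' ab <- matrix(c(10, 20, 12, 18), 2, 2,
#'              dimnames = list(c("P1", "P2"), c("C1", "P1s")))
#' pe <- ProteinExperiment(ab, matrix(3L, 2, 2), gene = c("NDUFS8", "SDHA"))
#' @export
ProteinExperiment <- function(abundance, peptides = NULL, gene,
                              design = NULL) {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)))
    rownames(abundance) <- paste0("protein", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    stop("abundance matrix must have sample ids as column names")
  if (is.null(peptides)) {
    warning("no peptide counts supplied; using detection indicators (0/1)")
    peptides <- (!is.na(abundance)) * 1L
  }
  peptides <- as.matrix(peptides)
  storage.mode(peptides) <- "integer"
  dimnames(peptides) <- dimnames(abundance)
  if (length(gene) != nrow(abundance))
    stop("'gene' must have one symbol per protein row")
  cd <- S4Vectors::DataFrame(
    group = rep(NA_character_, ncol(abundance)),
    batch = rep("batch1", ncol(abundance)),
    replicate_of = rep(NA_character_, ncol(abundance)),
    row.names = colnames(abundance))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance, peptides = peptides),
    rowData = S4Vectors::DataFrame(gene = as.character(gene)),
    colData = cd)
  pe <- new("ProteinExperiment", se)
  if (!is.null(design)) pe <- setSampleDesign(pe, design)
  pe
}

#' Filtering policy for cohort-specific protein clean-up
#'
#' Encodes the two-stage clean-up applied to each cohort: a peptide-evidence
#' rule (a protein is kept only when its maximum per-sample peptide count is
#' at least `minPeptides` within the control group AND within the proband
#' group) and a valid-value rule (a minimum count, or in `"fraction"` mode a
#' minimum fraction with ceiling semantics, of non-missing quantities per
#' group).
#'
#' @slot minPeptides integer peptide-evidence threshold (default 2; the
#'   stricter `>= 3` reading of single-peptide exclusion is one config
#'   change away).
#' @slot minValidControls,minValidProbands numeric thresholds; counts in
#'   `"count"` mode, fractions in `(0, 1]` in `"fraction"` mode.
#' @slot mode `"count"` or `"fraction"`.
#' @seealso [filterPolicy()], [presetPolicy()], [applyFilter()]
#' @export
setClass("FilterPolicy",
         representation(minPeptides = "integer",
                        minValidControls = "numeric",
                        minValidProbands = "numeric",
                        mode = "character"),
         prototype(minPeptides = 2L, minValidControls = 2,
                   minValidProbands = 2, mode = "count"))

setValidity("FilterPolicy", function(object) {
  msg <- character()
  if (length(object@mode) != 1L || !object@mode %in% c("count", "fraction"))
    msg <- c(msg, "mode must be 'count' or 'fraction'")
  if (object@minPeptides < 0L)
    msg <- c(msg, "minPeptides must be >= 0")
  th <- c(object@minValidControls, object@minValidProbands)
  if (any(th < 0))
    msg <- c(msg, "valid-value thresholds must be >= 0")
  if (identical(object@mode, "fraction") && any(th <= 0 | th > 1))
    msg <- c(msg, "fraction-mode thresholds must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterPolicy-class
#' @param minPeptides,minValidControls,minValidProbands,mode see slots.
#' @return a `FilterPolicy`.
#' @export
filterPolicy <- function(minPeptides = 2, minValidControls = 2,
                         minValidProbands = 2, mode = c("count", "fraction")) {
  new("FilterPolicy", minPeptides = as.integer(minPeptides),
      minValidControls = minValidControls,
      minValidProbands = minValidProbands, mode = match.arg(mode))
}

#' Defect classification thresholds for RCA calls
#'
#' A major defect is an RCA abundance at or below `majorMaxPct` (% of
#' controls), or at or below `majorWithAbsentMaxPct` when the protein of
#' interest is undetected in the proband despite more than
#' `absentMinControlPeptides` peptides in at least one control; a minor
#' defect is an RCA at or below `minorMaxPct`. Boundaries are inclusive.
#'
#' @slot majorMaxPct numeric, default 65.
#' @slot majorWithAbsentMaxPct numeric, default 75.
#' @slot minorMaxPct numeric, default 75.
#' @slot absentMinControlPeptides integer, default 2 (evidence requires a
#'   strictly greater count).
#' @seealso [classifyRCA()], [detectAbsentProtein()]
#' @export
setClass("DefectCriteria",
         representation(majorMaxPct = "numeric",
                        majorWithAbsentMaxPct = "numeric",
                        minorMaxPct = "numeric",
                        absentMinControlPeptides = "integer"),
         prototype(majorMaxPct = 65, majorWithAbsentMaxPct = 75,
                   minorMaxPct = 75, absentMinControlPeptides = 2L))

setValidity("DefectCriteria", function(object) {
  msg <- character()
  if (!(object@majorMaxPct <= object@majorWithAbsentMaxPct &&
        object@majorWithAbsentMaxPct <= 100))
    msg <- c(msg, "need majorMaxPct <= majorWithAbsentMaxPct <= 100")
  if (object@minorMaxPct > 100)
    msg <- c(msg, "minorMaxPct must be <= 100")
  if (object@absentMinControlPeptides < 0L)
    msg <- c(msg, "absentMinControlPeptides must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DefectCriteria-class
#' @param majorMaxPct,majorWithAbsentMaxPct,minorMaxPct,absentMinControlPeptides
#'   see slots.
#' @return a `DefectCriteria`.
#' @export
defectCriteria <- function(majorMaxPct = 65, majorWithAbsentMaxPct = 75,
                           minorMaxPct = 75, absentMinControlPeptides = 2) {
  new("DefectCriteria", majorMaxPct = majorMaxPct,
      majorWithAbsentMaxPct = majorWithAbsentMaxPct,
      minorMaxPct = minorMaxPct,
      absentMinControlPeptides = as.integer(absentMinControlPeptides))
}

#' Result of a Relative Complex Abundance computation
#'
#' Per-complex summary: `rcaPct` is 100 x the mean over subunits of the
#' proband/control abundance ratio (computed on the log10 scale and
#' unlogged), `pValue` an unpaired two-sided t-test between the pooled
#' per-sample per-subunit relative values of the two groups, the dispersion
#' band a 95% confidence interval or SD band on the proband group's pooled
#' relative values, and `defectCall` the classification of `rcaPct` under
#' the active [DefectCriteria-class].
#'
#' @slot complex character, one of CI..CV, mtLSU, mtSSU.
#' @slot rcaPct numeric, percent of control.
#' @slot dispersionLow,dispersionHigh numeric band bounds (percent).
#' @slot dispersionType `"ci95"` or `"sd"`.
#' @slot pValue numeric in `[0, 1]`.
#' @slot nSubunits integer number of subunits entering the mean.
#' @slot subunitRatios named numeric, per-gene proband/control ratio.
#' @slot excludedSubunits character, genes dropped for lacking a group mean.
#' @slot defectCall `"major"`, `"minor"` or `"none"`.
#' @slot controlRelValues,probandRelValues pooled per-sample relative values
#'   used for testing and dispersion.
#' @seealso [computeRCA()]
#' @export
setClass("RcaResult",
         representation(complex = "character", rcaPct = "numeric",
                        dispersionLow = "numeric", dispersionHigh = "numeric",
                        dispersionType = "character", pValue = "numeric",
                        nSubunits = "integer", subunitRatios = "numeric",
                        excludedSubunits = "character",
                        defectCall = "character",
                        controlRelValues = "numeric",
                        probandRelValues = "numeric"))

setValidity("RcaResult", function(object) {
  msg <- character()
  if (object@nSubunits < 1L)
    msg <- c(msg, "a reported complex needs >= 1 subunit")
  if (object@nSubunits != length(object@subunitRatios))
    msg <- c(msg, "nSubunits must match length(subunitRatios)")
  if (abs(object@rcaPct - 100 * mean(object@subunitRatios)) >
      1e-9 * max(1, abs(object@rcaPct)))
    msg <- c(msg, "rcaPct must equal 100 * mean(subunitRatios)")
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in [0, 1]")
  if (!object@defectCall %in% c("major", "minor", "none"))
    msg <- c(msg, "defectCall must be major, minor or none")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic proteome generator
#'
#' Defaults emulate a fibroblast-style DIA cohort: 2000 non-mitochondrial
#' background proteins, 959 mitochondrial background proteins plus the 177
#' OXPHOS/mitoribosome subunits (a MitoCarta-scale mitochondrial proteome of
#' 1136 genes), 5 controls vs 3 proband replicates, 20% biological CV
#' (log-normal), baseline log10 abundances N(6, 0.8), logistic
#' abundance-dependent dropout (threshold 4.5, steepness 2), and Poisson
#' peptide counts linked to log10 abundance (rate 4 per decade above the
#' detection threshold, minimum 1 where detected).
#'
#' @slot nBackground,nMitoBackground integer protein counts.
#' @slot complexLayout named integer, subunits per complex.
#' @slot nControls,nProbandReps integer sample counts.
#' @slot defects named numeric, complex -> residual fraction in (0, 1].
#' @slot moduleDefects named numeric, structural module -> residual,
#'   overriding the complex residual for member genes.
#' @slot mitoContentFactor numeric > 0, proband-wide scaling of all
#'   mitochondrial proteins (1 = no content shift).
#' @slot cvBiological numeric >= 0 biological coefficient of variation.
#' @slot baselineLogMean,baselineLogSD numeric, log10-scale baseline.
#' @slot detectionLogThreshold,dropoutSteepness numeric dropout curve.
#' @slot peptideRate numeric expected peptides per decade above threshold.
#' @slot seed integer default RNG seed.
#' @seealso [simulationConfig()], [simulateProteome()]
#' @export
setClass("SimulationConfig",
         representation(nBackground = "integer", nMitoBackground = "integer",
                        complexLayout = "integer", nControls = "integer",
                        nProbandReps = "integer", defects = "numeric",
                        moduleDefects = "numeric",
                        mitoContentFactor = "numeric",
                        cvBiological = "numeric", baselineLogMean = "numeric",
                        baselineLogSD = "numeric",
                        detectionLogThreshold = "numeric",
                        dropoutSteepness = "numeric", peptideRate = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nBackground < 0L || object@nMitoBackground < 0L)
    msg <- c(msg, "background protein counts must be >= 0")
  if (length(object@complexLayout) == 0L ||
      any(object@complexLayout < 1L) ||
      is.null(names(object@complexLayout)) ||
      !all(names(object@complexLayout) %in%
           setdiff(.COMPLEX_LEVELS, "none")))
    msg <- c(msg, "complexLayout must map known complexes to counts >= 1")
  if (object@nControls < 2L || object@nProbandReps < 1L)
    msg <- c(msg, "need >= 2 controls and >= 1 proband replicate")
  if (length(object@defects) &&
      (any(object@defects <= 0 | object@defects > 1) ||
       !all(names(object@defects) %in% names(object@complexLayout))))
    msg <- c(msg, "defects must map simulated complexes to residuals in (0, 1]")
  if (length(object@moduleDefects) &&
      any(object@moduleDefects <= 0 | object@moduleDefects > 1))
    msg <- c(msg, "module residuals must be in (0, 1]")
  if (object@mitoContentFactor <= 0)
    msg <- c(msg, "mitoContentFactor must be > 0")
  if (object@cvBiological < 0)
    msg <- c(msg, "cvBiological must be >= 0")
  if (object@peptideRate <= 0 || object@dropoutSteepness <= 0)
    msg <- c(msg, "peptideRate and dropoutSteepness must be > 0")
  if (length(msg)) msg else TRUE
})
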