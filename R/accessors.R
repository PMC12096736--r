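#' @name ProteinExperiment-accessors
#' @title Accessors for ProteinExperiment objects
#' @param x a [ProteinExperiment-class].
#' @description `abundances()` returns the linear-scale quantity matrix,
#'   `peptideCounts()` the peptide-count matrix, `geneSymbols()` the per-row
#'   gene symbols, `sampleGroups()` the control/proband assignment,
#'   `controlSamples()`/`probandSamples()` the corresponding sample ids,
#'   `filterReport()` the clean-up summary recorded by [applyFilter()], and
#'   `mitoCorrection()` the record left by [mitoCorrect()].
NULL

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("abundances", "ProteinExperiment", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("peptideCounts", function(x) standardGeneric("peptideCounts"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("peptideCounts", "ProteinExperiment", function(x)
  SummarizedExperiment::assay(x, "peptides"))

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("geneSymbols", "ProteinExperiment", function(x)
  as.character(SummarizedExperiment::rowData(x)$gene))

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("sampleGroups", "ProteinExperiment", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$group),
           colnames(x)))

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("controlSamples", "ProteinExperiment", function(x)
  colnames(x)[!is.na(sampleGroups(x)) & sampleGroups(x) == "control"])

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("probandSamples", function(x) standardGeneric("probandSamples"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("probandSamples", "ProteinExperiment", function(x)
  colnames(x)[!is.na(sampleGroups(x)) & sampleGroups(x) == "proband"])

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("filterReport", "ProteinExperiment", function(x)
  S4Vectors::metadata(x)$filter_report)

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("mitoCorrection", function(x) standardGeneric("mitoCorrection"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("mitoCorrection", "ProteinExperiment", function(x)
  S4Vectors::metadata(x)$mito_correction)

#' Attach a sample design to a ProteinExperiment
#'
#' The design assigns every listed sample to the control or proband group
#' (optionally with a batch and, for proband replicates, the proband they
#' replicate). The experiment is subset to the designed samples, which must
#' all exist in the matrix; at least one control and one proband are
#' required.
#'
#' @param x a [ProteinExperiment-class].
#' @param design a `data.frame` with columns `sample` (or `sample_id`),
#'   `group` (`"control"`/`"proband"`), and optionally `batch` and
#'   `replicate_of`.
#' @return the experiment restricted to designed samples, with colData set.
#' @export
setSampleDesign <- function(x, design) {
  design <- as.data.frame(design)
  idcol <- intersect(c("sample", "sample_id"), colnames(design))[1]
  if (is.na(idcol)) stop("design needs a 'sample' (or 'sample_id') column")
  if (!"group" %in% colnames(design)) stop("design needs a 'group' column")
  ids <- as.character(design[[idcol]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in design")
  missing <- setdiff(ids, colnames(x))
  if (length(missing))
    stop("design samples not found in the matrix: ",
         paste(missing, collapse = ", "))
  grp <- as.character(design$group)
  if (!all(grp %in% .GROUP_LEVELS))
    stop("group must be 'control' or 'proband'")
  if (!all(c("control", "proband") %in% grp))
    stop("design needs at least one control and one proband sample")
  x <- x[, ids]
  cd <- SummarizedExperiment::colData(x)
  cd$group <- grp
  cd$batch <- if ("batch" %in% colnames(design))
    as.character(design$batch) else rep("batch1", length(ids))
  cd$replicate_of <- if ("replicate_of" %in% colnames(design))
    as.character(design$replicate_of) else rep(NA_character_, length(ids))
  SummarizedExperiment::colData(x) <- cd
  validObject(x)
  x
}

.requireDesign <- function(x) {
  g <- sampleGroups(x)
  if (anyNA(g) || !all(c("control", "proband") %in% g))
    stop("the experiment has no complete sample design; ",
         "use setSampleDesign() first")
  invisible(g)
}

setMethod("show", "ProteinExperiment", function(object) {
  g <- sampleGroups(object)
  cat("ProteinExperiment:", nrow(object), "proteins x", ncol(object),
      "samples\n")
  cat("  groups:", sum(g == "control", na.rm = TRUE), "control /",
      sum(g == "proband", na.rm = TRUE), "proband",
      if (anyNA(g)) sprintf("(%d unassigned)", sum(is.na(g))) else "", "\n")
  ab <- abundances(object)
  cat(sprintf("  missing values: %.1f%%\n", 100 * mean(is.na(ab))))
  fr <- filterReport(object)
  if (!is.null(fr))
    cat(sprintf("  filtered: %d in, %d out (peptide rule -%d, valid-value rule -%d)\n",
                fr$n_in, fr$n_out, fr$removed_peptide, fr$removed_valid))
  mc <- mitoCorrection(object)
  if (!is.null(mc))
    cat(sprintf("  mito correction factor: %.4f\n", mc$factor))
  invisible(NULL)
})

setMethod("show", "FilterPolicy", function(object) {
  cat(sprintf(
    "FilterPolicy: peptides >= %d in each group; valid values %s >= %s (controls) / >= %s (probands)\n",
    object@minPeptides, object@mode,
    format(object@minValidControls), format(object@minValidProbands)))
  invisible(NULL)
})

setMethod("show", "DefectCriteria", function(object) {
  cat(sprintf(
    "DefectCriteria: major <= %g%% (or <= %g%% with absent protein, > %d control peptides); minor <= %g%%\n",
    object@majorMaxPct, object@majorWithAbsentMaxPct,
    object@absentMinControlPeptides, object@minorMaxPct))
  invisible(NULL)
})

setMethod("show", "RcaResult", function(object) {
  cat(sprintf("RCA %s: %.1f%% of control (%s %.1f-%.1f), p = %.3g, n = %d subunits, call: %s\n",
              object@complex, object@rcaPct, object@dispersionType,
              object@dispersionLow, object@dispersionHigh, object@pValue,
              object@nSubunits, object@defectCall))
  if (length(object@excludedSubunits))
    cat("  excluded subunits:",
        paste(object@excludedSubunits, collapse = ", "), "\n")
  invisible(NULL)
})

#' Flatten an RcaResult to a one-row data.frame
#'
#' @param x an [RcaResult-class].
#' @param row.names,optional,... ignored, for generic consistency.
#' @return a one-row `data.frame` with the summary fields.
#' @export
as.data.frame.RcaResult <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(complex = x@complex, rca_pct = x@rcaPct,
             dispersion_low = x@dispersionLow,
             dispersion_high = x@dispersionHigh,
             dispersion_type = x@dispersionType,
             p_value = x@pValue, n_subunits = x@nSubunits,
             defect_call = x@defectCall, stringsAsFactors = FALSE)
}

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("subunitRatios", function(x) standardGeneric("subunitRatios"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("subunitRatios", "RcaResult", function(x) x@subunitRatios)

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("rcaPct", function(x) standardGeneric("rcaPct"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("rcaPct", "RcaResult", function(x) x@rcaPct)

#' @rdname ProteinExperiment-accessors
#' @export
setGeneric("defectCall", function(x) standardGeneric("defectCall"))
#' @rdname ProteinExperiment-accessors
#' @export
setMethod("defectCall", "RcaResult", function(x) x@defectCall)
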