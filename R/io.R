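#' Reader dialects for protein quantity matrices
#'
#' `spectronautDialect()` targets a Spectronaut-style protein pivot report:
#' one protein-group id column, one gene column, per-run quantity columns
#' sharing a suffix, and parallel per-run peptide-count columns. The sample
#' id is the column name with the suffix stripped. `matrixDialect()` is the
#' generic form with explicit column maps for arbitrary tab-separated
#' matrices.
#'
#' @param id_col,gene_col identifier and gene symbol column names.
#' @param quantity_suffix,peptide_suffix column-name suffixes marking
#'   per-sample quantity and peptide-count columns.
#' @param quantity_cols,peptide_cols named character vectors
#'   (sample id -> column name) for the generic dialect; `peptide_cols` may
#'   be `NULL` when the file carries no peptide evidence.
#' @param missing_tokens cell values parsed as missing.
#' @param log_base if the file stores log-scale quantities, the base to
#'   unlog with; `NULL` (default) means linear scale.
#' @return a dialect object consumed by [readProteinMatrix()].
#' @export
spectronautDialect <- function(id_col = "PG.ProteinGroups",
                               gene_col = "PG.Genes",
                               quantity_suffix = ".PG.Quantity",
                               peptide_suffix = ".PG.NrOfStrippedSequencesIdentified",
                               missing_tokens = c("NaN", "Filtered", "", "NA"),
                               log_base = NULL) {
  structure(list(id_col = id_col, gene_col = gene_col,
                 quantity_suffix = quantity_suffix,
                 peptide_suffix = peptide_suffix,
                 quantity_cols = NULL, peptide_cols = NULL,
                 missing_tokens = missing_tokens, log_base = log_base),
            class = "matrix_dialect")
}

#' @rdname spectronautDialect
#' @export
matrixDialect <- function(id_col, gene_col, quantity_cols,
                          peptide_cols = NULL,
                          missing_tokens = c("NaN", "Filtered", "", "NA"),
                          log_base = NULL) {
  if (is.null(names(quantity_cols)))
    stop("quantity_cols must be named by sample id")
  if (!is.null(peptide_cols) &&
      !identical(sort(names(peptide_cols)), sort(names(quantity_cols))))
    stop("peptide_cols must be named by the same sample ids")
  structure(list(id_col = id_col, gene_col = gene_col,
                 quantity_suffix = NULL, peptide_suffix = NULL,
                 quantity_cols = quantity_cols, peptide_cols = peptide_cols,
                 missing_tokens = missing_tokens, log_base = log_base),
            class = "matrix_dialect")
}

.parseNumericCells <- function(raw, missing_tokens, what, path) {
  # raw: character matrix. Every cell must be a positive real or a missing
  # token; anything else is a hard error naming the offending row/column.
  vals <- suppressWarnings(as.numeric(raw))
  is_missing_token <- raw %in% missing_tokens | is.na(raw)
  bad <- is.na(vals) & !is_missing_token
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric %s cell '%s' at row %d, column '%s' in %s",
                 what, raw[bad][1], idx[1], colnames(raw)[idx[2]], path))
  }
  vals[is_missing_token] <- NA_real_
  matrix(vals, nrow = nrow(raw), dimnames = dimnames(raw))
}

#' Read a protein quantity matrix
#'
#' Parses a tab-separated protein pivot report into a
#' [ProteinExperiment-class]. Cells equal to a missing token (`"NaN"`,
#' `"Filtered"`, `""`, `"NA"`) become missing; zero or negative quantities
#' are set missing with a message (quantities are positive where present);
#' any other non-numeric quantity is a hard error naming its row and column.
#' Rows without a gene symbol are dropped with a message. When several
#' protein groups share a gene symbol the group with the highest summed
#' abundance is kept and the rest are dropped with a message, so downstream
#' joins by gene are unambiguous.
#'
#' @param path path to the tab-separated file.
#' @param dialect a [spectronautDialect()] or [matrixDialect()].
#' @param collapseGenes collapse duplicate gene symbols (default `TRUE`).
#' @return a [ProteinExperiment-class] (without a sample design; attach one
#'   with [setSampleDesign()]).
#' @export
readProteinMatrix <- function(path, dialect = spectronautDialect(),
                              collapseGenes = TRUE) {
  stopifnot(inherits(dialect, "matrix_dialect"))
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   na.strings = NULL)
  for (col in c(dialect$id_col, dialect$gene_col))
    if (!col %in% colnames(df))
      stop("column '", col, "' not found in ", path)
  dup <- colnames(df)[duplicated(colnames(df))]
  if (length(dup))
    stop("duplicate sample column(s): ", paste(unique(dup), collapse = ", "))

  if (!is.null(dialect$quantity_suffix)) {
    sfx <- dialect$quantity_suffix
    qcols <- colnames(df)[endsWith(colnames(df), sfx)]
    if (!length(qcols))
      stop("no quantity columns with suffix '", sfx, "' in ", path)
    samples <- substr(qcols, 1L, nchar(qcols) - nchar(sfx))
    names(qcols) <- samples
    pcols_all <- paste0(samples, dialect$peptide_suffix)
    pcols <- if (all(pcols_all %in% colnames(df)))
      setNames(pcols_all, samples) else NULL
  } else {
    qcols <- dialect$quantity_cols
    pcols <- dialect$peptide_cols
    missing_cols <- setdiff(c(qcols, pcols), colnames(df))
    if (length(missing_cols))
      stop("mapped column(s) not found: ",
           paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(names(qcols)))
    stop("duplicate sample column(s): ",
         paste(unique(names(qcols)[duplicated(names(qcols))]),
               collapse = ", "))

  raw_q <- as.matrix(df[, qcols, drop = FALSE])
  colnames(raw_q) <- names(qcols)
  ab <- .parseNumericCells(raw_q, dialect$missing_tokens, "quantity", path)
  if (!is.null(dialect$log_base)) ab <- dialect$log_base ^ ab
  nonpos <- !is.na(ab) & ab <= 0
  if (any(nonpos)) {
    message(sum(nonpos), " non-positive quantity cell(s) set to missing")
    ab[nonpos] <- NA_real_
  }

  if (!is.null(pcols)) {
    raw_p <- as.matrix(df[, pcols[names(qcols)], drop = FALSE])
    colnames(raw_p) <- names(qcols)
    pep <- .parseNumericCells(raw_p, dialect$missing_tokens,
                              "peptide-count", path)
    pep[is.na(pep)] <- 0
    if (any(pep != round(pep) | pep < 0))
      stop("peptide counts must be non-negative integers in ", path)
  } else {
    message("no peptide-count columns found; using detection indicators")
    pep <- (!is.na(ab)) * 1
  }

  gene <- df[[dialect$gene_col]]
  rownames(ab) <- rownames(pep) <- make.unique(df[[dialect$id_col]])
  no_gene <- is.na(gene) | !nzchar(trimws(gene))
  if (any(no_gene)) {
    message(sum(no_gene), " row(s) without a gene symbol dropped")
    ab <- ab[!no_gene, , drop = FALSE]
    pep <- pep[!no_gene, , drop = FALSE]
    gene <- gene[!no_gene]
  }
  gene <- trimws(gene)

  if (collapseGenes && anyDuplicated(gene)) {
    total <- rowSums(ab, na.rm = TRUE)
    keep <- unlist(lapply(split(seq_along(gene), gene),
                          function(i) i[which.max(total[i])]),
                   use.names = FALSE)
    dropped <- nrow(ab) - length(keep)
    message(dropped, " duplicate-gene protein group(s) dropped ",
            "(kept highest summed abundance)")
    keep <- sort(keep)
    ab <- ab[keep, , drop = FALSE]
    pep <- pep[keep, , drop = FALSE]
    gene <- gene[keep]
  }

  mode(pep) <- "integer"
  ProteinExperiment(ab, pep, gene = gene)
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene`, `is_mito`, `complex`
#' (`CI`..`CV`, `mtLSU`, `mtSSU` or `none`) and optional `module`.
#' Duplicate genes, unknown complex labels, and complex assignments on
#' non-mitochondrial genes are errors.
#'
#' @param path path to the file. The packaged OXPHOS annotation lives at
#'   `system.file("extdata", "oxphos_annotation.tsv", package = "mitoRCA")`.
#' @return a validated annotation `data.frame`.
#' @export
readAnnotation <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
  df$is_mito <- toupper(df$is_mito) %in% c("TRUE", "T", "1", "YES")
  .validateAnnotation(df)
}

#' Read a sample design table
#'
#' Tab-separated with columns `sample`, `group` and optionally `batch`,
#' `replicate_of`.
#'
#' @param path path to the file.
#' @return a `data.frame` suitable for [setSampleDesign()].
#' @export
readSampleDesign <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   na.strings = c("NA", ""))
  if (!all(c("sample", "group") %in% colnames(df)) &&
      !all(c("sample_id", "group") %in% colnames(df)))
    stop("design file needs 'sample' and 'group' columns")
  df
}

#' Read a respiratory chain enzymology table
#'
#' Tab-separated with columns `line_id`, `complex` (CI-CIV), `tissue` and
#' `activity_pct` (complex activity relative to the control mean, CS-ratio,
#' in percent).
#'
#' @param path path to the file.
#' @return a validated `data.frame`.
#' @export
readRce <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  need <- c("line_id", "complex", "tissue", "activity_pct")
  if (!all(need %in% colnames(df)))
    stop("RCE file needs columns: ", paste(need, collapse = ", "))
  df$complex <- as.character(df$complex)
  bad <- setdiff(unique(df$complex), c("CI", "CII", "CIII", "CIV"))
  if (length(bad))
    stop("unknown RCE complex label(s): ", paste(bad, collapse = ", "))
  df$activity_pct <- as.numeric(df$activity_pct)
  if (any(!is.na(df$activity_pct) & df$activity_pct < 0))
    stop("activity_pct must be >= 0")
  df
}

#' Write a result table as tab-separated text
#'
#' Stable column order, UTF-8, Unix newlines, `.` decimal separator;
#' numerics are written with 15 significant digits so a re-read reproduces
#' values to at least 12 significant digits.
#'
#' @param results a `data.frame` (or [RcaResult-class], flattened first).
#' @param path output path.
#' @return invisibly, the written `data.frame`.
#' @export
writeResults <- function(results, path) {
  if (is(results, "RcaResult")) results <- as.data.frame(results)
  results <- as.data.frame(results)
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), "NA", formatC(x, digits = 15, format = "g")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(results)
}

#' Read back a table written by writeResults
#'
#' @param path path to the file.
#' @return a `data.frame` with numeric columns restored.
#' @export
readResults <- function(path) {
  read.delim(path, check.names = FALSE, na.strings = "NA")
}

#' Read a run configuration file
#'
#' YAML with sections `samples` (design entries), `paths`, `policy`
#' (filter settings) and `thresholds` (defect criteria overrides).
#'
#' @param path path to the YAML file.
#' @return a named list with those sections (missing ones are `NULL`).
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("run configuration must be a YAML mapping")
  cfg[c("samples", "paths", "policy", "thresholds")]
}
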