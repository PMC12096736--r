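#' Single-protein range score against the control median
#'
#' Computes the proband median as a percentage of the control median
#' (medians on the linear scale; the log2 fold-change of the medians is
#' converted back to percent), and the number of standard deviations the
#' proband median lies from the control median on the log2 scale, where the
#' SD is the root mean squared deviation of the log2 control values about
#' the log2 control median (population divisor by default; dispersion about
#' the mean and the sample divisor are available). The SD score is rounded
#' to one decimal place. The control values relative to their median are
#' returned for range plotting.
#'
#' @param x a [ProteinExperiment-class] with a design.
#' @param gene gene symbol (needs >= 2 control values and >= 1 proband
#'   value).
#' @param sdAbout dispersion anchor: `"median"` (default) or `"mean"`.
#' @param sdDivisor `"population"` (default, divisor n) or `"sample"`
#'   (divisor n - 1).
#' @return a list with `gene`, `pct_of_control_median`, `sd_from_median`
#'   (rounded to 1 decimal), `log2_fc`, `sd_log2`, and
#'   `control_values_pct`.
#' @examples
#' sim <- simulateProteome(simulationConfig(defects = c(CI = 0.43), seed = 1))
#' proteinRange(sim$experiment, "NDUFS8")$pct_of_control_median
#' @export
proteinRange <- function(x, gene, sdAbout = c("median", "mean"),
                         sdDivisor = c("population", "sample")) {
  stopifnot(is(x, "ProteinExperiment"), length(gene) == 1L)
  sdAbout <- match.arg(sdAbout)
  sdDivisor <- match.arg(sdDivisor)
  .requireDesign(x)
  idx <- which(geneSymbols(x) == gene)
  if (!length(idx)) stop("gene ", gene, " not present in the matrix")
  ab <- abundances(x)[idx[1], ]
  ctl <- ab[controlSamples(x)]
  pro <- ab[probandSamples(x)]
  ctl <- ctl[!is.na(ctl)]
  pro <- pro[!is.na(pro)]
  if (length(ctl) < 2L || length(pro) < 1L)
    stop("need >= 2 control and >= 1 proband values for ", gene)
  cm <- median(ctl)
  pm <- median(pro)
  if (cm <= 0) stop("zero control median for ", gene)
  fc <- log2(pm) - log2(cm)
  anchor <- if (sdAbout == "median") log2(cm) else mean(log2(ctl))
  denom <- if (sdDivisor == "population") length(ctl) else length(ctl) - 1L
  s <- sqrt(sum((log2(ctl) - anchor)^2) / denom)
  list(gene = gene,
       pct_of_control_median = 100 * 2^fc,
       sd_from_median = round(fc / s, 1),
       log2_fc = fc,
       sd_log2 = s,
       control_values_pct = 100 * ctl / cm)
}

#' Volcano statistics: per-protein fold-change and t-test
#'
#' For every protein with at least two non-missing values per group,
#' computes the log2 fold-change of the group means and an unpaired
#' two-sided t-test (Welch by default) on the log2-transformed values.
#' No multiple-testing correction is applied to `p_value` (the analysis
#' thresholds raw p at 0.05); a Benjamini-Hochberg column `p_adj_bh` is
#' emitted alongside as a clearly-labelled extension. Untestable proteins
#' are skipped and counted in a message.
#'
#' @param x a [ProteinExperiment-class] with a design.
#' @param varEqual use Student's pooled-variance t-test.
#' @return a `data.frame` with `gene`, `log2_fc`, `p_value`, `p_adj_bh`,
#'   `n_control`, `n_proband`.
#' @export
volcanoStats <- function(x, varEqual = FALSE) {
  stopifnot(is(x, "ProteinExperiment"))
  .requireDesign(x)
  ab <- abundances(x)
  ctl <- controlSamples(x)
  pro <- probandSamples(x)
  n_ctl <- rowSums(!is.na(ab[, ctl, drop = FALSE]))
  n_pro <- rowSums(!is.na(ab[, pro, drop = FALSE]))
  testable <- n_ctl >= 2L & n_pro >= 2L
  if (!any(testable)) stop("no testable proteins (need >= 2 values/group)")
  if (any(!testable))
    message(sum(!testable), " protein(s) skipped (fewer than 2 values in a group)")
  lab <- log2(ab[testable, , drop = FALSE])
  genes <- geneSymbols(x)[testable]
  cmat <- lab[, ctl, drop = FALSE]
  pmat <- lab[, pro, drop = FALSE]
  fc <- log2(rowMeans(ab[testable, pro, drop = FALSE], na.rm = TRUE)) -
    log2(rowMeans(ab[testable, ctl, drop = FALSE], na.rm = TRUE))
  pv <- vapply(seq_len(nrow(lab)), function(i) {
    a <- pmat[i, ]
    b <- cmat[i, ]
    .safeTTest(a[!is.na(a)], b[!is.na(b)], varEqual)
  }, numeric(1))
  data.frame(gene = genes, log2_fc = fc, p_value = pv,
             p_adj_bh = p.adjust(pv, method = "BH"),
             n_control = n_ctl[testable], n_proband = n_pro[testable],
             row.names = NULL, stringsAsFactors = FALSE)
}

## Single Pearson implementation shared by fold-change correlation and the
## enzymology benchmark.
.pearson <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = "fewer than 3 complete pairs"))
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n,
                reason = "constant vector: correlation undefined"))
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, reason = NULL)
}

#' Correlation of log2 fold-changes between two analyses
#'
#' Pairs two volcano tables by gene symbol (optionally restricted to a gene
#' subset, e.g. mitochondrial genes) and returns the Pearson correlation of
#' their log2 fold-changes.
#'
#' @param a,b `data.frame`s with columns `gene` and `log2_fc`
#'   (as returned by [volcanoStats()]).
#' @param subset optional character vector of gene symbols to restrict to.
#' @return a list with `r`, `p`, `n` (genes paired).
#' @export
fcCorrelation <- function(a, b, subset = NULL) {
  for (tb in list(a, b))
    if (!all(c("gene", "log2_fc") %in% colnames(tb)))
      stop("tables need 'gene' and 'log2_fc' columns")
  shared <- intersect(a$gene, b$gene)
  if (!is.null(subset)) shared <- intersect(shared, subset)
  if (length(shared) < 3L)
    stop("need >= 3 shared genes, got ", length(shared))
  va <- a$log2_fc[match(shared, a$gene)]
  vb <- b$log2_fc[match(shared, b$gene)]
  res <- .pearson(va, vb)
  list(r = res$r, p = res$p, n = res$n)
}

#' Gene panel coverage of a detected proteome
#'
#' Percentage of panel genes present in the detected gene set, matching by
#' upper-cased symbol.
#'
#' @param detected character vector of detected gene symbols.
#' @param panel character vector of panel gene symbols (non-empty).
#' @return numeric percentage in `[0, 100]`.
#' @examples
#' panelCoverage(c("A", "B", "C"), c("B", "C", "D", "E"))  # 50
#' @export
panelCoverage <- function(detected, panel) {
  panel <- unique(toupper(trimws(panel)))
  panel <- panel[nzchar(panel)]
  if (!length(panel)) stop("panel is empty")
  detected <- unique(toupper(trimws(detected)))
  100 * length(intersect(detected, panel)) / length(panel)
}
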