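## Curated OXPHOS / mitoribosome subunit gene lists (HGNC symbols), used for
## the packaged annotation and for naming simulated subunits. Complex I
## N-module membership follows the cryo-EM structural assignment.

.CI_GENES <- c(
  "MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5", "MT-ND6",
  "NDUFS1", "NDUFS2", "NDUFS3", "NDUFS4", "NDUFS5", "NDUFS6", "NDUFS7",
  "NDUFS8", "NDUFV1", "NDUFV2", "NDUFV3",
  "NDUFA1", "NDUFA2", "NDUFA3", "NDUFA5", "NDUFA6", "NDUFA7", "NDUFA8",
  "NDUFA9", "NDUFA10", "NDUFA11", "NDUFA12", "NDUFA13", "NDUFAB1",
  "NDUFB1", "NDUFB2", "NDUFB3", "NDUFB4", "NDUFB5", "NDUFB6", "NDUFB7",
  "NDUFB8", "NDUFB9", "NDUFB10", "NDUFB11", "NDUFC1", "NDUFC2")

.CI_N_MODULE <- c("NDUFV1", "NDUFV2", "NDUFV3", "NDUFS1", "NDUFS4",
                  "NDUFS6", "NDUFA2", "NDUFA6", "NDUFA7", "NDUFA12",
                  "NDUFAB1")

.CII_GENES <- c("SDHA", "SDHB", "SDHC", "SDHD")

.CIII_GENES <- c("UQCRC1", "UQCRC2", "CYC1", "UQCRFS1", "MT-CYB", "UQCRB",
                 "UQCRQ", "UQCRH", "UQCR10", "UQCR11")

.CIV_GENES <- c("MT-CO1", "MT-CO2", "MT-CO3", "COX4I1", "COX4I2", "COX5A",
                "COX5B", "COX6A1", "COX6A2", "COX6B1", "COX6C", "COX7A1",
                "COX7A2", "COX7A2L", "COX7B", "COX7C", "COX8A", "COX8C",
                "NDUFA4")

.CV_GENES <- c("ATP5F1A", "ATP5F1B", "ATP5F1C", "ATP5F1D", "ATP5F1E",
               "ATP5PB", "ATP5PD", "ATP5PF", "ATP5PO", "ATP5MC1", "ATP5MC2",
               "ATP5MC3", "ATP5ME", "ATP5MF", "ATP5MG", "ATP5MJ",
               "MT-ATP6", "MT-ATP8")

.MTLSU_GENES <- c(paste0("MRPL", c(1:4, 9:24, 27, 28, 30, 32:58)), "MRP63",
                  "GADD45GIP1")[1:52]

.MTSSU_GENES <- c("DAP3", paste0("MRPS", c(2, 5:7, 9:12, 14:18, 21:28,
                                           30, 31, 33:36)),
                  "MRPS18A", "MRPS18B", "CHCHD1", "AURKAIP1", "PTCD3")[1:30]

.COMPLEX_GENE_LISTS <- function() list(
  CI = .CI_GENES, CII = .CII_GENES, CIII = .CIII_GENES, CIV = .CIV_GENES,
  CV = .CV_GENES, mtLSU = .MTLSU_GENES, mtSSU = .MTSSU_GENES)

#' Packaged OXPHOS and mitoribosome subunit annotation
#'
#' Builds the gene -> (mitochondrial flag, complex, structural module) table
#' used throughout the package, mirroring a curated mitochondrial annotation
#' of the kind distributed with MitoCarta. Complex I genes carry their
#' N-module assignment where applicable. The same table is shipped as
#' `inst/extdata/oxphos_annotation.tsv`.
#'
#' @param layout optional named integer vector (complex -> subunit count) to
#'   truncate or extend each complex's gene list; counts beyond the curated
#'   list are padded with synthetic symbols (`CI_EXTRA1`, ...), which is only
#'   intended for simulation layouts.
#' @return a `data.frame` with columns `gene`, `is_mito`, `complex`,
#'   `module`.
#' @examples
#' annot <- oxphosAnnotation()
#' table(annot$complex)
#' @export
oxphosAnnotation <- function(layout = NULL) {
  lists <- .COMPLEX_GENE_LISTS()
  if (!is.null(layout)) {
    if (is.null(names(layout)) ||
        !all(names(layout) %in% names(lists)))
      stop("layout names must be among: ",
           paste(names(lists), collapse = ", "))
    lists <- lapply(names(layout), function(cx) {
      genes <- lists[[cx]]
      k <- layout[[cx]]
      if (k <= length(genes)) genes[seq_len(k)]
      else c(genes, paste0(cx, "_EXTRA", seq_len(k - length(genes))))
    })
    names(lists) <- names(layout)
  }
  gene <- unlist(lists, use.names = FALSE)
  complex <- rep(names(lists), lengths(lists))
  module <- ifelse(complex == "CI" & gene %in% .CI_N_MODULE,
                   "N-module", NA_character_)
  out <- data.frame(gene = gene, is_mito = TRUE, complex = complex,
                    module = module, stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene))
    stop("internal error: duplicate genes in annotation")
  out
}

.validateAnnotation <- function(annot) {
  annot <- as.data.frame(annot)
  need <- c("gene", "is_mito", "complex")
  if (!all(need %in% colnames(annot)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (!"module" %in% colnames(annot)) annot$module <- NA_character_
  annot$gene <- as.character(annot$gene)
  annot$is_mito <- as.logical(annot$is_mito)
  annot$complex <- as.character(annot$complex)
  annot$module <- as.character(annot$module)
  if (anyDuplicated(annot$gene))
    stop("duplicate gene in annotation: ",
         paste(unique(annot$gene[duplicated(annot$gene)]), collapse = ", "))
  bad <- setdiff(unique(annot$complex), .COMPLEX_LEVELS)
  if (length(bad))
    stop("unknown complex label(s): ", paste(bad, collapse = ", "))
  if (anyNA(annot$is_mito))
    stop("is_mito must be TRUE/FALSE")
  inconsistent <- annot$complex != "none" & !annot$is_mito
  if (any(inconsistent))
    stop("complex assigned but is_mito FALSE for: ",
         paste(annot$gene[inconsistent], collapse = ", "))
  annot
}
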