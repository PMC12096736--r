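#' Build a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning and defaults of every
#' parameter. The defaults emulate the study conditions the analysis is
#' designed for: a fibroblast-style DIA cohort of 5 controls and 3 proband
#' replicates with 20% biological CV, a MitoCarta-scale mitochondrial
#' proteome (1136 mito genes, 177 of them OXPHOS/mitoribosome subunits),
#' and abundance-dependent (MNAR) dropout.
#'
#' @param nBackground,nMitoBackground,complexLayout,nControls,nProbandReps,defects,moduleDefects,mitoContentFactor,cvBiological,baselineLogMean,baselineLogSD,detectionLogThreshold,dropoutSteepness,peptideRate,seed
#'   see [SimulationConfig-class].
#' @return a validated [SimulationConfig-class].
#' @examples
#' simulationConfig(defects = c(CI = 0.43), seed = 7)
#' @export
simulationConfig <- function(nBackground = 2000, nMitoBackground = 959,
                             complexLayout = c(CI = 44L, CII = 4L,
                                               CIII = 10L, CIV = 19L,
                                               CV = 18L, mtLSU = 52L,
                                               mtSSU = 30L),
                             nControls = 5, nProbandReps = 3,
                             defects = numeric(), moduleDefects = numeric(),
                             mitoContentFactor = 1, cvBiological = 0.2,
                             baselineLogMean = 6, baselineLogSD = 0.8,
                             detectionLogThreshold = 4.5,
                             dropoutSteepness = 2, peptideRate = 4,
                             seed = 1) {
  layout <- setNames(as.integer(complexLayout), names(complexLayout))
  new("SimulationConfig",
      nBackground = as.integer(nBackground),
      nMitoBackground = as.integer(nMitoBackground),
      complexLayout = layout,
      nControls = as.integer(nControls),
      nProbandReps = as.integer(nProbandReps),
      defects = defects, moduleDefects = moduleDefects,
      mitoContentFactor = mitoContentFactor,
      cvBiological = cvBiological,
      baselineLogMean = baselineLogMean, baselineLogSD = baselineLogSD,
      detectionLogThreshold = detectionLogThreshold,
      dropoutSteepness = dropoutSteepness, peptideRate = peptideRate,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      object@nBackground, "background +", object@nMitoBackground,
      "mito background +", sum(object@complexLayout), "subunit proteins;",
      object@nControls, "controls vs", object@nProbandReps,
      "proband reps\n")
  if (length(object@defects))
    cat("  defects:", paste(names(object@defects), "=",
                            object@defects, collapse = ", "), "\n")
  if (object@mitoContentFactor != 1)
    cat("  mito content factor:", object@mitoContentFactor, "\n")
  invisible(NULL)
})

#' Simulate a control/proband proteome experiment
#'
#' Draws per-protein baseline abundances from a wide log-normal
#' (`10^N(baselineLogMean, baselineLogSD)`), multiplies in log-normal
#' biological noise at `cvBiological`, scales proband subunits of each
#' defective complex by its residual fraction (structural-module residuals
#' override the complex residual for their member genes), additionally
#' scales all proband mitochondrial proteins by `mitoContentFactor`, drops
#' values through a logistic detection curve in log10 abundance (the
#' dominant missing-not-at-random mechanism of DIA data), and draws peptide
#' counts as Poisson variates linked to log10 abundance (minimum 1 where
#' detected, 0 where not). Fully reproducible from the seed.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional integer overriding `config@seed`.
#' @return a list with `experiment` (a designed [ProteinExperiment-class]),
#'   `annotation` (gene table with mito/complex/module columns), and
#'   `truth` (per-complex injected residuals, per-gene true proband
#'   fold-change, and the mito content factor).
#' @examples
#' sim <- simulateProteome(simulationConfig(defects = c(CI = 0.43)), seed = 1)
#' sim$truth$residuals
#' @export
simulateProteome <- function(config = simulationConfig(), seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(if (is.null(seed)) config@seed else as.integer(seed))

  layout <- config@complexLayout
  subunit_annot <- oxphosAnnotation(layout)
  n_bg <- config@nBackground
  n_mbg <- config@nMitoBackground
  annotation <- rbind(
    data.frame(gene = sprintf("BG%04d", seq_len(n_bg)),
               is_mito = FALSE, complex = "none", module = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(gene = sprintf("MTBG%04d", seq_len(n_mbg)),
               is_mito = TRUE, complex = "none", module = NA_character_,
               stringsAsFactors = FALSE),
    subunit_annot)
  n <- nrow(annotation)
  n_ctl <- config@nControls
  n_pro <- config@nProbandReps
  samples <- c(sprintf("Control_%d", seq_len(n_ctl)),
               sprintf("Proband_R%d", seq_len(n_pro)))
  group <- rep(c("control", "proband"), c(n_ctl, n_pro))

  baseline <- 10^rnorm(n, config@baselineLogMean, config@baselineLogSD)

  # true proband fold-change per gene: complex residual, overridden by a
  # structural-module residual, times the mito content factor
  fold <- rep(1, n)
  for (cx in names(config@defects))
    fold[annotation$complex == cx] <- config@defects[[cx]]
  for (md in names(config@moduleDefects))
    fold[!is.na(annotation$module) & annotation$module == md] <-
      config@moduleDefects[[md]]
  fold[annotation$is_mito] <- fold[annotation$is_mito] *
    config@mitoContentFactor

  sigma <- sqrt(log(1 + config@cvBiological^2))
  noise <- matrix(exp(rnorm(n * length(samples), 0, sigma)),
                  n, length(samples))
  expected <- baseline * cbind(matrix(1, n, n_ctl),
                               matrix(fold, n, n_pro))
  x <- expected * noise

  p_detect <- plogis(config@dropoutSteepness *
                       (log10(x) - config@detectionLogThreshold))
  detected <- runif(length(x)) <= p_detect
  peptides <- matrix(0L, n, length(samples))
  lambda <- config@peptideRate *
    pmax(0.25, log10(x) - config@detectionLogThreshold)
  peptides[detected] <- pmax(1L, rpois(sum(detected), lambda[detected]))
  x[!detected] <- NA_real_

  dimnames(x) <- dimnames(peptides) <- list(annotation$gene, samples)
  pe <- ProteinExperiment(x, peptides, gene = annotation$gene,
                          design = data.frame(sample = samples,
                                              group = group,
                                              batch = "sim_batch1"))
  residuals <- setNames(rep(1, length(layout)), names(layout))
  residuals[names(config@defects)] <- config@defects
  truth <- list(residuals = residuals,
                gene_fold_change = setNames(fold, annotation$gene),
                mito_content_factor = config@mitoContentFactor)
  list(experiment = pe, annotation = annotation, truth = truth)
}

#' Simulate a proteome with one protein absent in the proband
#'
#' Runs [simulateProteome()] and then removes the given gene's proband
#' values entirely while forcing its control peptide counts to at least 3,
#' emulating a protein confidently detected in controls but undetected in
#' the patient.
#'
#' @param config a [SimulationConfig-class].
#' @param gene a subunit gene present in the simulated annotation.
#' @param seed optional integer overriding `config@seed`.
#' @return as [simulateProteome()].
#' @export
simulateAbsentProtein <- function(config = simulationConfig(), gene,
                                  seed = NULL) {
  sim <- simulateProteome(config, seed = seed)
  pe <- sim$experiment
  idx <- which(geneSymbols(pe) == gene)
  if (!length(idx))
    stop("gene ", gene, " is not in the simulated layout")
  ab <- abundances(pe)
  pep <- peptideCounts(pe)
  pro <- probandSamples(pe)
  ctl <- controlSamples(pe)
  ab[idx, pro] <- NA_real_
  pep[idx, pro] <- 0L
  pep[idx, ctl] <- pmax(pep[idx, ctl], 3L)
  SummarizedExperiment::assay(pe, "abundance") <- ab
  SummarizedExperiment::assay(pe, "peptides") <- pep
  sim$experiment <- pe
  sim$truth$absent_gene <- gene
  sim
}
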