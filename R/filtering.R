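#' Cohort preset filtering policies
#'
#' Returns the clean-up policy used for each cohort type:
#' \describe{
#'   \item{VC}{validation-style cohort: peptide evidence >= 2 in each group;
#'     >= 3 valid values in controls and >= 2 in probands (count mode).}
#'   \item{KC}{knockout-style cohort: peptide rule; >= 2 valid values in
#'     each group (count mode).}
#'   \item{UDP}{undiagnosed-proband cohort: peptide rule; >= 70% valid
#'     values in each group (fraction mode, ceiling semantics).}
#'   \item{SC}{supporting cohort: as UDP.}
#' }
#'
#' @param cohort one of `"VC"`, `"KC"`, `"UDP"`, `"SC"`.
#' @return a [FilterPolicy-class].
#' @examples
#' presetPolicy("VC")
#' @export
presetPolicy <- function(cohort = c("VC", "KC", "UDP", "SC")) {
  cohort <- match.arg(cohort)
  switch(cohort,
         VC = filterPolicy(2, 3, 2, "count"),
         KC = filterPolicy(2, 2, 2, "count"),
         UDP = filterPolicy(2, 0.7, 0.7, "fraction"),
         SC = filterPolicy(2, 0.7, 0.7, "fraction"))
}

.validThreshold <- function(threshold, n, mode) {
  if (mode == "fraction") ceiling(threshold * n) else threshold
}

#' Apply a cohort filtering policy
#'
#' Two-stage clean-up. Peptide rule: a protein is kept when its maximum
#' per-sample peptide count reaches `minPeptides` within the control group
#' AND within the proband group (proteins seen with only a single peptide
#' throughout either group are removed at the default of 2). Valid-value
#' rule: the number of non-missing quantities per group must reach the
#' policy thresholds; in fraction mode, "at least 70%" of 5 controls means
#' >= ceiling(3.5) = 4. A filter report (proteins in, removed by each rule,
#' proteins out) is stored in the result's metadata ([filterReport()]).
#' Abundance values are never modified, only row membership.
#'
#' @param x a [ProteinExperiment-class] with a sample design attached.
#' @param policy a [FilterPolicy-class]; defaults to the VC preset.
#' @return the filtered [ProteinExperiment-class].
#' @examples
#' sim <- simulateProteome(simulationConfig(seed = 1))
#' filtered <- applyFilter(sim$experiment, presetPolicy("VC"))
#' filterReport(filtered)
#' @export
applyFilter <- function(x, policy = presetPolicy("VC")) {
  stopifnot(is(x, "ProteinExperiment"), is(policy, "FilterPolicy"))
  validObject(policy)
  .requireDesign(x)
  ctl <- controlSamples(x)
  pro <- probandSamples(x)
  if (policy@mode == "count" &&
      (policy@minValidControls > length(ctl) ||
       policy@minValidProbands > length(pro)))
    stop("count-mode thresholds exceed group sizes (",
         length(ctl), " controls, ", length(pro), " probands)")

  ab <- abundances(x)
  pep <- peptideCounts(x)
  pass_pep <-
    apply(pep[, ctl, drop = FALSE], 1L, max) >= policy@minPeptides &
    apply(pep[, pro, drop = FALSE], 1L, max) >= policy@minPeptides
  need_ctl <- .validThreshold(policy@minValidControls, length(ctl),
                              policy@mode)
  need_pro <- .validThreshold(policy@minValidProbands, length(pro),
                              policy@mode)
  pass_valid <-
    rowSums(!is.na(ab[, ctl, drop = FALSE])) >= need_ctl &
    rowSums(!is.na(ab[, pro, drop = FALSE])) >= need_pro

  keep <- pass_pep & pass_valid
  report <- list(
    n_in = nrow(x),
    removed_peptide = sum(!pass_pep),
    removed_valid = sum(pass_pep & !pass_valid),
    n_out = sum(keep),
    policy = sprintf("peptides>=%d; valid %s >=%s ctl / >=%s pro",
                     policy@minPeptides, policy@mode,
                     format(policy@minValidControls),
                     format(policy@minValidProbands)))
  out <- x[keep, ]
  S4Vectors::metadata(out)$filter_report <- report
  out
}
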