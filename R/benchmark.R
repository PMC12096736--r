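#' Classify a respiratory chain enzymology result
#'
#' Bernier-style classification of complex activity (as % of the control
#' mean, CS-ratio): a definite defect below `majorLt` (default 30%, the
#' major criterion), a probable defect below `minorLt` (minor criterion;
#' the 40% default comes from the clinical criteria literature and is
#' exposed because no single value is universal), otherwise none.
#' Inequalities are strict, so 30% is not a definite defect.
#'
#' @param activityPct numeric vector of activities (>= 0).
#' @param majorLt,minorLt thresholds, `majorLt < minorLt`.
#' @return character vector: `"definite"`, `"probable"` or `"none"`.
#' @examples
#' classifyRCE(c(25, 30, 35, 80))
#' @export
classifyRCE <- function(activityPct, majorLt = 30, minorLt = 40) {
  if (majorLt >= minorLt) stop("need majorLt < minorLt")
  if (any(is.na(activityPct)) || any(activityPct < 0))
    stop("activityPct must be non-negative")
  ifelse(activityPct < majorLt, "definite",
         ifelse(activityPct < minorLt, "probable", "none"))
}

#' Build benchmark pairs from RCE and RCA tables
#'
#' Default pairing for benchmarking proteomic RCA against enzymology: one
#' point per line per genetically expected complex among CI, CIII and CIV
#' (complexes whose activity enzymology measures directly and RCA
#' quantifies; CII is the usual internal control and CV has no standard
#' activity assay). Lines whose expected complex is outside that set
#' contribute a point for each expected complex that is inside it. An
#' explicit, externally constructed pairs table can be passed straight to
#' [benchmarkRCA()] instead.
#'
#' @param rce `data.frame` with `line_id`, `complex`, `activity_pct` (and
#'   optionally `tissue` to filter on).
#' @param rca `data.frame` with `line_id`, `complex`, `rca_pct`.
#' @param expected `data.frame` with `line_id`, `complex` marking the
#'   genetically expected complex(es) per line.
#' @param complexes complexes eligible for pairing.
#' @param tissue optional tissue to restrict the RCE table to.
#' @return a `data.frame` of pairs: `line_id`, `complex`, `rce_pct`,
#'   `rca_pct`, `expected_defect`.
#' @export
makeBenchmarkPairs <- function(rce, rca, expected,
                               complexes = c("CI", "CIII", "CIV"),
                               tissue = NULL) {
  if (!is.null(tissue) && "tissue" %in% colnames(rce))
    rce <- rce[rce$tissue == tissue, , drop = FALSE]
  key <- function(d) paste(d$line_id, d$complex)
  pairs <- merge(
    data.frame(line_id = rce$line_id, complex = rce$complex,
               rce_pct = rce$activity_pct, stringsAsFactors = FALSE),
    data.frame(line_id = rca$line_id, complex = rca$complex,
               rca_pct = rca$rca_pct, stringsAsFactors = FALSE),
    by = c("line_id", "complex"))
  pairs <- pairs[pairs$complex %in% complexes, , drop = FALSE]
  pairs$expected_defect <- key(pairs) %in% key(expected)
  pairs <- pairs[pairs$expected_defect, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Benchmark RCA calls against enzymology
#'
#' Classifies each pair's RCA percentage (via [classifyRCA()]) and RCE
#' activity (via [classifyRCE()]), summarises per line the most severe call
#' across its expected complexes, and reports counts, fractions and the
#' Pearson correlation between the RCA and RCE percentages over all pairs.
#'
#' @param pairs `data.frame` with `line_id`, `complex`, `rce_pct`,
#'   `rca_pct` (>= 2 rows); an `expected_defect` logical column restricts
#'   the per-line summaries to expected complexes (default all).
#' @param criteria a [DefectCriteria-class] for the RCA side.
#' @param majorLt,minorLt RCE thresholds (see [classifyRCE()]).
#' @return a list: `n_lines`, `n_pairs`, `rca_counts`, `rca_fractions`,
#'   `rce_counts`, `rce_fractions`, `pearson` (list `r`, `p`, `n`, possibly
#'   `reason` when undefined), and the annotated `pairs` table.
#' @export
benchmarkRCA <- function(pairs, criteria = defectCriteria(),
                         majorLt = 30, minorLt = 40) {
  pairs <- as.data.frame(pairs)
  need <- c("line_id", "complex", "rce_pct", "rca_pct")
  if (!all(need %in% colnames(pairs)))
    stop("pairs need columns: ", paste(need, collapse = ", "))
  if (nrow(pairs) < 2L) stop("need >= 2 pairs")
  if (!"expected_defect" %in% colnames(pairs))
    pairs$expected_defect <- TRUE
  pairs$rca_call <- classifyRCA(pairs$rca_pct, criteria = criteria)
  pairs$rce_call <- classifyRCE(pairs$rce_pct, majorLt, minorLt)

  worst <- function(calls, levels) levels[min(match(calls, levels))]
  exp_pairs <- pairs[pairs$expected_defect, , drop = FALSE]
  rca_line <- vapply(split(exp_pairs$rca_call, exp_pairs$line_id),
                     worst, character(1),
                     levels = c("major", "minor", "none"))
  rce_line <- vapply(split(exp_pairs$rce_call, exp_pairs$line_id),
                     worst, character(1),
                     levels = c("definite", "probable", "none"))
  rca_counts <- table(factor(rca_line, c("major", "minor", "none")))
  rce_counts <- table(factor(rce_line, c("definite", "probable", "none")))

  list(n_lines = length(rca_line), n_pairs = nrow(pairs),
       rca_counts = as.list(rca_counts),
       rca_fractions = as.list(rca_counts / sum(rca_counts)),
       rce_counts = as.list(rce_counts),
       rce_fractions = as.list(rce_counts / sum(rce_counts)),
       pearson = .pearson(pairs$rce_pct, pairs$rca_pct),
       pairs = pairs)
}
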