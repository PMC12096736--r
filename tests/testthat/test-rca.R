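annot_small <- function(genes, complex = "CI", extra_mito = character()) {
  rbind(
    data.frame(gene = genes, is_mito = TRUE, complex = complex,
               module = NA_character_),
    if (length(extra_mito))
      data.frame(gene = extra_mito, is_mito = TRUE, complex = "none",
                 module = NA_character_))
}

test_that("equal group mito means give factor 1 and an unchanged matrix", {
  ab <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
               dimnames = list(NULL, c("C1", "P1")))
  pe <- toy_experiment(ab, gene = c("M1", "M2", "M3"), n_ctl = 1, n_pro = 1)
  out <- suppressWarnings(mitoCorrect(pe, annot_small(c("M1", "M2", "M3"))))
  expect_equal(mitoCorrection(out)$factor, 1)
  expect_identical(abundances(out), abundances(pe))
})

test_that("a uniform 2x proband content shift yields factor 0.5 and restores controls", {
  set.seed(3)
  base <- 10^runif(20, 4, 6)
  ab <- cbind(C1 = base, C2 = base * 1.0, P1 = base * 2, P2 = base * 2)
  genes <- paste0("M", 1:20)
  pe <- toy_experiment(ab, gene = genes, n_ctl = 2, n_pro = 2)
  out <- mitoCorrect(pe, annot_small(genes))
  expect_equal(mitoCorrection(out)$factor, 0.5, tolerance = 1e-12)
  expect_equal(abundances(out)[, "P1"], abundances(pe)[, "C1"],
               tolerance = 1e-12)
})

test_that("the correction factor matches the brute-force oracle and equalises group mito means", {
  pe <- random_experiment(7, n_prot = 120, n_ctl = 4, n_pro = 3, miss = 0.1)
  genes <- geneSymbols(pe)
  mito <- genes[1:40]
  annot <- rbind(annot_small(mito, "none"),
                 data.frame(gene = genes[41:120], is_mito = FALSE,
                            complex = "none", module = NA_character_))
  out <- mitoCorrect(pe, annot)
  mc <- mitoCorrection(out)
  groups <- unname(sampleGroups(pe))
  expect_equal(mc$factor,
               oracle_mito_factor(abundances(pe), groups,
                                  genes %in% mito),
               tolerance = 1e-12)
  # recomputed group mito means agree after correction
  per_sample <- colMeans(abundances(out)[genes %in% mito, ], na.rm = TRUE)
  expect_equal(mean(per_sample[controlSamples(out)]),
               mean(per_sample[probandSamples(out)]), tolerance = 1e-9)
  # per-sample mode equalises each proband sample individually
  ps <- mitoCorrect(pe, annot, perSample = TRUE)
  per_sample2 <- colMeans(abundances(ps)[genes %in% mito, ], na.rm = TRUE)
  ctl_mean <- mean(per_sample2[controlSamples(ps)])
  for (s in probandSamples(ps))
    expect_equal(unname(per_sample2[s]), ctl_mean, tolerance = 1e-9)
})

test_that("mito correction errors without mito proteins or a zero group mean", {
  pe <- toy_experiment(matrix(10, 2, 4))
  annot <- data.frame(gene = c("G1", "G2"), is_mito = FALSE,
                      complex = "none", module = NA_character_)
  expect_error(mitoCorrect(pe, annot), "no mitochondrial proteins")
  ab <- matrix(c(10, NA, 10, NA), 1, 4,
               dimnames = list("G1", c("C1", "C2", "P1", "P2")))
  pe2 <- toy_experiment(ab, gene = "G1", n_ctl = 2, n_pro = 2)
  expect_warning(
    expect_error(mitoCorrect(pe2, annot_small("G1")), "zero or undefined"),
    "unstable")
})

test_that("identical groups give RCA 100, p near 1 and no defect call", {
  vals <- 10^seq(3, 5, length.out = 8)
  ab <- matrix(rep(vals, 4), 8, 4,
               dimnames = list(NULL, c("C1", "C2", "P1", "P2")))
  genes <- paste0("S", 1:8)
  pe <- toy_experiment(ab, gene = genes, n_ctl = 2, n_pro = 2)
  res <- computeRCA(pe, annot_small(genes), "CI")
  expect_equal(rcaPct(res), 100, tolerance = 1e-12)
  expect_gte(res@pValue, 0.99)
  expect_identical(defectCall(res), "none")
})

test_that("two halved subunits give RCA exactly 50 and excluded subunits are logged", {
  ab <- rbind(S1 = c(100, 100, 50, 50),
              S2 = c(200, 200, 100, 100),
              S3 = c(300, 300, NA, NA))   # proband mean missing -> excluded
  colnames(ab) <- c("C1", "C2", "P1", "P2")
  pe <- toy_experiment(ab, gene = rownames(ab), n_ctl = 2, n_pro = 2)
  expect_message(res <- computeRCA(pe, annot_small(rownames(ab)), "CI"),
                 "S3")
  expect_equal(rcaPct(res), 50, tolerance = 1e-12)
  expect_equal(res@nSubunits, 2L)
  expect_identical(res@excludedSubunits, "S3")
  expect_identical(defectCall(res), "major")
  expect_equal(unname(subunitRatios(res)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("RCA matches a brute-force recomputation on a simulated complex", {
  sim <- simulateProteome(simulationConfig(defects = c(CI = 0.43)), seed = 1)
  pe <- mitoCorrect(applyFilter(sim$experiment, presetPolicy("VC")),
                    sim$annotation)
  res <- computeRCA(pe, sim$annotation, "CI")
  genes <- geneSymbols(pe)
  subunit_rows <- which(genes %in%
    sim$annotation$gene[sim$annotation$complex == "CI"])
  expect_equal(rcaPct(res),
               oracle_rca(abundances(pe), unname(sampleGroups(pe)),
                          subunit_rows),
               tolerance = 1e-9)
  expect_true(rcaPct(res) >= 38 && rcaPct(res) <= 48)
})

test_that("the log10-unlog path equals the direct ratio to 1e-12 relative", {
  set.seed(9)
  q <- 10^runif(500, -2, 8)
  c0 <- 10^runif(500, -2, 8)
  expect_equal(10^(log10(q) - log10(c0)), q / c0, tolerance = 1e-12)
  # and on a computed result: ratios equal direct mean ratios
  ab <- rbind(S1 = c(100, 120, 40, 44), S2 = c(1000, 900, 470, 480))
  colnames(ab) <- c("C1", "C2", "P1", "P2")
  pe <- toy_experiment(ab, gene = rownames(ab), n_ctl = 2, n_pro = 2)
  res <- computeRCA(pe, annot_small(rownames(ab)), "CI")
  direct <- c(mean(c(40, 44)) / mean(c(100, 120)),
              mean(c(470, 480)) / mean(c(1000, 900)))
  expect_equal(unname(subunitRatios(res)), direct, tolerance = 1e-12)
})

test_that("global proband scaling is absorbed by the mito correction", {
  sim <- simulateProteome(simulationConfig(defects = c(CIII = 0.6)),
                          seed = 5)
  pe0 <- applyFilter(sim$experiment, presetPolicy("VC"))
  run <- function(pe) {
    corrected <- mitoCorrect(pe, sim$annotation)
    vapply(c("CI", "CIII", "CIV"), function(cx)
      rcaPct(computeRCA(corrected, sim$annotation, cx)), numeric(1))
  }
  base <- run(pe0)
  for (c_scale in c(0.25, 3)) {
    scaled <- pe0
    ab <- abundances(scaled)
    ab[, probandSamples(scaled)] <- ab[, probandSamples(scaled)] * c_scale
    SummarizedExperiment::assay(scaled, "abundance") <- ab
    expect_equal(run(scaled), base, tolerance = 1e-9)
  }
})

test_that("dispersion bands are t-based confidence intervals or SD bands", {
  ab <- rbind(S1 = c(100, 110, 90, 50, 60),
              S2 = c(200, 190, 210, 80, 120))
  colnames(ab) <- c("C1", "C2", "C3", "P1", "P2")
  pe <- toy_experiment(ab, gene = rownames(ab), n_ctl = 3, n_pro = 2)
  annot <- annot_small(rownames(ab))
  ci <- computeRCA(pe, annot, "CI", dispersion = "ci95")
  sd_ <- computeRCA(pe, annot, "CI", dispersion = "sd")
  rel <- ci@probandRelValues
  m <- mean(rel); n <- length(rel)
  half <- qt(0.975, n - 1) * sd(rel) / sqrt(n)
  expect_equal(c(ci@dispersionLow, ci@dispersionHigh),
               100 * c(m - half, m + half), tolerance = 1e-12)
  expect_equal(c(sd_@dispersionLow, sd_@dispersionHigh),
               100 * c(m - sd(rel), m + sd(rel)), tolerance = 1e-12)
  expect_equal(rcaPct(ci), rcaPct(sd_))
})

test_that("defect classification applies inclusive thresholds and the absence upgrade", {
  expect_identical(classifyRCA(43), "major")
  expect_identical(classifyRCA(71), "minor")
  expect_identical(classifyRCA(104), "none")
  expect_identical(classifyRCA(70, targetAbsent = TRUE), "major")
  # boundaries inclusive
  expect_identical(classifyRCA(65), "major")
  expect_identical(classifyRCA(75), "minor")
  expect_identical(classifyRCA(75, targetAbsent = TRUE), "major")
  expect_identical(classifyRCA(75.0001, targetAbsent = TRUE), "none")
  expect_identical(classifyRCA(0), "major")
  expect_error(classifyRCA(-1), "non-negative")
  # vectorised and total over a grid
  grid <- seq(0, 120, by = 0.5)
  calls <- classifyRCA(grid)
  expect_identical(calls, ifelse(grid <= 65, "major",
                                 ifelse(grid <= 75, "minor", "none")))
  # custom criteria flow through
  strict <- defectCriteria(majorMaxPct = 50, majorWithAbsentMaxPct = 60,
                           minorMaxPct = 60)
  expect_identical(classifyRCA(55, criteria = strict), "minor")
})

test_that("absent-protein evidence requires full proband missingness and control peptides", {
  ab <- rbind(GENE = c(1000, 1100, NA, NA),
              OTHER = c(1000, 1100, 900, 950))
  colnames(ab) <- c("C1", "C2", "P1", "P2")
  pep <- matrix(0L, 2, 4, dimnames = dimnames(ab))
  pep["GENE", c("C1", "C2")] <- c(14L, 18L)
  pep["OTHER", ] <- 5L
  pe <- toy_experiment(ab, pep, gene = rownames(ab), n_ctl = 2, n_pro = 2)
  expect_true(detectAbsentProtein(pe, "GENE"))
  expect_false(detectAbsentProtein(pe, "OTHER"))
  expect_message(expect_false(detectAbsentProtein(pe, "MISSING")),
                 "not present")
  # strictly-greater evidence threshold
  pep["GENE", c("C1", "C2")] <- 2L
  pe2 <- toy_experiment(ab, pep, gene = rownames(ab), n_ctl = 2, n_pro = 2)
  expect_false(detectAbsentProtein(pe2, "GENE"))
})

test_that("rcaTable reports every requested complex and tolerates empty ones", {
  sim <- simulateProteome(simulationConfig(), seed = 2)
  pe <- mitoCorrect(applyFilter(sim$experiment, presetPolicy("VC")),
                    sim$annotation)
  tab <- rcaTable(pe, sim$annotation)
  expect_setequal(tab$complex,
                  c("CI", "CII", "CIII", "CIV", "CV", "mtLSU", "mtSSU"))
  expect_true(all(is.finite(tab$rca_pct)))
  expect_true(all(tab$n_subunits >= 1))
})
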