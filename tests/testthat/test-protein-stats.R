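test_that("a proband at the control median scores 100% and 0.0 SD", {
  ab <- rbind(G1 = c(1000, 1200, 800, 1000))
  colnames(ab) <- c("C1", "C2", "C3", "P1")
  pe <- toy_experiment(ab, gene = "G1", n_ctl = 3, n_pro = 1)
  res <- proteinRange(pe, "G1")
  expect_equal(res$pct_of_control_median, 100, tolerance = 1e-12)
  expect_identical(res$sd_from_median, 0)
  expect_equal(sort(unname(res$control_values_pct)), c(80, 100, 120),
               tolerance = 1e-12)
})

test_that("range scoring reproduces the hand-computed example and the oracle", {
  # controls at log2 10, 10.5, 9.5; proband at log2 9:
  # fc = -1, s = sqrt((0 + 0.25 + 0.25)/3), score = -1/s = -2.449 -> -2.4
  ctl <- 2^c(10, 10.5, 9.5)
  ab <- rbind(G1 = c(ctl, 2^9))
  colnames(ab) <- c("C1", "C2", "C3", "P1")
  pe <- toy_experiment(ab, gene = "G1", n_ctl = 3, n_pro = 1)
  res <- proteinRange(pe, "G1")
  expect_equal(res$pct_of_control_median, 50, tolerance = 1e-9)
  expect_identical(res$sd_from_median, -2.4)
  oracle <- oracle_range(ctl, 2^9)
  expect_equal(res$pct_of_control_median, oracle$pct, tolerance = 1e-9)
  expect_identical(res$sd_from_median, oracle$sd)
  # rounding is to exactly one decimal
  expect_identical(res$sd_from_median, round(res$log2_fc / res$sd_log2, 1))
  # the invariant pct = 100 * 2^(log2 pm - log2 cm)
  expect_equal(res$pct_of_control_median, 100 * 2^res$log2_fc,
               tolerance = 1e-9)
})

test_that("range scoring guards its preconditions and supports SD config alternatives", {
  ab <- rbind(G1 = c(1000, NA, NA, 500))
  colnames(ab) <- c("C1", "C2", "C3", "P1")
  pe <- toy_experiment(ab, gene = "G1", n_ctl = 3, n_pro = 1)
  expect_error(proteinRange(pe, "G1"), ">= 2 control")
  expect_error(proteinRange(pe, "NOPE"), "not present")

  ab2 <- rbind(G1 = c(2^10, 2^11, 2^9.2, 2^8))
  colnames(ab2) <- c("C1", "C2", "C3", "P1")
  pe2 <- toy_experiment(ab2, gene = "G1", n_ctl = 3, n_pro = 1)
  pop <- proteinRange(pe2, "G1")
  sam <- proteinRange(pe2, "G1", sdDivisor = "sample")
  expect_gt(pop$sd_log2 * sqrt(3 / 2), sam$sd_log2 - 1e-12)
  about_mean <- proteinRange(pe2, "G1", sdAbout = "mean")
  expect_false(isTRUE(all.equal(pop$sd_log2, about_mean$sd_log2)))
})

test_that("volcano statistics: identical groups are null, forced halving shows log2 fc -1", {
  vals <- 10^seq(3, 6, length.out = 10)
  ab <- matrix(rep(vals, 6), 10, 6,
               dimnames = list(NULL, c("C1", "C2", "C3", "P1", "P2", "P3")))
  pe <- toy_experiment(ab, n_ctl = 3, n_pro = 3)
  v <- volcanoStats(pe)
  expect_true(all(v$log2_fc == 0))
  expect_true(all(v$p_value >= 0.99))

  set.seed(4)
  eps <- function(n) exp(rnorm(n, 0, 1e-4))
  ab2 <- rbind(HALVED = c(1000 * eps(3), 500 * eps(3)),
               FLAT = c(1000 * eps(3), 1000 * eps(3)))
  colnames(ab2) <- colnames(ab)[1:6]
  pe2 <- toy_experiment(ab2, gene = rownames(ab2), n_ctl = 3, n_pro = 3)
  v2 <- volcanoStats(pe2)
  expect_equal(v2$log2_fc[v2$gene == "HALVED"], -1, tolerance = 1e-3)
  expect_lt(v2$p_value[v2$gene == "HALVED"], 0.001)
})

test_that("a simulated CI knockdown moves most CI subunits below log2 fc -1", {
  hits <- vapply(1:10, function(seed) {
    sim <- simulateProteome(simulationConfig(defects = c(CI = 0.4)),
                            seed = 100 + seed)
    pe <- applyFilter(sim$experiment, presetPolicy("VC"))
    v <- volcanoStats(mitoCorrect(pe, sim$annotation))
    ci_genes <- sim$annotation$gene[sim$annotation$complex == "CI"]
    rows <- v[v$gene %in% ci_genes, ]
    mean(rows$log2_fc < -1)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("fold-change correlation is exact on self, negation and a closed-form toy", {
  tab <- data.frame(gene = c("A", "B", "C", "D"),
                    log2_fc = c(-2, -0.5, 0.3, 1.2))
  expect_equal(fcCorrelation(tab, tab)$r, 1, tolerance = 1e-12)
  neg <- transform(tab, log2_fc = -log2_fc)
  expect_equal(fcCorrelation(tab, neg)$r, -1, tolerance = 1e-12)

  other <- data.frame(gene = c("B", "C", "D", "E"),
                      log2_fc = c(0.4, -0.1, 0.9, 5))
  res <- fcCorrelation(tab, other)
  expect_equal(res$n, 3L)
  expect_equal(res$r, oracle_pearson(c(-0.5, 0.3, 1.2), c(0.4, -0.1, 0.9)),
               tolerance = 1e-12)
  # subset restriction and the shared-gene guard
  expect_error(fcCorrelation(tab, other, subset = c("B", "C")),
               ">= 3 shared genes")
})

test_that("Pearson agrees with the closed form over a grid of 3-point inputs", {
  grid <- expand.grid(a2 = c(-1, 0, 2), a3 = c(1, 3),
                      b1 = c(-2, 0), b2 = c(0.5, 1), b3 = c(2, 4))
  for (i in seq_len(nrow(grid))) {
    a <- c(0, grid$a2[i], grid$a3[i])
    b <- c(grid$b1[i], grid$b2[i], grid$b3[i])
    if (sd(a) == 0 || sd(b) == 0) next
    tab_a <- data.frame(gene = c("X", "Y", "Z"), log2_fc = a)
    tab_b <- data.frame(gene = c("X", "Y", "Z"), log2_fc = b)
    expect_equal(fcCorrelation(tab_a, tab_b)$r, oracle_pearson(a, b),
                 tolerance = 1e-9)
  }
})

test_that("range percent agrees with volcano fold-change when medians equal means", {
  # duplicated values per group: median = mean, so the two statistics match
  ab <- rbind(G1 = c(1000, 1000, 700, 700), G2 = c(500, 500, 600, 600))
  colnames(ab) <- c("C1", "C2", "P1", "P2")
  pe <- toy_experiment(ab, gene = rownames(ab), n_ctl = 2, n_pro = 2)
  v <- volcanoStats(pe)
  for (g in rownames(ab)) {
    rng <- proteinRange(pe, g)
    expect_equal(rng$pct_of_control_median,
                 100 * 2^v$log2_fc[v$gene == g], tolerance = 1e-9)
  }
})

test_that("panel coverage is exact set arithmetic on upper-cased symbols", {
  expect_equal(panelCoverage(c("a", "b", "c"), c("A", "B", "C")), 100)
  expect_equal(panelCoverage(c("A", "B"), c("X", "Y")), 0)
  expect_equal(panelCoverage(c("A", "B", "C"), c("B", "C", "D", "E")), 50)
  expect_error(panelCoverage(c("A"), character()), "empty")
  # duplicates in the panel do not inflate the denominator
  expect_equal(panelCoverage(c("A"), c("A", "a", "B")), 50)
})

test_that("label-permuted null volcano yields about 5% of proteins at p < 0.05", {
  fprs <- vapply(1:8, function(seed) {
    sim <- simulateProteome(
      simulationConfig(nBackground = 1200, nMitoBackground = 100),
      seed = 200 + seed)
    pe <- sim$experiment
    set.seed(seed)
    perm <- sample(colnames(pe))
    design <- data.frame(sample = perm,
                         group = rep(c("control", "proband"), c(5, 3)))
    pe <- setSampleDesign(pe, design)
    v <- volcanoStats(applyFilter(pe, presetPolicy("KC")))
    mean(v$p_value < 0.05)
  }, numeric(1))
  expect_gt(mean(fprs), 0.03)
  expect_lt(mean(fprs), 0.07)
})
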