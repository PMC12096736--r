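# Small in-code fixtures shared across tests.

toy_design <- function(n_ctl = 2, n_pro = 2) {
  data.frame(sample = c(paste0("C", seq_len(n_ctl)),
                        paste0("P", seq_len(n_pro))),
             group = rep(c("control", "proband"), c(n_ctl, n_pro)))
}

# deterministic toy experiment: proteins x (controls, probands)
toy_experiment <- function(ab, pep = NULL, gene = NULL,
                           n_ctl = NULL, n_pro = NULL) {
  ab <- as.matrix(ab)
  if (is.null(n_ctl)) n_ctl <- ceiling(ncol(ab) / 2)
  if (is.null(n_pro)) n_pro <- ncol(ab) - n_ctl
  colnames(ab) <- c(paste0("C", seq_len(n_ctl)), paste0("P", seq_len(n_pro)))
  if (is.null(gene)) gene <- paste0("G", seq_len(nrow(ab)))
  rownames(ab) <- gene
  if (is.null(pep)) pep <- matrix(3L, nrow(ab), ncol(ab))
  ProteinExperiment(ab, pep, gene = gene,
                    design = toy_design(n_ctl, n_pro))
}

# random matrix with missingness for property tests
random_experiment <- function(seed, n_prot = 200, n_ctl = 5, n_pro = 3,
                              miss = 0.15) {
  set.seed(seed)
  n <- n_prot * (n_ctl + n_pro)
  ab <- matrix(10^rnorm(n, 5, 1), n_prot, n_ctl + n_pro)
  ab[runif(n) < miss] <- NA
  pep <- matrix(rpois(n, 3), n_prot, n_ctl + n_pro)
  toy_experiment(ab, pep, n_ctl = n_ctl, n_pro = n_pro)
}

write_pivot_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
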