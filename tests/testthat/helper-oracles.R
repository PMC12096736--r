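# Independent brute-force re-implementations used as oracles. These follow
# the written rules literally with explicit loops and stay independent of the
# package internals they check.

oracle_filter <- function(ab, pep, groups, min_pep, min_ctl, min_pro, mode) {
  ctl <- which(groups == "control")
  pro <- which(groups == "proband")
  keep <- logical(nrow(ab))
  removed_pep <- removed_valid <- 0L
  for (i in seq_len(nrow(ab))) {
    pass_pep <- max(pep[i, ctl]) >= min_pep && max(pep[i, pro]) >= min_pep
    nc <- sum(!is.na(ab[i, ctl]))
    np <- sum(!is.na(ab[i, pro]))
    if (mode == "fraction") {
      pass_valid <- nc >= ceiling(min_ctl * length(ctl)) &&
        np >= ceiling(min_pro * length(pro))
    } else {
      pass_valid <- nc >= min_ctl && np >= min_pro
    }
    if (!pass_pep) removed_pep <- removed_pep + 1L
    else if (!pass_valid) removed_valid <- removed_valid + 1L
    keep[i] <- pass_pep && pass_valid
  }
  list(keep = keep, removed_pep = removed_pep, removed_valid = removed_valid)
}

oracle_mito_factor <- function(ab, groups, is_mito) {
  per_sample <- numeric(ncol(ab))
  for (s in seq_len(ncol(ab))) {
    v <- ab[is_mito, s]
    per_sample[s] <- mean(v[!is.na(v)])
  }
  mean(per_sample[groups == "control"]) /
    mean(per_sample[groups == "proband"])
}

oracle_rca <- function(ab, groups, subunit_rows) {
  ctl <- which(groups == "control")
  pro <- which(groups == "proband")
  ratios <- c()
  for (i in subunit_rows) {
    cv <- ab[i, ctl]; qv <- ab[i, pro]
    cm <- mean(cv[!is.na(cv)])
    qm <- mean(qv[!is.na(qv)])
    if (is.finite(cm) && cm > 0 && is.finite(qm) && qm > 0)
      ratios <- c(ratios, 10^(log10(qm) - log10(cm)))
  }
  100 * mean(ratios)
}

oracle_range <- function(ctl_values, pro_values) {
  cm <- median(ctl_values)
  pm <- median(pro_values)
  fc <- log2(pm) - log2(cm)
  s <- sqrt(mean((log2(ctl_values) - log2(cm))^2))
  list(pct = 100 * 2^fc, sd = round(fc / s, 1))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}
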