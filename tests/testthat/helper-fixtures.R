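# Shared fixtures, built in code.

fixture_coeffs <- function() default_bcsc_coefficients()
fixture_thresholds <- function() default_thresholds()

# tiny deterministic two-SNP panel matching the hand-worked scoring example:
# SNP1 OR=2 p=0.3, SNP2 OR=0.8 p=0.5 (same parameters in every group)
tiny_panel <- function(ors = c(2, 0.8), freqs = c(0.3, 0.5)) {
  n <- length(ors)
  x <- data.frame(
    rsid = sprintf("rs%d", seq_len(n)),
    chrom = as.character(seq_len(n)), pos = 1000L * seq_len(n),
    risk_allele = rep("A", n), other_allele = rep("G", n),
    stringsAsFactors = FALSE
  )
  for (g in prs_groups()) {
    x[[paste0("or_", g)]] <- ors
    x[[paste0("freq_", g)]] <- freqs
  }
  as_snp_panel(x)
}

# Published-count reassignment tables: cell values constrained by the printed
# totals and reassignment counts of the trial's year-1 analysis (row/column
# marginals beyond those constraints are a synthetic reconstruction, since
# the full supplementary tables are not reproduced here).
recon_table_40_49 <- function() {
  lv <- c("none_or_stop", "biennial", "annual_risk", "q6mo_alternating")
  m <- rbind(c(3975, 460, 21, 10),
             c(150, 480, 50, 20),
             c(5, 60, 420, 15),
             c(0, 0, 3, 83))
  dimnames(m) <- list(lv, lv)
  reassignment_table(m, age_stratum = c(40, 49))
}

recon_table_50_74 <- function() {
  lv <- c("none_or_stop", "biennial", "annual_risk", "q6mo_alternating")
  m <- rbind(c(370, 30, 0, 0),
             c(40, 6330, 100, 30),
             c(0, 436, 99, 140),
             c(0, 10, 15, 124))
  dimnames(m) <- list(lv, lv)
  reassignment_table(m, age_stratum = c(50, 74))
}

# exhaustive two-sample Wilcoxon oracle: enumerate all C(n1+n2, n1) rank
# splits of the pooled sample, two-sided p for the rank-sum of group 1
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
  mu <- n1 * length(y) / 2
  splits <- utils::combn(length(pooled), n1)
  ws <- apply(splits, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# brute-force pair-count oracle for cross-tabs
pair_count_oracle <- function(a, b, levels) {
  m <- matrix(0, length(levels), length(levels),
              dimnames = list(levels, levels))
  for (i in seq_along(a)) m[a[i], b[i]] <- m[a[i], b[i]] + 1
  m
}
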