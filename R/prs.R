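#' Hardy-Weinberg genotype distribution
#'
#' Probabilities of carrying 0, 1 or 2 copies of the risk allele at a locus
#' with risk-allele frequency `p`, under Hardy-Weinberg equilibrium:
#' `((1-p)^2, 2p(1-p), p^2)`.
#'
#' @param freq Risk-allele frequency (or vector of frequencies) in `[0, 1]`.
#' @return For a single frequency, a numeric vector of length 3; for a vector
#'   of frequencies, a matrix with columns `d0`, `d1`, `d2`.
#' @export
hwe_genotype_distribution <- function(freq) {
  if (any(!is.finite(freq) | freq < 0 | freq > 1)) {
    stop("allele frequency must lie in [0, 1]")
  }
  q <- 1 - freq
  m <- cbind(d0 = q^2, d1 = 2 * freq * q, d2 = freq^2)
  if (length(freq) == 1L) drop(m) else m
}

#' Population mean relative risk of one SNP
#'
#' Under a multiplicative per-allele model the genotype relative risk is
#' `OR^g`; its population mean under Hardy-Weinberg genotype frequencies is
#' `mu = (1-p)^2 + 2p(1-p) OR + p^2 OR^2`. Dividing each genotype's relative
#' risk by `mu` centers the population mean of the per-SNP factor at exactly
#' 1, which is what makes the product-form PRS interpretable as a
#' relative-risk multiplier with population mean ~ 1.
#'
#' @param or_per_allele Per-allele odds ratio(s), > 0.
#' @param freq Risk-allele frequency(ies) strictly in (0, 1).
#' @return Numeric vector of mean relative risks, all > 0.
#' @export
snp_mean_relative_risk <- function(or_per_allele, freq) {
  if (any(!is.finite(or_per_allele) | or_per_allele <= 0)) {
    stop("odds ratio must be finite and > 0")
  }
  if (any(!is.finite(freq) | freq <= 0 | freq >= 1)) {
    stop("allele frequency must lie strictly in (0, 1)")
  }
  q <- 1 - freq
  q^2 + 2 * freq * q * or_per_allele + freq^2 * or_per_allele^2
}

#' Normalized per-SNP risk factor
#'
#' `OR^g / mu` for dosage `g` in 0/1/2; a missing dosage contributes the
#' neutral factor 1 (exclusion of unscoreable participants is handled by the
#' missingness threshold in [compute_prs()], not by imputation).
#'
#' @param dosage Risk-allele dosage(s): 0, 1, 2 or `NA`.
#' @param or_per_allele Per-allele odds ratio(s).
#' @param mu Population mean relative risk(s), from [snp_mean_relative_risk()].
#' @return Numeric vector of normalized risk factors.
#' @export
snp_adjusted_risk <- function(dosage, or_per_allele, mu) {
  out <- or_per_allele^dosage / mu
  out[is.na(dosage)] <- 1
  out
}

#' Compute centered polygenic risk scores
#'
#' The PRS is the product over panel SNPs of `OR^g / mu`, computed internally
#' as a sum of logs for numerical stability. With `mu` the Hardy-Weinberg
#' population mean of `OR^g`, the expected PRS in a cancer-free population
#' with the panel's allele frequencies is exactly 1.
#'
#' @param dosages Integer vector (one participant) or matrix (participants in
#'   rows) of risk-allele dosages in `{0, 1, 2, NA}`, columns aligned to the
#'   panel's SNP order.
#' @param panel A `snp_panel`.
#' @param group Ancestry group whose odds ratios and allele frequencies to
#'   use; one of [prs_groups()].
#' @param max_missing_fraction Maximum tolerated fraction of missing SNPs;
#'   participants above it are flagged non-scoreable (`scoreable = FALSE`,
#'   `prs = NA`). Default 0: any missing SNP makes the score non-scoreable,
#'   mirroring a trial design that excludes rather than imputes.
#' @return Data frame with columns `prs`, `n_used`, `n_missing`, `scoreable`,
#'   `group`, one row per participant.
#' @export
compute_prs <- function(dosages, panel, group,
                        max_missing_fraction = 0) {
  group <- match.arg(group, prs_groups())
  if (!is.numeric(max_missing_fraction) || max_missing_fraction < 0 ||
      max_missing_fraction >= 1) {
    stop("max_missing_fraction must lie in [0, 1)")
  }
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1L)
  p <- panel_for_group(panel, group)
  if (ncol(dosages) != nrow(p)) {
    stop("genotype vector length (", ncol(dosages),
         ") does not match panel size (", nrow(p), ")")
  }
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")

  mu <- snp_mean_relative_risk(p$or, p$freq)
  log_or <- log(p$or)
  d0 <- dosages
  d0[is.na(d0)] <- 0                       # neutral: contributes OR^0, and
  miss <- is.na(dosages)                   # its -log(mu) is added back below
  log_prs <- d0 %*% log_or - sum(log(mu)) + miss %*% log(mu)

  n_missing <- rowSums(miss)
  n_used <- ncol(dosages) - n_missing
  scoreable <- n_missing <= max_missing_fraction * ncol(dosages)
  prs <- exp(drop(log_prs))
  prs[!scoreable] <- NA_real_
  data.frame(prs = prs, n_used = n_used, n_missing = n_missing,
             scoreable = scoreable, group = group,
             stringsAsFactors = FALSE)
}

#' Quintile cutpoints of a PRS distribution
#'
#' 20/40/60/80th percentiles with linear interpolation between order
#' statistics (`stats::quantile()` type 7).
#'
#' @param prs_values Numeric vector, at least 5 values, no `NA`.
#' @return Named numeric vector of the four ascending cutoffs.
#' @export
quintile_cutpoints <- function(prs_values) {
  prs_values <- prs_values[!is.na(prs_values)]
  if (length(prs_values) < 5L) {
    stop("need at least 5 values to compute quintile cutpoints")
  }
  stats::quantile(prs_values, probs = c(0.2, 0.4, 0.6, 0.8),
                  names = TRUE, type = 7)
}
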