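#' SNP panels
#'
#' A SNP panel is a data frame with one row per SNP and columns
#' `rsid`, `chrom`, `pos`, `risk_allele`, `other_allele`, plus a pair of
#' columns `or_<group>` (per-allele odds ratio) and `freq_<group>`
#' (risk-allele frequency) for each ancestry group in [prs_groups()].
#' Frequencies used for scoring must lie strictly inside (0, 1) and odds
#' ratios must be positive.
#'
#' @param x Data frame with the columns above.
#' @return `as_snp_panel()` returns `x` validated, with class `snp_panel`
#'   prepended.
#' @export
as_snp_panel <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  validate_snp_panel(x)
  class(x) <- unique(c("snp_panel", class(x)))
  x
}

#' @rdname as_snp_panel
#' @export
validate_snp_panel <- function(x) {
  needed <- c("rsid", "chrom", "pos", "risk_allele", "other_allele")
  miss <- setdiff(needed, names(x))
  if (length(miss)) stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) < 1L) stop("panel must contain at least one SNP")
  if (anyDuplicated(x$rsid)) stop("panel rsids must be unique")
  if (any(x$risk_allele == x$other_allele)) {
    stop("risk_allele must differ from other_allele")
  }
  for (g in prs_groups()) {
    oc <- paste0("or_", g); fc <- paste0("freq_", g)
    if (!oc %in% names(x) || !fc %in% names(x)) {
      stop("panel is missing per-group columns for group: ", g)
    }
    if (any(!is.finite(x[[oc]]) | x[[oc]] <= 0)) {
      stop("odds ratios for group ", g, " must be finite and > 0")
    }
    if (any(!is.finite(x[[fc]]) | x[[fc]] <= 0 | x[[fc]] >= 1)) {
      stop("risk-allele frequencies for group ", g,
           " must lie strictly in (0, 1)")
    }
  }
  invisible(x)
}

#' Read a SNP panel from a tab-separated file
#'
#' @param path Path to a TSV with header columns `rsid`, `chrom`, `pos`,
#'   `risk_allele`, `other_allele`, and `or_<group>` / `freq_<group>` per
#'   ancestry group.
#' @return A validated `snp_panel`.
#' @export
read_snp_panel <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  x$chrom <- as.character(x$chrom)
  as_snp_panel(x)
}

#' Extract one group's scoring parameters from a panel
#'
#' @param panel A `snp_panel`.
#' @param group One of [prs_groups()].
#' @return Data frame with columns `rsid`, `or`, `freq` in panel order.
#' @export
panel_for_group <- function(panel, group) {
  group <- match.arg(group, prs_groups())
  data.frame(
    rsid = panel$rsid,
    or   = panel[[paste0("or_", group)]],
    freq = panel[[paste0("freq_", group)]],
    stringsAsFactors = FALSE
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel:", nrow(x), "SNPs,", length(prs_groups()),
      "ancestry groups\n")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...", nrow(x) - 4L, "more SNPs\n")
  invisible(x)
}

#' Flag strand-ambiguous SNPs
#'
#' A/T and C/G SNPs cannot be strand-resolved from alleles alone; they are
#' flagged (and scored by default).
#'
#' @param panel A `snp_panel`.
#' @return Logical vector, one element per SNP.
#' @export
strand_ambiguous <- function(panel) {
  a <- toupper(panel$risk_allele); b <- toupper(panel$other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}
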