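#' Read a risk-allele dosage matrix from CSV
#'
#' Rows are participants (first column `id`), remaining columns are SNP
#' rsids. Entries are risk-allele counts 0/1/2 or empty/NA for missing.
#'
#' @param path CSV path.
#' @param panel Optional `snp_panel`; when given, columns are reordered to
#'   the panel's SNP order and an error is raised for absent SNPs.
#' @return Numeric matrix with participant ids as rownames.
#' @export
read_dosage_csv <- function(path, panel = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(x)) stop("dosage CSV must have an 'id' column")
  ids <- as.character(x$id)
  m <- as.matrix(x[setdiff(names(x), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!is.null(panel)) {
    miss <- setdiff(panel$rsid, colnames(m))
    if (length(miss)) {
      stop("dosage matrix lacks panel SNP(s): ", paste(miss, collapse = ", "))
    }
    m <- m[, panel$rsid, drop = FALSE]
  }
  m
}

#' Derive risk-allele dosages from a VCF
#'
#' Genotypes are read with `vcfR`; variants are matched to panel SNPs by rsid
#' first, then by chromosome/position plus allele pair for records without a
#' matching id. The dosage is the count of the panel's risk allele in the GT
#' field. Panel SNPs absent from the VCF (or with unphaseable/missing GT)
#' yield `NA`. Strand-ambiguous (A/T, C/G) panel SNPs are scored but reported
#' via the `strand_ambiguous` attribute so callers can exclude them.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param panel A `snp_panel`.
#' @return Numeric matrix (participants x panel SNPs) of dosages with sample
#'   names as rownames, panel rsids as colnames.
#' @export
read_genotypes_vcf <- function(path, panel) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")

  # match panel rows to VCF rows: rsid, then chrom/pos + allele pair
  key_pos <- paste(fix$CHROM, fix$POS)
  idx <- match(panel$rsid, fix$ID)
  unmatched <- which(is.na(idx))
  if (length(unmatched)) {
    cand <- match(paste(panel$chrom[unmatched], panel$pos[unmatched]), key_pos)
    same_alleles <- !is.na(cand) &
      ((toupper(fix$REF[cand]) == toupper(panel$risk_allele[unmatched]) &
          toupper(fix$ALT[cand]) == toupper(panel$other_allele[unmatched])) |
         (toupper(fix$REF[cand]) == toupper(panel$other_allele[unmatched]) &
            toupper(fix$ALT[cand]) == toupper(panel$risk_allele[unmatched])))
    idx[unmatched[same_alleles]] <- cand[same_alleles]
  }

  n_samp <- ncol(gt)
  out <- matrix(NA_real_, nrow = n_samp, ncol = nrow(panel),
                dimnames = list(colnames(gt), panel$rsid))
  for (j in seq_len(nrow(panel))) {
    i <- idx[j]
    if (is.na(i)) next
    # which GT allele index (0 = REF) is the risk allele?
    alleles <- c(fix$REF[i], strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    risk_idx <- which(toupper(alleles) == toupper(panel$risk_allele[j])) - 1L
    if (!length(risk_idx)) next
    calls <- strsplit(gsub("\\|", "/", gt[i, ]), "/", fixed = FALSE)
    out[, j] <- vapply(calls, function(a) {
      if (any(a %in% c(".", ""))) return(NA_real_)
      sum(as.integer(a) == risk_idx)
    }, numeric(1))
  }
  attr(out, "strand_ambiguous") <- strand_ambiguous(panel)
  out
}
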