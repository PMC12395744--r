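#' Simulate a SNP panel
#'
#' Generates an ancestry-tailored scoring panel with per-group per-allele
#' odds ratios drawn log-normal around 1 (sdlog 0.08, the effect-size scale
#' typical of genome-wide-significant breast cancer SNPs) and risk-allele
#' frequencies Uniform(0.05, 0.95). The panel satisfies every scoring
#' invariant and stands in for a real panel file of the same format.
#'
#' @param n_snps Number of SNPs (the trial's per-group panels held 118-126;
#'   default 120).
#' @param seed Optional RNG seed for reproducibility.
#' @param or_sdlog Log-scale SD of the per-allele odds ratios.
#' @return A `snp_panel`.
#' @export
simulate_panel <- function(n_snps = 120L, seed = NULL, or_sdlog = 0.08) {
  stopifnot(n_snps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  chrom <- sort(sample(1:22, n_snps, replace = TRUE))
  pos <- integer(n_snps)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(5e7, length(i)))
  }
  bases <- c("A", "C", "G", "T")
  risk <- sample(bases, n_snps, replace = TRUE)
  other <- vapply(risk, function(b) sample(setdiff(bases, b), 1L), character(1))
  x <- data.frame(
    rsid = sprintf("rs%07d", sample.int(9999999, n_snps)),
    chrom = as.character(chrom), pos = pos,
    risk_allele = risk, other_allele = unname(other),
    stringsAsFactors = FALSE
  )
  for (g in prs_groups()) {
    x[[paste0("or_", g)]] <- stats::rlnorm(n_snps, 0, or_sdlog)
    x[[paste0("freq_", g)]] <- stats::runif(n_snps, 0.05, 0.95)
  }
  as_snp_panel(x)
}

#' Simulate Hardy-Weinberg genotypes for one ancestry group
#'
#' Each SNP's risk-allele dosage is drawn independently as Binomial(2, p)
#' with p the group's risk-allele frequency — exactly the Hardy-Weinberg
#' genotype distribution used by the PRS centering.
#'
#' @param panel A `snp_panel`.
#' @param group Ancestry group, one of [prs_groups()].
#' @param n Number of individuals.
#' @param seed Optional RNG seed.
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @return Integer matrix (n x panel size) of dosages, rsids as colnames.
#' @export
simulate_genotypes <- function(panel, group, n, seed = NULL,
                               missing_rate = 0) {
  stopifnot(n >= 1L, missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  p <- panel_for_group(panel, group)
  m <- matrix(NA_real_, n, nrow(p), dimnames = list(NULL, p$rsid))
  for (j in seq_len(nrow(p))) m[, j] <- stats::rbinom(n, 2L, p$freq[j])
  if (missing_rate > 0) {
    m[stats::runif(length(m)) < missing_rate] <- NA_real_
  }
  m
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the baseline composition of a large US risk-based
#' screening trial population: race/ethnicity mixture (Hispanic 8.9%, NH
#' American Indian/Alaska Native 0.2%, NH Asian/Pacific Islander 4.8%, NH
#' Black 4.5%, NH other/mixed/unknown 4.0%, NH White 77.6%), family-history
#' strata (none 48%, second-degree only 25%, first-degree only 16%, both
#' 12%), pathogenic-variant carriage 3.1%, BI-RADS density mixture (a 4.7%,
#' b 35%, c 40%, d 8.7%, unknown 12%), and ages 40-74 with median near 53
#' (IQR roughly 45-62). `fh_prs_link` and `density_prs_link` are
#' proportional-odds slopes (per unit of centered log-PRS) tying
#' family-history extent and density to the realized PRS, so the generator
#' reproduces the direction of the observed PRS gradients; zero slopes give
#' independence.
#'
#' @param race_mix,fh_mix,density_mix,biopsy_mix Named probability vectors
#'   (renormalized from the default counts; must sum to 1 within 1e-9 if
#'   supplied).
#' @param pv_rate Pathogenic-variant carrier probability.
#' @param age_shape1,age_shape2 Beta shape parameters of the discretized age
#'   distribution scaled onto 40-74.
#' @param fh_prs_link,density_prs_link Ordinal-logistic slopes on centered
#'   log-PRS.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(race_mix = NULL, fh_mix = NULL, density_mix = NULL,
                          biopsy_mix = NULL, pv_rate = 669 / 21631,
                          age_shape1 = 1.3, age_shape2 = 1.9,
                          fh_prs_link = 0.6, density_prs_link = 0.3) {
  norm <- function(x) x / sum(x)
  if (is.null(race_mix)) {
    race_mix <- norm(c(hispanic = 1932, american_indian_alaska_native = 44,
                       asian = 1029, black = 969, other = 875, white = 16782))
  }
  if (is.null(fh_mix)) {
    fh_mix <- norm(c(none = 10433, sdr_only = 5302, fdr_only = 3369,
                     both = 2527))
  }
  if (is.null(density_mix)) {
    density_mix <- norm(c(a = 1009, b = 7565, c = 8581, d = 1876,
                          unknown = 2600))
  }
  if (is.null(biopsy_mix)) {
    biopsy_mix <- c(none = 0.85, nonproliferative = 0.06,
                    proliferative_no_atypia = 0.04, atypia = 0.02,
                    lcis = 0.005, unknown = 0.025)
  }
  for (m in list(race_mix, fh_mix, density_mix, biopsy_mix)) {
    if (abs(sum(m) - 1) > 1e-9) stop("mixture proportions must sum to 1")
    if (any(m < 0)) stop("mixture proportions must be nonnegative")
  }
  stopifnot(pv_rate >= 0, pv_rate <= 1,
            is.finite(fh_prs_link), is.finite(density_prs_link))
  structure(list(race_mix = race_mix, fh_mix = fh_mix,
                 density_mix = density_mix, biopsy_mix = biopsy_mix,
                 pv_rate = pv_rate, age_shape1 = age_shape1,
                 age_shape2 = age_shape2, fh_prs_link = fh_prs_link,
                 density_prs_link = density_prs_link),
            class = "cohort_config")
}

# ordinal draw: P(Y <= k | z) = plogis(cut_k - beta * z), cutpoints from the
# target marginal at z = 0
.ordinal_draw <- function(marginal, z, beta) {
  k <- length(marginal)
  cuts <- stats::qlogis(cumsum(marginal)[-k])
  u <- stats::runif(length(z))
  cum <- vapply(cuts, function(ck) stats::plogis(ck - beta * z),
                numeric(length(z)))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1L)
  idx <- rowSums(u > cum) + 1L
  names(marginal)[idx]
}

#' Simulate a synthetic screening cohort with genotypes
#'
#' Draws demographics from the configured mixtures, samples Hardy-Weinberg
#' genotypes from the participant's PRS group's allele frequencies, computes
#' the centered PRS, and then draws family-history extent and breast density
#' conditional on the realized PRS through ordinal-logistic links, so that
#' positive link slopes reproduce the direction of the observed PRS
#' gradients across those strata. Pathogenic-variant status is an
#' independent Bernoulli draw.
#'
#' @param n Cohort size.
#' @param panel A `snp_panel` (default: a fresh simulated 120-SNP panel).
#' @param config A [cohort_config()].
#' @param seed Optional RNG seed covering every draw.
#' @return List of class `synthetic_cohort` with elements `cohort` (data
#'   frame: id, age, race, hispanic, prs_group, fdr_bc, sdr_bc, biopsy,
#'   density, pv_carrier, prs), `dosages` (matrix) and `panel`.
#' @export
simulate_cohort <- function(n, panel = NULL, config = cohort_config(),
                            seed = NULL) {
  stopifnot(n >= 0L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(panel)) panel <- simulate_panel()

  race_cat <- sample(names(config$race_mix), n, replace = TRUE,
                     prob = config$race_mix)
  hispanic <- race_cat == "hispanic"
  race <- ifelse(hispanic, "other", race_cat)
  grp <- assign_prs_group(race, hispanic)
  age <- 40L + as.integer(round(34 * stats::rbeta(n, config$age_shape1,
                                                  config$age_shape2)))

  dosages <- matrix(NA_real_, n, nrow(panel),
                    dimnames = list(NULL, panel$rsid))
  prs <- numeric(n)
  for (g in unique(grp)) {
    i <- which(grp == g)
    dosages[i, ] <- simulate_genotypes(panel, g, length(i))
    prs[i] <- compute_prs(dosages[i, , drop = FALSE], panel, g)$prs
  }

  z <- if (n > 1L) log(prs) - mean(log(prs)) else rep(0, n)
  fh <- .ordinal_draw(config$fh_mix, z, config$fh_prs_link)
  # density: "unknown" is missingness, drawn independently; the ordered a-d
  # part carries the PRS link
  p_unk <- config$density_mix[["unknown"]]
  unk <- stats::runif(n) < p_unk
  dmix <- config$density_mix[c("a", "b", "c", "d")]
  density <- .ordinal_draw(dmix / sum(dmix), z, config$density_prs_link)
  density[unk] <- "unknown"
  biopsy <- sample(names(config$biopsy_mix), n, replace = TRUE,
                   prob = config$biopsy_mix)
  pv <- stats::runif(n) < config$pv_rate

  cohort <- data.frame(
    id = sprintf("P%06d", seq_len(n)),
    age = age, race = race, hispanic = hispanic, prs_group = grp,
    fdr_bc = as.integer(fh %in% c("fdr_only", "both")),
    sdr_bc = as.integer(fh %in% c("sdr_only", "both")),
    fh_category = factor(fh, levels = c("none", "sdr_only", "fdr_only",
                                        "both")),
    biopsy = biopsy, density = density, pv_carrier = pv, prs = prs,
    stringsAsFactors = FALSE
  )
  structure(list(cohort = cohort, dosages = dosages, panel = panel),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", nrow(x$cohort), "participants,",
      nrow(x$panel), "panel SNPs\n")
  print(utils::head(x$cohort, 4L))
  invisible(x)
}

#' Write cohort fixtures to disk
#'
#' Emits the phenotype table as CSV, the dosage matrix as CSV (participants
#' in rows, rsids in columns), and the genotypes as a plain-text VCF v4.2
#' (one sample column per participant, the panel's risk allele as ALT, GT
#' derived from the dosage). All files round-trip losslessly through the
#' package readers.
#'
#' @param sim A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`cohort`, `dosages`, `vcf`,
#'   `panel`).
#' @export
write_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(cohort = file.path(dir, "cohort.csv"),
                dosages = file.path(dir, "dosages.csv"),
                vcf = file.path(dir, "genotypes.vcf"),
                panel = file.path(dir, "panel.tsv"))
  utils::write.csv(sim$cohort, paths$cohort, row.names = FALSE)
  dos <- data.frame(id = sim$cohort$id, sim$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(dos, paths$dosages, row.names = FALSE, na = "")
  write_genotypes_vcf(sim$dosages, sim$panel, paths$vcf,
                      sample_ids = sim$cohort$id)
  utils::write.table(as.data.frame(sim$panel), paths$panel, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write a dosage matrix as a plain-text VCF
#'
#' @param dosages Matrix (participants x panel SNPs) of risk-allele dosages.
#' @param panel The matching `snp_panel`; the risk allele is written as ALT,
#'   the other allele as REF, so dosage equals the ALT-allele count.
#' @param path Output path.
#' @param sample_ids Sample column names (default `rownames(dosages)` or
#'   generated).
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(dosages, panel, path, sample_ids = NULL) {
  n <- nrow(dosages)
  if (is.null(sample_ids)) sample_ids <- rownames(dosages)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%06d", seq_len(n))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

  ord <- order(suppressWarnings(as.numeric(panel$chrom)), panel$chrom,
               panel$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=prsscreen",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- vapply(ord, function(j) {
    d <- dosages[, j]
    calls <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(panel$chrom[j], panel$pos[j], panel$rsid[j],
            panel$other_allele[j], panel$risk_allele[j], ".", "PASS", ".",
            "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
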