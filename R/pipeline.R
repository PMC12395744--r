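#' Bundled synthetic configuration files
#'
#' Paths to the synthetic coefficient and threshold fixtures shipped with
#' the package. Both are stand-ins with the structure (not the values) of
#' the published BCSC v2 tables and a trial threshold table; real tables in
#' the same format can be supplied to the readers instead.
#'
#' @return A file path.
#' @export
default_bcsc_coefficients <- function() {
  read_bcsc_coefficients(system.file("extdata",
                                     "bcsc_coefficients_synthetic.yaml",
                                     package = "prsscreen"))
}

#' @rdname default_bcsc_coefficients
#' @export
default_thresholds <- function() {
  read_threshold_table(system.file("extdata", "thresholds_synthetic.yaml",
                                   package = "prsscreen"))
}

#' Run the full risk-stratified screening pipeline
#'
#' For each participant: compute the ancestry-tailored PRS from genotypes,
#' the clinical (BCSC-style) 5-year risk from phenotypes, the Bayesian
#' combined risk, and the screening recommendation under both risk models;
#' then apply any manual-review overrides. Pathogenic-variant carriers are
#' assigned guideline-based screening in every slot.
#'
#' @param cohort Phenotype data frame with columns `id`, `age`, `race`,
#'   `hispanic`, `fdr_bc`, `biopsy`, `density`, `pv_carrier` (and optionally
#'   `prs_group`).
#' @param dosages Dosage matrix aligned to `panel` (participants in rows,
#'   same order as `cohort`).
#' @param panel A `snp_panel`.
#' @param coeffs A `bcsc_coefficients` object (default: bundled synthetic
#'   fixture).
#' @param thresholds A `threshold_table` (default: bundled synthetic
#'   fixture).
#' @param max_missing_fraction Passed to [compute_prs()].
#' @param alpha PRS attenuation exponent passed to [combine_bcsc_prs()].
#' @param overrides Optional named vector of manual-review overrides, see
#'   [apply_override()].
#' @return Object of class `screening_comparison`: a list with `records`
#'   (id, group, prs, scoreable, bcsc_5yr, combined_5yr, rec_bcsc,
#'   rec_combined, rec_final, age, pv) plus the inputs' metadata.
#' @export
risk_screening <- function(cohort, dosages, panel,
                           coeffs = default_bcsc_coefficients(),
                           thresholds = default_thresholds(),
                           max_missing_fraction = 0, alpha = 1,
                           overrides = NULL) {
  cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  n <- nrow(cohort)
  stopifnot(nrow(dosages) == n)
  grp <- if ("prs_group" %in% names(cohort)) cohort$prs_group
         else assign_prs_group(cohort$race, cohort$hispanic)

  prs <- rep(NA_real_, n); scoreable <- rep(FALSE, n)
  for (g in unique(grp)) {
    i <- which(grp == g)
    res <- compute_prs(dosages[i, , drop = FALSE], panel, g,
                       max_missing_fraction = max_missing_fraction)
    prs[i] <- res$prs; scoreable[i] <- res$scoreable
  }

  rr <- relative_risk(cohort, coeffs)
  bcsc <- absolute_5yr_risk(rr, cohort$age, grp, coeffs)
  combined <- rep(NA_real_, n)
  combined[scoreable] <- combine_bcsc_prs(bcsc[scoreable], prs[scoreable],
                                          alpha = alpha)

  pv <- as.logical(cohort$pv_carrier)
  rec_bcsc <- assign_screening(cohort$age, bcsc, cohort$density, pv,
                               thresholds)
  rec_combined <- rep(NA_character_, n)
  ok <- pv | scoreable
  rec_combined[ok] <- assign_screening(cohort$age[ok],
                                       ifelse(pv[ok], 0.5, combined[ok]),
                                       cohort$density[ok], pv[ok],
                                       thresholds)
  records <- data.frame(
    id = cohort$id, age = cohort$age, group = grp, pv = pv,
    prs = prs, scoreable = scoreable, bcsc_5yr = bcsc,
    combined_5yr = combined, rec_bcsc = rec_bcsc,
    rec_combined = rec_combined, stringsAsFactors = FALSE
  )
  records <- apply_override(records, overrides)
  structure(list(records = records, thresholds = thresholds,
                 alpha = alpha),
            class = "screening_comparison")
}

#' @export
print.screening_comparison <- function(x, ...) {
  r <- x$records
  cat("Screening comparison: n =", nrow(r), "participants (",
      sum(r$pv), "PV carriers,", sum(!r$scoreable & !r$pv),
      "non-scoreable )\n")
  print(utils::head(r, 4L))
  invisible(x)
}

#' @export
summary.screening_comparison <- function(object,
                                         strata = list(c(40, 49), c(50, 74)),
                                         freq_map = default_freq_map(),
                                         ...) {
  r <- object$records[object$records$scoreable & !object$records$pv, ,
                      drop = FALSE]
  out <- lapply(strata, function(s) {
    tab <- cross_tabulate(r, age_stratum = s)
    if (tab$n_total == 0) {
      return(list(stratum = s, n = 0))
    }
    rs <- r[r$age >= s[1] & r$age <= s[2], , drop = FALSE]
    list(stratum = s, n = tab$n_total, table = tab,
         discordance = discordance_percentage(tab),
         screens_bcsc = mean_screens_per_woman_year(rs, "bcsc", freq_map),
         screens_combined = mean_screens_per_woman_year(rs, "combined",
                                                        freq_map))
  })
  names(out) <- vapply(strata, function(s) paste(s, collapse = "-"),
                       character(1))
  class(out) <- "summary.screening_comparison"
  out
}

#' @export
print.summary.screening_comparison <- function(x, ...) {
  for (nm in names(x)) {
    s <- x[[nm]]
    cat("== ages ", nm, " (n = ", s$n, ") ==\n", sep = "")
    if (s$n == 0) next
    cat(sprintf("  discordant recommendations: %.2f%% (%d/%d)\n",
                s$discordance$percent, s$discordance$n_discordant,
                s$discordance$n_total))
    cat(sprintf("  screens/woman-year: clinical %.3f (1 per %d women), combined %.3f (1 per %d women)\n",
                s$screens_bcsc$mean_screens, s$screens_bcsc$women_per_screen,
                s$screens_combined$mean_screens,
                s$screens_combined$women_per_screen))
  }
  invisible(x)
}
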