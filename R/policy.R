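#' Screening recommendation vocabulary
#'
#' The closed set of recommendations: no screening (or stop screening),
#' biennial mammography, annual mammography indicated by risk, annual
#' mammography indicated by extreme density, every-6-months screening
#' alternating mammogram and MRI, and guideline-based screening for
#' pathogenic-variant carriers (who bypass the risk pathway entirely).
#'
#' @param include_pv Include the `pv_guideline` level (default `TRUE`).
#' @return Character vector of levels in increasing screening intensity
#'   (with the two annual categories at equal intensity).
#' @export
screening_levels <- function(include_pv = TRUE) {
  lv <- c("none_or_stop", "biennial", "annual_risk", "annual_density",
          "q6mo_alternating")
  if (include_pv) lv <- c(lv, "pv_guideline")
  lv
}

# ordinal intensity used for density overrides and monotonicity checks
.rec_intensity <- c(none_or_stop = 0, biennial = 1, annual_risk = 2,
                    annual_density = 2, q6mo_alternating = 3,
                    pv_guideline = NA_real_)

#' Screening intensity of a recommendation
#'
#' @param rec Character vector of recommendation labels.
#' @return Numeric intensity: 0 none, 1 biennial, 2 annual, 3 six-monthly;
#'   `NA` for `pv_guideline` (not on the risk-ordered scale).
#' @export
recommendation_intensity <- function(rec) {
  unname(.rec_intensity[rec])
}

#' Construct and validate a screening threshold table
#'
#' Age bands must partition the configured age range with no gaps or
#' overlaps, and within each band the risk intervals must partition (0, 1)
#' exactly: half-open, lower-inclusive `[risk_lo, risk_hi)`, so a risk
#' sitting exactly on a boundary resolves upward to the higher-intensity
#' rule. Density overrides are applied after the risk rules and can only
#' escalate a recommendation.
#'
#' @param age_bands List of bands, each `list(ages = c(lo, hi), rules =
#'   data.frame(risk_lo, risk_hi, recommendation))` with inclusive integer
#'   age limits.
#' @param density_overrides Optional list of `list(density =, recommendation
#'   =)` entries.
#' @return A validated object of class `threshold_table`.
#' @export
threshold_table <- function(age_bands, density_overrides = list()) {
  tt <- structure(list(age_bands = age_bands,
                       density_overrides = density_overrides),
                  class = "threshold_table")
  validate_threshold_table(tt)
  tt
}

#' @rdname threshold_table
#' @param x Object to validate.
#' @export
validate_threshold_table <- function(x) {
  if (!length(x$age_bands)) stop("threshold table has no age bands")
  lims <- t(vapply(x$age_bands, function(b) as.numeric(b$ages), numeric(2)))
  o <- order(lims[, 1])
  lims <- lims[o, , drop = FALSE]
  if (any(lims[, 1] > lims[, 2])) stop("age band with lo > hi")
  if (nrow(lims) > 1L) {
    gaps <- lims[-1L, 1] - lims[-nrow(lims), 2]
    if (any(gaps <= 0)) stop("overlapping age bands")
    if (any(gaps != 1)) stop("gap between consecutive age bands")
  }
  for (b in x$age_bands) {
    r <- as.data.frame(b$rules, stringsAsFactors = FALSE)
    need <- c("risk_lo", "risk_hi", "recommendation")
    if (!all(need %in% names(r))) {
      stop("threshold rules need columns ", paste(need, collapse = ", "))
    }
    bad <- setdiff(r$recommendation, screening_levels(include_pv = FALSE))
    if (length(bad)) stop("unknown recommendation(s): ",
                          paste(bad, collapse = ", "))
    r <- r[order(r$risk_lo), , drop = FALSE]
    if (any(r$risk_lo >= r$risk_hi)) stop("risk interval with lo >= hi")
    if (r$risk_lo[1] != 0 || r$risk_hi[nrow(r)] != 1) {
      stop("risk intervals must cover (0, 1): first lo must be 0, last hi 1")
    }
    if (nrow(r) > 1L) {
      lo <- r$risk_lo[-1L]; hi <- r$risk_hi[-nrow(r)]
      if (any(lo < hi)) stop("overlapping risk intervals in an age band")
      if (any(lo > hi)) stop("gap between risk intervals in an age band")
    }
  }
  for (d in x$density_overrides) {
    if (!d$recommendation %in% screening_levels(include_pv = FALSE)) {
      stop("unknown override recommendation: ", d$recommendation)
    }
  }
  invisible(x)
}

#' Read a screening threshold table from YAML
#'
#' The package fixture
#' `system.file("extdata", "thresholds_synthetic.yaml", package =
#' "prsscreen")` is a synthetic placeholder with the trial's structure (age
#' bands 40-49 and 50-74, four ascending risk bands, an extreme-density
#' override); the trial's own threshold table can be dropped in verbatim.
#'
#' @param path YAML path with `age_bands` and optional `density_overrides`.
#' @return A validated `threshold_table`.
#' @export
read_threshold_table <- function(path) {
  raw <- yaml::read_yaml(path)
  bands <- lapply(raw$age_bands, function(b) {
    list(ages = unlist(b$ages),
         rules = do.call(rbind, lapply(b$rules, function(r)
           data.frame(risk_lo = r$risk_lo, risk_hi = r$risk_hi,
                      recommendation = r$recommendation,
                      stringsAsFactors = FALSE))))
  })
  ov <- lapply(raw$density_overrides, function(d)
    list(density = d$density, recommendation = d$recommendation))
  threshold_table(bands, ov)
}

#' @export
print.threshold_table <- function(x, ...) {
  for (b in x$age_bands) {
    cat("ages ", b$ages[1], "-", b$ages[2], ":\n", sep = "")
    r <- b$rules
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  [%-7g, %-7g) -> %s\n", r$risk_lo[i], r$risk_hi[i],
                  r$recommendation[i]))
    }
  }
  for (d in x$density_overrides) {
    cat("density", d$density, "escalates to at least", d$recommendation, "\n")
  }
  invisible(x)
}

#' Assign a screening recommendation
#'
#' Pathogenic-variant carriers are always assigned guideline-based screening
#' regardless of risk. Everyone else gets the unique rule whose age band and
#' risk interval contain them, after which density overrides may escalate
#' (never de-escalate) the recommendation.
#'
#' @param age Age(s) in whole years.
#' @param risk 5-year absolute risk(s), strictly in (0, 1).
#' @param density BI-RADS density label(s) (`"a"`..`"d"`, `"unknown"`).
#' @param pv Logical: pathogenic-variant carrier.
#' @param thresholds A `threshold_table`.
#' @return Character vector of recommendations from [screening_levels()].
#' @export
assign_screening <- function(age, risk, density, pv, thresholds) {
  n <- max(length(age), length(risk), length(density), length(pv))
  age <- rep_len(age, n); risk <- rep_len(risk, n)
  density <- rep_len(as.character(density), n); pv <- rep_len(pv, n)
  if (any(!pv & (!is.finite(risk) | risk <= 0 | risk >= 1))) {
    stop("risk must lie strictly in (0, 1)")
  }

  out <- character(n)
  out[pv] <- "pv_guideline"
  for (i in which(!pv)) {
    band <- NULL
    for (b in thresholds$age_bands) {
      if (age[i] >= b$ages[1] && age[i] <= b$ages[2]) { band <- b; break }
    }
    if (is.null(band)) stop("no age band covers age ", age[i])
    r <- band$rules
    hit <- which(risk[i] >= r$risk_lo & risk[i] < r$risk_hi)
    if (length(hit) != 1L) stop("no unique risk rule for risk ", risk[i])
    rec <- r$recommendation[hit]
    for (d in thresholds$density_overrides) {
      if (identical(density[i], d$density) &&
          .rec_intensity[rec] < .rec_intensity[d$recommendation]) {
        rec <- d$recommendation
      }
    }
    out[i] <- rec
  }
  out
}

#' Apply manual review overrides to assignment records
#'
#' Models a screening review board as a pass-through: the final
#' recommendation equals the model recommendation unless an explicit
#' override is present for that participant.
#'
#' @param records Data frame with columns `id` and `rec_combined` (plus any
#'   others, untouched).
#' @param overrides Named character vector (or NULL) mapping participant id
#'   to a forced recommendation. Overrides for unknown ids raise a warning
#'   and are ignored.
#' @return `records` with a `rec_final` column set or updated.
#' @export
apply_override <- function(records, overrides = NULL) {
  records$rec_final <- records$rec_combined
  if (is.null(overrides) || !length(overrides)) return(records)
  ids <- names(overrides)
  unknown <- setdiff(ids, as.character(records$id))
  if (length(unknown)) {
    warning("overrides for unknown id(s) ignored: ",
            paste(unknown, collapse = ", "))
  }
  i <- match(as.character(records$id), ids)
  hit <- !is.na(i)
  records$rec_final[hit] <- unname(overrides[i[hit]])
  records
}

#' Expected screening encounters per year for a recommendation
#'
#' @param rec Character vector of recommendation labels.
#' @param freq_map Named numeric map recommendation -> screens per year.
#'   The default encodes biennial mammography as 0.5 encounters/year, annual
#'   as 1 and 6-monthly alternating mammogram/MRI as 2; pathogenic-variant
#'   carriers are excluded from utilization analyses and deliberately absent
#'   from the default map.
#' @return Numeric vector of screens per year.
#' @export
screens_per_year <- function(rec, freq_map = default_freq_map()) {
  miss <- setdiff(unique(rec), names(freq_map))
  if (length(miss)) {
    stop("no screening frequency defined for: ", paste(miss, collapse = ", "))
  }
  unname(freq_map[rec])
}

#' @rdname screens_per_year
#' @export
default_freq_map <- function() {
  c(none_or_stop = 0, biennial = 0.5, annual_risk = 1,
    annual_density = 1, q6mo_alternating = 2)
}
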